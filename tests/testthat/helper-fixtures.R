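# shared fixtures and independent oracles, all built in code at test time

# write a small PDB file by hand (fixed-column ATOM records) so the reader
# is tested against text we control, not against write_model()
write_tiny_pdb <- function(path, b = c(70, 80), record = "ATOM",
                           drop_ca_in = integer(0)) {
  lines <- character(0)
  eleno <- 0L
  for (i in seq_along(b)) {
    for (atom in c("N", "CA", "C")) {
      if (atom == "CA" && i %in% drop_ca_in) next
      eleno <- eleno + 1L
      lines <- c(lines, sprintf(
        "%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        record, eleno, atom, "ALA", "A", i,
        i * 3.8 + match(atom, c("N", "CA", "C")) * 0.5, 1.0, 2.0, 1.00, b[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# random non-degenerate point cloud
random_points <- function(n, seed) {
  with_seed_test(seed, matrix(stats::rnorm(n * 3, sd = 3), ncol = 3))
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function(seed) {
  with_seed_test(seed, {
    qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# --- brute-force rotation-grid oracle for the Kabsch superposition ---------
# All rotations on a ZYZ Euler grid at `step` degrees; returns the minimum
# RMSD over the grid after optimal translation (centroid matching). Entirely
# independent of kabsch_superpose().
rotation_grid_matrix <- local({
  cache <- list()
  function(step) {
    key <- as.character(step)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    a <- seq(0, 360 - step, by = step) * pi / 180
    b <- seq(0, 180, by = step) * pi / 180
    g <- expand.grid(a = a, b = b, c = a)
    out <- matrix(NA_real_, nrow(g), 9)
    for (k in seq_len(nrow(g))) {
      out[k, ] <- as.vector(rz(g$a[k]) %*% ry(g$b[k]) %*% rz(g$c[k]))
    }
    cache[[key]] <<- out
    out
  }
})

grid_min_rmsd <- function(X, Y, step = 10) {
  Rmat <- rotation_grid_matrix(step)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  const <- sum(Xc^2) + sum(Yc^2)
  M <- crossprod(Xc, Yc) # sum_i x_i y_i^T
  scores <- as.numeric(Rmat %*% as.vector(t(M))) # trace(R_k M) per rotation
  sqrt(pmax(0, const - 2 * max(scores)) / nrow(X))
}

# a reusable reference pair for structure-side tests
fixture_refs <- function(length = 40, seed = 1) {
  make_fold_pair(length, seed = seed)
}

# copy of with_seed from the package internals for test-local determinism
with_seed <- with_seed_test
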