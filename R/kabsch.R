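#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` (determinant +1, reflections excluded) and
#' translation `t` minimizing the root-mean-square deviation between
#' `X %*% t(R) + t` and `Y`, via singular value decomposition of the
#' cross-covariance of the centred point sets.
#'
#' @param X,Y N x 3 coordinate matrices with paired rows, N >= 3 and not all
#'   collinear.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd` in Angstrom after the transform.
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3L, ncol(Y) == 3L, nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < 3L) stop("at least 3 paired points are required", call. = FALSE)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc) # 3x3 cross-covariance
  sv <- svd(H)
  # collinear/degenerate sets leave the rotation about the axis undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cy - R %*% cx)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Two-conformation reference pair
#'
#' The two experimentally determined conformations of a fold-switching
#' protein (e.g. the dominant "ground" state and the alternative,
#' fold-switched state) together with the fold-switching residue interval
#' they are scored over. Both references must carry the same sequence over
#' the region.
#'
#' @param ground,alternative [structure_model]s of the two conformations.
#' @param region inclusive residue-number interval `c(from, to)`.
#' @param labels names for the two conformations.
#' @return object of class `reference_pair`.
#' @export
reference_pair <- function(ground, alternative, region,
                           labels = c("ground", "alternative")) {
  stopifnot(inherits(ground, "structure_model"),
            inherits(alternative, "structure_model"),
            length(region) == 2L, region[1] <= region[2],
            length(labels) == 2L)
  g <- extract_region(ground, region)
  a <- extract_region(alternative, region)
  if (length(g$plddt) == 0L || length(a$plddt) == 0L) {
    stop("fold-switching region empty in a reference", call. = FALSE)
  }
  if (model_sequence(g) != model_sequence(a)) {
    stop("reference conformations differ in sequence over the region",
         call. = FALSE)
  }
  structure(list(ground = ground, alternative = alternative,
                 region = as.integer(region), labels = labels),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("reference_pair: %s / %s, region %d-%d\n",
              x$labels[1], x$labels[2], x$region[1], x$region[2]))
  invisible(x)
}

#' RMSD of a model against both reference conformations
#'
#' Extracts the fold-switching region from the model and from each
#' reference, superposes independently with [kabsch_superpose()] on the
#' region's atoms only (set `fit_whole = TRUE` to fit on the full shared
#' chain but still score the region), and reports both RMSDs.
#'
#' @param model a [structure_model] covering `refs$region`.
#' @param refs a [reference_pair].
#' @param atom_mode `"all_heavy"` (default) or `"ca_only"`.
#' @param fit_whole logical; fit the superposition on the whole chain
#'   instead of the region only.
#' @return object of class `dual_rmsd`: list with `rmsd_ground`, `rmsd_alt`
#'   (Angstrom), `n_atoms`, `atom_mode`.
#' @export
dual_rmsd <- function(model, refs, atom_mode = c("all_heavy", "ca_only"),
                      fit_whole = FALSE) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(model, "structure_model"), inherits(refs, "reference_pair"))
  one <- function(ref) {
    if (fit_whole) {
      fit <- map_atoms(model, ref, atom_mode)
      sup <- kabsch_superpose(fit$X, fit$Y)
      mr <- extract_region(model, refs$region)
      rr <- extract_region(ref, refs$region)
      sc <- map_atoms(mr, rr, atom_mode)
      moved <- sweep(sc$X %*% t(sup$rotation), 2, sup$translation, "+")
      list(rmsd = sqrt(mean(rowSums((moved - sc$Y)^2))), n = sc$n_atoms)
    } else {
      mr <- extract_region(model, refs$region)
      rr <- extract_region(ref, refs$region)
      sc <- map_atoms(mr, rr, atom_mode)
      list(rmsd = kabsch_superpose(sc$X, sc$Y)$rmsd, n = sc$n_atoms)
    }
  }
  g <- one(refs$ground)
  a <- one(refs$alternative)
  structure(list(rmsd_ground = g$rmsd, rmsd_alt = a$rmsd,
                 n_atoms = min(g$n, a$n), atom_mode = atom_mode),
            class = "dual_rmsd")
}

#' @export
print.dual_rmsd <- function(x, ...) {
  cat(sprintf("dual_rmsd: ground %.2f A, alternative %.2f A (%d atoms, %s)\n",
              x$rmsd_ground, x$rmsd_alt, x$n_atoms, x$atom_mode))
  invisible(x)
}
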