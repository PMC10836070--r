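test_that("superposition recovers exact rigid motions with zero RMSD", {
  X <- random_points(7, seed = 1)
  # identity: rotation = I, rmsd = 0
  id <- kabsch_superpose(X, X)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)
  expect_lt(id$rmsd, 1e-9)

  # 37-degree rotation about z plus translation (1,2,3)
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- sweep(X %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, Rz, tolerance = 1e-6)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-6)
})

test_that("RMSD is invariant under random proper rigid motions of either input", {
  for (seed in 1:10) {
    X <- random_points(6, seed = seed)
    Y <- random_points(6, seed = seed + 100)
    base <- kabsch_superpose(X, Y)$rmsd
    R <- random_rotation(seed + 200)
    t_vec <- with_seed_test(seed + 300, stats::rnorm(3, sd = 5))
    moved <- sweep(X %*% t(R), 2, t_vec, "+")
    expect_equal(kabsch_superpose(moved, Y)$rmsd, base, tolerance = 1e-6)
    movedY <- sweep(Y %*% t(R), 2, t_vec, "+")
    expect_equal(kabsch_superpose(X, movedY)$rmsd, base, tolerance = 1e-6)
    # symmetry after superposition
    expect_equal(kabsch_superpose(Y, X)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("the returned rotation is always proper (det +1, no reflections)", {
  for (seed in 1:10) {
    X <- random_points(5, seed = seed)
    Y <- random_points(5, seed = seed + 50)
    fit <- kabsch_superpose(X, Y)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
  # reflected target: best proper rotation must still have det +1
  X <- random_points(5, seed = 7)
  Yr <- X %*% diag(c(-1, 1, 1))
  expect_equal(det(kabsch_superpose(X, Yr)$rotation), 1, tolerance = 1e-8)
})

test_that("superposition never exceeds the brute-force rotation-grid minimum", {
  for (seed in 1:8) {
    n <- 4 + (seed %% 5)
    X <- random_points(n, seed = seed)
    Y <- random_points(n, seed = seed + 1000)
    kab <- kabsch_superpose(X, Y)$rmsd
    grid <- grid_min_rmsd(X, Y, step = 10)
    expect_lte(kab, grid + 1e-9)
    # 10-degree resolution: the grid comes close to the optimum
    expect_lt(grid - kab, 0.5)
  }
})

test_that("degenerate and undersized configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
  expect_error(kabsch_superpose(random_points(2, 1)[1:2, ],
                                random_points(2, 2)[1:2, ]), "at least 3")
})

test_that("superposition RMSD agrees with an independent implementation", {
  X <- random_points(20, seed = 21)
  Y <- random_points(20, seed = 22)
  ours <- kabsch_superpose(X, Y)$rmsd
  xyz_x <- as.numeric(t(X))
  xyz_y <- as.numeric(t(Y))
  theirs <- bio3d::rmsd(xyz_y, xyz_x, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("dual RMSD is zero against the matching reference and large against the other", {
  refs <- fixture_refs()
  d <- dual_rmsd(refs$ground, refs)
  expect_lt(d$rmsd_ground, 1e-6)
  expect_gt(d$rmsd_alt, 5)
  d2 <- dual_rmsd(refs$alternative, refs)
  expect_lt(d2$rmsd_alt, 1e-6)
  expect_gt(d2$rmsd_ground, 5)
  expect_gte(d$n_atoms, 3L)
})

test_that("interpolating toward the alternative reference decreases rmsd_alt monotonically", {
  refs <- fixture_refs()
  reg <- refs$region
  g <- extract_region(refs$ground, reg)
  a <- extract_region(refs$alternative, reg)
  ga <- map_atoms(g, a)
  # bring the alternative into the ground frame so the blend is pure shape
  sup <- kabsch_superpose(ga$Y, ga$X)
  Y_in_g <- sweep(ga$Y %*% t(sup$rotation), 2, sup$translation, "+")
  fracs <- seq(0, 1, by = 0.25)
  rmsds <- vapply(fracs, function(f) {
    m <- g
    m$atoms[, c("x", "y", "z")] <- (1 - f) * ga$X + f * Y_in_g
    dual_rmsd(m, refs)$rmsd_alt
  }, numeric(1))
  expect_true(all(diff(rmsds) < 0))
  expect_lt(rmsds[length(rmsds)], 1e-6)
})

test_that("reference pairs with mismatched region sequences are rejected", {
  refs <- fixture_refs()
  other <- make_fold_pair(40, seed = 99)
  expect_error(reference_pair(refs$ground, other$alternative, refs$region),
               "differ in sequence")
})
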