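test_that("ideal helical dihedrals give the canonical CA-CA spacing", {
  h <- build_chain(strrep("A", 20), phi = -57, psi = -47)
  ca <- as.matrix(h$atoms[h$atoms$elety == "CA", c("x", "y", "z")])
  d_ca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d_ca - 3.8) < 0.1))
  expect_equal(nrow(h$atoms), 20L * 4L) # N, CA, C, O per residue
})

test_that("strand dihedrals extend the chain relative to a helix", {
  h <- build_chain(strrep("A", 20), -57, -47)
  s <- build_chain(strrep("A", 20), -139, 135)
  skip2 <- function(m) {
    ca <- as.matrix(m$atoms[m$atoms$elety == "CA", c("x", "y", "z")])
    mean(sqrt(rowSums((ca[-(1:2), ] - ca[seq_len(nrow(ca) - 2), ])^2)))
  }
  expect_gt(skip2(s), skip2(h))
})

test_that("chain construction validates its inputs", {
  expect_error(build_chain("AC", -57, -47), "at least 4")
  expect_error(build_chain("ACDB", -57, -47), "unknown residue")
})

test_that("fold pairs are well separated over the region and share a sequence", {
  refs <- make_fold_pair(40, seed = 1)
  pr <- map_atoms(extract_region(refs$ground, refs$region),
                  extract_region(refs$alternative, refs$region))
  expect_gt(kabsch_superpose(pr$X, pr$Y)$rmsd, 5)
  expect_error(make_fold_pair(40, seed = 1, min_separation = 1e6),
               "not separable")
  expect_error(make_fold_pair(10), ">= 20")
  expect_error(make_fold_pair(40, region = c(50, 60)), "inside")
})

test_that("decoys at target 0 reproduce the base conformer exactly", {
  refs <- fixture_refs()
  d <- make_decoy(refs, decoy_spec("ground", target_rmsd = 0, plddt = 91))
  expect_equal(d$atoms[, c("x", "y", "z")],
               refs$ground$atoms[, c("x", "y", "z")])
  expect_equal(unname(d$plddt), rep(91, 40))
  expect_lt(dual_rmsd(d, refs)$rmsd_ground, 1e-9)
})

test_that("decoy noise is deterministic per seed", {
  refs <- fixture_refs()
  a <- make_decoy(refs, decoy_spec("alternative", 2, seed = 5))
  b <- make_decoy(refs, decoy_spec("alternative", 2, seed = 5))
  expect_identical(a$atoms, b$atoms)
  c <- make_decoy(refs, decoy_spec("alternative", 2, seed = 6))
  expect_false(identical(a$atoms, c$atoms))
})

test_that("achieved decoy RMSD tracks the target within 10 percent", {
  refs <- fixture_refs()
  for (target in c(2, 4)) {
    achieved <- vapply(1:30, function(seed) {
      d <- make_decoy(refs, decoy_spec("ground", target, seed = seed))
      dual_rmsd(d, refs)$rmsd_ground
    }, numeric(1))
    expect_lt(abs(mean(achieved) - target) / target, 0.10)
  }
})

test_that("hybrid decoys sit far from both references", {
  refs <- fixture_refs()
  mid <- floor(mean(refs$region))
  h <- make_decoy(refs, decoy_spec("hybrid", 0, hybrid_split = mid, seed = 1))
  d <- dual_rmsd(h, refs)
  expect_gt(d$rmsd_ground, 3)
  expect_gt(d$rmsd_alt, 3)
  expect_error(decoy_spec("hybrid", 0), "hybrid_split")
  expect_error(make_decoy(refs, decoy_spec("hybrid", 0, hybrid_split = 1)),
               "inside the chain")
})

test_that("ensembles are written with a faithful manifest and round-trip", {
  refs <- fixture_refs()
  dir <- withr::local_tempdir()
  specs <- c(
    lapply(1:4, function(s) decoy_spec("ground", 1, plddt = 85, seed = s)),
    lapply(5:8, function(s) decoy_spec("alternative", 1, plddt = 85, seed = s)),
    list(decoy_spec("hybrid", 0, plddt = 85, seed = 9,
                    hybrid_split = floor(mean(refs$region)))))
  man <- make_ensemble(refs, specs, dir)
  expect_equal(nrow(man), 9L)
  expect_length(list.files(dir, pattern = "\\.pdb$"), 9L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # read back and classify: generator labels recovered at these wide margins
  for (i in seq_len(nrow(man))) {
    m <- read_model(file.path(dir, man$file[i]))
    cl <- classify_model(dual_rmsd(m, refs), mean_plddt(m, refs$region))
    expected <- if (man$base[i] == "hybrid") "neither" else man$base[i]
    expect_equal(cl$label, expected)
  }
  expect_error(make_ensemble(refs, list(), withr::local_tempdir()),
               "non-empty")
})

test_that("msa generation honours its rates and determinism", {
  # zero mutation rate: every member equals its founder
  aln0 <- synth_msa(msa_spec(5, 30, mutation_rate = 0, seed = 2))
  expect_equal(length(unique(aln0$rows[1:6])), 1L) # query + subfamily A
  expect_equal(length(unique(aln0$rows[7:11])), 1L) # subfamily B
  expect_false(aln0$rows[1] == aln0$rows[7])

  # intra-subfamily identity exceeds inter-subfamily identity
  intra <- inter <- numeric(0)
  for (seed in 1:5) {
    aln <- synth_msa(msa_spec(6, 50, founder_divergence = 0.6,
                              mutation_rate = 0.05, seed = seed))
    rows <- aln$rows
    intra <- c(intra, pairwise_identity(rows[2], rows[3]),
               pairwise_identity(rows[8], rows[9]))
    inter <- c(inter, pairwise_identity(rows[2], rows[8]))
  }
  expect_gt(mean(intra), mean(inter))
  expect_gt(mean(intra), 0.85) # ~ (1 - rate)^2 at rate 0.05
  expect_lt(mean(inter), 0.55) # founders 60% divergent

  expect_identical(synth_msa(msa_spec(4, 20, seed = 3)),
                   synth_msa(msa_spec(4, 20, seed = 3)))
  expect_error(msa_spec(3, 20, founder_divergence = 1.2), "\\[0, 1\\]")
  expect_error(msa_spec(0, 20), ">= 1")
})

test_that("one member per subfamily leaves the density clusterer with only noise", {
  aln <- synth_msa(msa_spec(1, 30, seed = 4))
  res <- cluster_sequences(aln, eps = 0.3, min_samples = 3L)
  expect_true(all(res$labels == -1L))
})
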