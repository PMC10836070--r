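# build a dual_rmsd without geometry, for threshold-logic tests
fake_dual <- function(g, a) {
  structure(list(rmsd_ground = g, rmsd_alt = a, n_atoms = 100L,
                 atom_mode = "all_heavy"),
            class = "dual_rmsd")
}

test_that("models are classified by nearest reference within the accuracy cutoff", {
  th <- classification_thresholds()
  c1 <- classify_model(fake_dual(1.0, 9.0), plddt = 80, th)
  expect_equal(c1$label, "ground")
  expect_true(c1$accurate)
  expect_true(c1$high_confidence)

  # geometry fine but confidence below 55: not accurate
  c2 <- classify_model(fake_dual(2.0, 8.0), plddt = 50, th)
  expect_equal(c2$label, "ground")
  expect_false(c2$accurate)
  expect_false(c2$high_confidence)

  # hybrid-like: close to neither reference, yet confident
  c3 <- classify_model(fake_dual(6.0, 6.5), plddt = 85, th)
  expect_equal(c3$label, "neither")
  expect_false(c3$accurate)
  expect_true(c3$high_confidence)

  # boundary: exactly 3 A and exactly 55 still count as accurate
  c4 <- classify_model(fake_dual(3.0, 9.0), plddt = 55, th)
  expect_true(c4$accurate)
})

test_that("RMSD ties are broken toward ground with a warning", {
  expect_warning(tie <- classify_model(fake_dual(2.5, 2.5), plddt = 80),
                 "tie")
  expect_equal(tie$label, "ground")
})

test_that("classification is monotone in rmsd_ground", {
  th <- classification_thresholds()
  for (seed in 1:20) {
    vals <- with_seed_test(seed, sort(stats::runif(2, 0, 10)))
    a_rmsd <- with_seed_test(seed + 40, stats::runif(1, 0, 10))
    hi <- suppressWarnings(classify_model(fake_dual(vals[2], a_rmsd), 80, th))
    lo <- suppressWarnings(classify_model(fake_dual(vals[1], a_rmsd), 80, th))
    # lowering rmsd_ground never moves the label away from ground
    if (hi$label == "ground") expect_equal(lo$label, "ground")
    if (lo$label == "alternative") expect_equal(hi$label, "alternative")
  }
})

test_that("high-confidence false positives are detected against the truth set", {
  th <- classification_thresholds()
  # confident model of an experimentally unobserved conformation is flagged
  tv4_like <- classify_model(fake_dual(1.5, 8.0), plddt = 75, th)
  fps <- detect_false_positives(list(tv4_like), protein_truth("alternative"))
  expect_length(fps, 1L)

  # all-accurate calls on a metamorphic protein: nothing flagged
  ok <- list(classify_model(fake_dual(1.0, 9.0), 80, th),
             classify_model(fake_dual(9.0, 1.0), 80, th))
  expect_length(detect_false_positives(ok, protein_truth(c("ground", "alternative"))), 0L)

  # confident model matching neither reference is flagged regardless of truth
  hybrid <- classify_model(fake_dual(7.0, 7.0), plddt = 90, th)
  expect_length(detect_false_positives(list(hybrid),
                                       protein_truth(c("ground", "alternative"))), 1L)

  # a low-confidence wrong model is not a *high-confidence* false positive
  meek <- classify_model(fake_dual(1.5, 8.0), plddt = 60, th)
  expect_length(detect_false_positives(list(meek), protein_truth("alternative")), 0L)

  expect_error(detect_false_positives(list(), protein_truth("ground")),
               "non-empty")
})

test_that("protein verdicts follow confident accurate coverage of the conformations", {
  th <- classification_thresholds()
  g <- classify_model(fake_dual(1.0, 9.0), 80, th)
  a <- classify_model(fake_dual(9.0, 1.0), 80, th)
  both <- call_protein(list(g, a, g), protein_truth(c("ground", "alternative")))
  expect_equal(both$verdict, "metamorphic")
  expect_true(both$correct)

  only_g <- call_protein(list(g, g), protein_truth("ground"))
  expect_equal(only_g$verdict, "single-folder")
  expect_true(only_g$correct)

  # single folder mispredicted as metamorphic: verdict + FP flag together
  wrong <- call_protein(list(g, a), protein_truth("alternative"))
  expect_equal(wrong$verdict, "metamorphic")
  expect_false(wrong$correct)
  expect_length(wrong$false_positives, 1L)

  # accurate but low-confidence models do not establish a conformation
  g_low <- classify_model(fake_dual(1.0, 9.0), 60, th)
  und <- call_protein(list(g_low), protein_truth("ground"))
  expect_equal(und$verdict, "undetermined")
  expect_error(call_protein(list(), protein_truth("ground")), "non-empty")
})

test_that("confusion tallies the 2x2 table of decisions", {
  expect_equal(confusion(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)),
               c(TP = 2L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(confusion(TRUE, FALSE), c(TP = 0L, FP = 1L, TN = 0L, FN = 0L))
  expect_equal(confusion(c(FALSE, TRUE), c(TRUE, TRUE))[["FN"]], 1L)
  expect_error(confusion(logical(0), logical(0)), "no decisions")
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("MCC matches the closed form and its conventions", {
  expect_equal(mcc(TP = 2, FP = 0, TN = 2, FN = 0), 1.0)
  expect_equal(mcc(TP = 1, FP = 1, TN = 1, FN = 1), 0.0)
  # independent evaluation of the closed form for a fixed table
  expect_equal(mcc(TP = 5, FP = 1, TN = 3, FN = 2),
               (5 * 3 - 1 * 2) / sqrt((5 + 1) * (5 + 2) * (3 + 1) * (3 + 2)))
  expect_equal(round(mcc(TP = 5, FP = 1, TN = 3, FN = 2), 4), 0.4485)
  # degenerate-table conventions: error-free -> 1, no-correct -> -1, else 0
  expect_equal(mcc(TP = 0, FP = 0, TN = 3, FN = 2), 0)
  expect_equal(mcc(TP = 2, FP = 0, TN = 0, FN = 0), 1)
  expect_equal(mcc(TP = 0, FP = 2, TN = 0, FN = 0), -1)
  expect_equal(mcc(confusion(c(TRUE, FALSE), c(TRUE, FALSE))), 1.0)
})

test_that("MCC stays in [-1, 1] and is class-swap symmetric", {
  for (seed in 1:25) {
    tab <- with_seed_test(seed, stats::rpois(4, 5))
    if (sum(tab) == 0) next
    v <- mcc(tab[1], tab[2], tab[3], tab[4])
    expect_gte(v, -1)
    expect_lte(v, 1)
    expect_equal(v, mcc(tab[3], tab[4], tab[1], tab[2])) # swap classes
  }
  expect_equal(mcc(TP = 0, FP = 3, TN = 0, FN = 3), -1)
})

test_that("success rates follow the printed rounding convention", {
  s1 <- success_rate(10, 250)
  expect_equal(s1$percent, 4.0)
  expect_equal(s1$formatted, "4%")
  s2 <- success_rate(5, 21)
  expect_equal(s2$percent, 100 * 5 / 21, tolerance = 1e-12)
  expect_equal(s2$percent_rounded, 24L)
  expect_equal(s2$formatted, "24%")
  expect_equal(success_rate(0, 100)$percent, 0)
  expect_error(success_rate(1, 0), "positive")
  expect_error(success_rate(5, 4), "\\[0, n_models\\]")
})

test_that("run accounting counts distinct runs", {
  expect_equal(runs_accounting(data.frame(run_id = c("r1", "r2"))), 2L)
  expect_equal(runs_accounting(data.frame(run_id = character(0))), 0L)
  expect_equal(runs_accounting(c("a", "a", "b")), 2L)
  expect_equal(runs_accounting(data.frame()), 0L)
})
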