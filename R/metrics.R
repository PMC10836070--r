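#' Confusion counts from paired predicted/observed decisions
#'
#' Standard 2x2 tally. The ensemble evaluation scores one decision per
#' (protein, conformation) pair: predicted = a confident accurate model of
#' that conformation exists; observed = the conformation is experimentally
#' confirmed.
#'
#' @param predicted,observed logical vectors of equal, positive length.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(predicted, observed) {
  predicted <- as.logical(predicted)
  observed <- as.logical(observed)
  if (length(predicted) == 0L) stop("no decisions to tally", call. = FALSE)
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  c(TP = sum(predicted & observed),
    FP = sum(predicted & !observed),
    TN = sum(!predicted & !observed),
    FN = sum(!predicted & observed))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' summary of a 2x2 confusion table in `[-1, 1]`. Conventions for the
#' degenerate (zero-marginal) tables the formula leaves undefined: an
#' error-free table (`FP = FN = 0` with at least one correct decision)
#' scores 1, a table with no correct decision scores -1, and any other
#' zero-marginal table scores 0 — so a perfect evaluation of a protein whose
#' observed conformations leave no negative decisions still reports 1.
#'
#' @param TP,FP,TN,FN non-negative counts (or a single named vector as
#'   returned by [confusion()] passed as `TP`).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L) {
    tab <- TP
    TP <- tab[["TP"]]; FP <- tab[["FP"]]; TN <- tab[["TN"]]; FN <- tab[["FN"]]
  }
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom2 == 0) {
    if (FP == 0 && FN == 0) return(1)
    if (TP == 0 && TN == 0) return(-1)
    return(0)
  }
  (TP * TN - FP * FN) / sqrt(denom2)
}

#' Ensemble success rate
#'
#' Percentage of models in an ensemble whose fold-switching region was
#' predicted accurately, reported both at full precision and at the printed
#' convention (nearest integer percent): 10 accurate out of 250 models is a
#' 4\% success rate; 5 out of 21 rounds to 24\%.
#'
#' @param n_accurate number of accurate models, `0 <= n_accurate <= n_models`.
#' @param n_models total number of models, positive.
#' @return object of class `success_rate`: list with `percent` (full
#'   precision), `percent_rounded` (integer), `formatted` (e.g. `"4%"`),
#'   `n_accurate`, `n_models`.
#' @export
success_rate <- function(n_accurate, n_models) {
  if (n_models <= 0) stop("`n_models` must be positive", call. = FALSE)
  if (n_accurate < 0 || n_accurate > n_models) {
    stop("`n_accurate` must lie in [0, n_models]", call. = FALSE)
  }
  pct <- 100 * n_accurate / n_models
  structure(list(percent = pct,
                 percent_rounded = as.integer(round(pct)),
                 formatted = sprintf("%d%%", as.integer(round(pct))),
                 n_accurate = as.integer(n_accurate),
                 n_models = as.integer(n_models)),
            class = "success_rate")
}

#' @export
print.success_rate <- function(x, ...) {
  cat(sprintf("success rate: %s (%d/%d, %.4g%% unrounded)\n",
              x$formatted, x$n_accurate, x$n_models, x$percent))
  invisible(x)
}

#' @export
format.success_rate <- function(x, ...) x$formatted

#' Runs contributing to an ensemble
#'
#' Counts the distinct prediction runs listed in an ensemble manifest.
#' Random-subsampling protocols need only 1-2 predictor runs per ensemble
#' while cluster-per-run protocols have needed 95-329; the count feeds the
#' efficiency comparison.
#'
#' @param manifest data.frame with a `run_id` column (one row per
#'   prediction), or a vector of run identifiers. Empty input counts 0 runs.
#' @return integer number of distinct runs.
#' @export
runs_accounting <- function(manifest) {
  ids <- if (is.data.frame(manifest)) {
    if (nrow(manifest) == 0L) character(0) else manifest$run_id
  } else {
    manifest
  }
  length(unique(ids))
}

#' Summarize an evaluated ensemble
#'
#' Combines per-model calls and the protein-level verdict into the ensemble
#' summary: confusion counts over the per-conformation decisions, MCC,
#' percent success (fraction of decisions correct), model-level success
#' rate, and run accounting.
#'
#' @param calls list of [classify_model()] results.
#' @param truth a [protein_truth].
#' @param runs number of distinct predictor runs behind the ensemble.
#' @param protein optional protein name carried into reports.
#' @param method optional method name (e.g. subsampling vs clustering).
#' @return object of class `ensemble_summary`.
#' @export
ensemble_summary <- function(calls, truth, runs = 1L, protein = NA_character_,
                             method = NA_character_) {
  pc <- call_protein(calls, truth)
  confs <- c("ground", "alternative")
  tab <- confusion(predicted = pc$predicted[confs],
                   observed = confs %in% truth$observed)
  n_models <- length(calls)
  n_accurate <- sum(vapply(calls, `[[`, logical(1), "accurate"))
  structure(list(protein = protein, method = method,
                 predicted = pc$predicted, verdict = pc$verdict,
                 false_positives = length(pc$false_positives),
                 TP = tab[["TP"]], FP = tab[["FP"]],
                 TN = tab[["TN"]], FN = tab[["FN"]],
                 mcc = mcc(tab),
                 percent_success = 100 * (tab[["TP"]] + tab[["TN"]]) / sum(tab),
                 success_rate = success_rate(n_accurate, n_models),
                 n_models = n_models, runs = as.integer(runs)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary%s: %d models, verdict %s\n",
              if (!is.na(x$protein)) paste0(" [", x$protein, "]") else "",
              x$n_models, x$verdict))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  |  MCC %.3f  %%success %.1f\n",
              x$TP, x$FP, x$TN, x$FN, x$mcc, x$percent_success))
  cat(sprintf("  model success rate %s (%d/%d), %d high-confidence FP, %d run(s)\n",
              x$success_rate$formatted, x$success_rate$n_accurate,
              x$success_rate$n_models, x$false_positives, x$runs))
  invisible(x)
}
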