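#' Classification thresholds for dual-reference evaluation
#'
#' Defaults follow the published evaluation of fold-switching ensembles: a
#' model is *accurate* when its fold-switching region lies within 3 Angstrom
#' of either experimental conformation and its average confidence is at
#' least 55; a model is *high-confidence* at plDDT >= 70 (the level at which
#' a wrong conformation counts as a high-confidence false positive); models
#' beyond 5 Angstrom of experiment are considered poor.
#'
#' @param accurate_rmsd RMSD cutoff (Angstrom) for an accurate model.
#' @param accurate_plddt minimum mean plDDT for an accurate model.
#' @param high_conf_plddt plDDT at or above which a model is high-confidence.
#' @param poor_rmsd RMSD (Angstrom) above which a model is flagged poor.
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(accurate_rmsd = 3.0,
                                      accurate_plddt = 55,
                                      high_conf_plddt = 70,
                                      poor_rmsd = 5.0) {
  stopifnot(accurate_rmsd > 0, poor_rmsd > 0, accurate_rmsd < poor_rmsd,
            accurate_plddt >= 0, accurate_plddt <= 100,
            high_conf_plddt >= 0, high_conf_plddt <= 100)
  structure(list(accurate_rmsd = accurate_rmsd,
                 accurate_plddt = accurate_plddt,
                 high_conf_plddt = high_conf_plddt,
                 poor_rmsd = poor_rmsd),
            class = "classification_thresholds")
}

#' Classify a model against the two reference conformations
#'
#' The model is labelled with the conformation of smaller RMSD provided that
#' RMSD is within `accurate_rmsd`, otherwise `"neither"`; exact RMSD ties
#' are broken toward ground with a warning. `accurate` additionally requires
#' mean plDDT at or above `accurate_plddt`; `high_confidence` is plDDT at or
#' above `high_conf_plddt` regardless of geometry (a high-confidence model
#' of the wrong conformation is the false-positive signature).
#'
#' @param dual a [dual_rmsd].
#' @param plddt mean plDDT over the scored region.
#' @param th a [classification_thresholds].
#' @return object of class `conformation_call`: list with `label` (one of
#'   `"ground"`, `"alternative"`, `"neither"`), `accurate`,
#'   `high_confidence`, `dual`, `plddt`.
#' @export
classify_model <- function(dual, plddt, th = classification_thresholds()) {
  stopifnot(inherits(dual, "dual_rmsd"),
            inherits(th, "classification_thresholds"))
  if (dual$rmsd_ground == dual$rmsd_alt && dual$rmsd_ground <= th$accurate_rmsd) {
    warning("equal RMSD to both references; tie broken toward ground",
            call. = FALSE)
  }
  best <- if (dual$rmsd_ground <= dual$rmsd_alt) "ground" else "alternative"
  best_rmsd <- min(dual$rmsd_ground, dual$rmsd_alt)
  label <- if (best_rmsd <= th$accurate_rmsd) best else "neither"
  structure(list(label = label,
                 accurate = label != "neither" && plddt >= th$accurate_plddt,
                 high_confidence = plddt >= th$high_conf_plddt,
                 dual = dual, plddt = plddt),
            class = "conformation_call")
}

#' @export
print.conformation_call <- function(x, ...) {
  cat(sprintf("conformation_call: %s (rmsd_g %.2f, rmsd_a %.2f, plDDT %.1f)%s%s\n",
              x$label, x$dual$rmsd_ground, x$dual$rmsd_alt, x$plddt,
              if (x$accurate) " [accurate]" else "",
              if (x$high_confidence) " [high-confidence]" else ""))
  invisible(x)
}

#' Experimentally confirmed conformations of a protein
#'
#' @param observed non-empty subset of `c("ground", "alternative")`: the
#'   conformations with experimental support. A metamorphic protein has
#'   both; a single folder exactly one.
#' @return object of class `protein_truth`.
#' @export
protein_truth <- function(observed) {
  observed <- match.arg(observed, c("ground", "alternative"),
                        several.ok = TRUE)
  structure(list(observed = unique(observed)), class = "protein_truth")
}

#' High-confidence false positives in a set of calls
#'
#' Returns every call with `high_confidence = TRUE` whose label is
#' `"neither"` (confident model matching no experimental conformation, e.g.
#' a hybrid artifact) or whose label names a conformation without
#' experimental support (the single-folder-mispredicted-as-metamorphic
#' signature).
#'
#' @param calls non-empty list of [classify_model()] results.
#' @param truth a [protein_truth].
#' @return list of flagged `conformation_call`s (possibly empty).
#' @export
detect_false_positives <- function(calls, truth) {
  stopifnot(inherits(truth, "protein_truth"))
  if (length(calls) == 0L) stop("`calls` must be non-empty", call. = FALSE)
  Filter(function(cl) {
    cl$high_confidence &&
      (cl$label == "neither" || !(cl$label %in% truth$observed))
  }, calls)
}

#' Metamorphic / single-folder verdict for a protein
#'
#' A conformation counts as *predicted* when at least one call carries its
#' label with `accurate = TRUE` and `high_confidence = TRUE`. The protein is
#' called metamorphic when both conformations are predicted, single-folder
#' when exactly one is, and undetermined when neither is. High-confidence
#' false positives (per [detect_false_positives()]) are reported alongside.
#'
#' @param calls non-empty list of [classify_model()] results.
#' @param truth a [protein_truth].
#' @return object of class `protein_call`: list with `predicted` (named
#'   logical for ground/alternative), `verdict` (`"metamorphic"`,
#'   `"single-folder"` or `"undetermined"`), `false_positives`, and
#'   `correct` (whether predicted conformations equal the observed set).
#' @export
call_protein <- function(calls, truth) {
  stopifnot(inherits(truth, "protein_truth"))
  if (length(calls) == 0L) stop("`calls` must be non-empty", call. = FALSE)
  predicted <- vapply(c(ground = "ground", alternative = "alternative"),
                      function(conf) {
                        any(vapply(calls, function(cl) {
                          cl$label == conf && cl$accurate && cl$high_confidence
                        }, logical(1)))
                      }, logical(1))
  verdict <- if (all(predicted)) "metamorphic"
             else if (any(predicted)) "single-folder"
             else "undetermined"
  fps <- detect_false_positives(calls, truth)
  correct <- setequal(names(predicted)[predicted], truth$observed)
  structure(list(predicted = predicted, verdict = verdict,
                 false_positives = fps, correct = correct, truth = truth),
            class = "protein_call")
}

#' @export
print.protein_call <- function(x, ...) {
  cat(sprintf("protein_call: %s (predicted: %s; observed: %s; %d high-confidence FP)\n",
              x$verdict,
              paste(names(x$predicted)[x$predicted], collapse = "+") %0% "none",
              paste(x$truth$observed, collapse = "+"),
              length(x$false_positives)))
  invisible(x)
}

`%0%` <- function(a, b) if (nzchar(a)) a else b
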