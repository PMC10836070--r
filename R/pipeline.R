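#' Evaluation run configuration
#'
#' Declarative description of one protein's evaluation: where the two
#' experimental references live, the fold-switching region, which
#' conformations are experimentally confirmed, and the thresholds. Can be
#' built directly or loaded from a YAML file with [read_run_config()].
#' Unknown fields are rejected (fail fast). The per-protein subsampling
#' presets follow the benchmark depths: `max_seq` 1 for KaiB, 8 for Mad2,
#' 64 for RfaH, each with `max_extra_seq = 2 * max_seq`.
#'
#' @param protein protein name.
#' @param ref_ground,ref_alt paths to the two reference PDB files (or
#'   [structure_model]s directly).
#' @param region fold-switching residue interval `c(from, to)`.
#' @param truth character subset of `c("ground", "alternative")`.
#' @param thresholds a [classification_thresholds].
#' @param atom_mode `"all_heavy"` or `"ca_only"`.
#' @param subsample optional [subsample_spec].
#' @param method label for the prediction protocol being evaluated.
#' @return object of class `run_config`.
#' @export
run_config <- function(protein, ref_ground, ref_alt, region, truth,
                       thresholds = classification_thresholds(),
                       atom_mode = c("all_heavy", "ca_only"),
                       subsample = NULL, method = NA_character_) {
  atom_mode <- match.arg(atom_mode)
  load_ref <- function(r) {
    if (inherits(r, "structure_model")) return(r)
    if (!file.exists(r)) stop("reference file not found: ", r, call. = FALSE)
    read_model(r)
  }
  refs <- reference_pair(load_ref(ref_ground), load_ref(ref_alt), region)
  structure(list(protein = protein, refs = refs,
                 truth = protein_truth(truth),
                 thresholds = thresholds, atom_mode = atom_mode,
                 subsample = subsample, method = method),
            class = "run_config")
}

#' Per-protein subsampling presets
#'
#' @param protein one of `"KaiB"`, `"Mad2"`, `"RfaH"`.
#' @param seed seed for the subsampling draw.
#' @return a [subsample_spec] with the benchmark depth for that protein.
#' @export
preset_subsample <- function(protein = c("KaiB", "Mad2", "RfaH"), seed = 0L) {
  protein <- match.arg(protein)
  max_seq <- c(KaiB = 1L, Mad2 = 8L, RfaH = 64L)[[protein]]
  subsample_spec(max_seq = max_seq, seed = seed)
}

#' Read a run configuration from YAML
#'
#' Expected keys: `protein`, `ref_ground`, `ref_alt`, `region` (two
#' integers), `truth`, and optionally `thresholds` (named list),
#' `atom_mode`, `method`. Any other key is an error.
#'
#' @param path YAML file.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("protein", "ref_ground", "ref_alt", "region", "truth",
               "thresholds", "atom_mode", "method")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  th <- if (is.null(cfg$thresholds)) classification_thresholds()
        else do.call(classification_thresholds, cfg$thresholds)
  run_config(protein = cfg$protein, ref_ground = cfg$ref_ground,
             ref_alt = cfg$ref_alt, region = as.integer(unlist(cfg$region)),
             truth = unlist(cfg$truth), thresholds = th,
             atom_mode = cfg$atom_mode %||% "all_heavy",
             method = cfg$method %||% NA_character_)
}

#' Evaluate a directory of predicted models
#'
#' Reads every PDB in `models`, computes dual-reference RMSDs over the
#' fold-switching region, classifies each model, and summarizes the
#' ensemble. If the directory contains a `manifest.json` (as written by
#' [make_ensemble()]) its run ids feed the run accounting; otherwise `runs`
#' applies. Unreadable models are skipped with a warning; reports are
#' written deterministically so identical inputs give byte-identical
#' outputs.
#'
#' @param config a [run_config].
#' @param models directory containing model PDB files.
#' @param out_dir optional directory for reports: `per_model.tsv` (one row
#'   per model: file, rmsd_ground, rmsd_alt, plddt, label, accurate,
#'   high_confidence) and `ensemble.json` (the summary).
#' @param runs run count to use when no manifest is present.
#' @return list with `summary` (an `ensemble_summary`), `per_model`
#'   (data.frame) and `calls`.
#' @export
run_evaluation <- function(config, models, out_dir = NULL, runs = 1L) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(models)) stop("model directory not found: ", models,
                                call. = FALSE)
  files <- sort(list.files(models, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) == 0L) stop("no PDB models in ", models, call. = FALSE)
  manifest_path <- file.path(models, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    runs <- runs_accounting(man)
  }
  calls <- list()
  rows <- list()
  for (f in files) {
    res <- tryCatch({
      m <- read_model(f)
      d <- dual_rmsd(m, config$refs, atom_mode = config$atom_mode)
      p <- mean_plddt(m, config$refs$region)
      classify_model(d, p, config$thresholds)
    }, error = function(e) {
      warning("skipping unreadable model ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    calls[[length(calls) + 1L]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f),
      rmsd_ground = res$dual$rmsd_ground,
      rmsd_alt = res$dual$rmsd_alt,
      plddt = res$plddt,
      label = res$label,
      accurate = res$accurate,
      high_confidence = res$high_confidence,
      stringsAsFactors = FALSE
    )
  }
  if (length(calls) == 0L) stop("no readable models in ", models, call. = FALSE)
  per_model <- do.call(rbind, rows)
  summ <- ensemble_summary(calls, config$truth, runs = runs,
                           protein = config$protein, method = config$method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- per_model
    for (col in c("rmsd_ground", "rmsd_alt", "plddt")) {
      tsv[[col]] <- sprintf("%.4f", tsv[[col]])
    }
    utils::write.table(tsv, file.path(out_dir, "per_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary_as_list(summ),
                         file.path(out_dir, "ensemble.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summ, per_model = per_model, calls = calls)
}

summary_as_list <- function(s) {
  list(protein = s$protein, method = s$method, verdict = s$verdict,
       predicted = as.list(s$predicted),
       confusion = list(TP = s$TP, FP = s$FP, TN = s$TN, FN = s$FN),
       mcc = s$mcc, percent_success = s$percent_success,
       success_rate_percent = s$success_rate$percent,
       success_rate = s$success_rate$formatted,
       n_accurate = s$success_rate$n_accurate,
       n_models = s$n_models,
       high_confidence_false_positives = s$false_positives,
       runs = s$runs)
}

#' Compare evaluated ensembles across methods
#'
#' Side-by-side table of MCC, percent success, model success rate and run
#' counts for two or more ensemble summaries of the same protein set — the
#' accuracy-and-efficiency comparison between prediction protocols (e.g. a
#' random-subsampling ensemble built from 1-2 predictor runs against a
#' cluster-per-run ensemble built from hundreds).
#'
#' @param summaries list of >= 2 `ensemble_summary` objects covering
#'   identical protein sets.
#' @param out optional path to write the table as TSV.
#' @return data.frame with one row per (protein, method) and an
#'   `efficiency_ratio` column (runs relative to the cheapest method for
#'   that protein).
#' @export
compare_methods <- function(summaries, out = NULL) {
  if (length(summaries) < 2L) {
    stop("need at least two summaries to compare", call. = FALSE)
  }
  stopifnot(all(vapply(summaries, inherits, logical(1), "ensemble_summary")))
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(protein = s$protein, method = s$method, mcc = s$mcc,
               percent_success = s$percent_success,
               success_rate_percent = s$success_rate$percent,
               false_positives = s$false_positives,
               n_models = s$n_models, runs = s$runs,
               stringsAsFactors = FALSE)
  }))
  prot_by_method <- lapply(split(tab$protein, tab$method), sort)
  if (length(unique(prot_by_method)) != 1L) {
    stop("summaries do not cover identical protein sets", call. = FALSE)
  }
  by_prot <- split(seq_len(nrow(tab)), tab$protein)
  tab$efficiency_ratio <- NA_real_
  for (idx in by_prot) {
    tab$efficiency_ratio[idx] <- tab$runs[idx] / min(tab$runs[idx])
  }
  if (!is.null(out)) {
    tsv <- tab
    for (col in c("mcc", "percent_success", "success_rate_percent",
                  "efficiency_ratio")) {
      tsv[[col]] <- sprintf("%.4f", tsv[[col]])
    }
    utils::write.table(tsv, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
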