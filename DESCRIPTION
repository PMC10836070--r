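Package: foldswitchr
Title: Evaluation Pipeline for Predicted Ensembles of Fold-Switching Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate predicted structural ensembles of
    fold-switching (metamorphic) proteins against their two experimentally
    determined conformations. Provides MSA handling (FASTA/A3M parsing,
    density-based sequence clustering, shallow random subsampling, pairwise
    identity), rigid-body Kabsch superposition with dual-reference RMSD
    classification of predicted models using per-residue confidence (plDDT)
    thresholds, ensemble-level metrics (confusion counts, Matthews
    correlation coefficient, success rates, runs-per-ensemble accounting),
    and a synthetic-data generator that builds two-conformation reference
    pairs, calibrated decoy ensembles and two-subfamily alignments with
    known ground truth so the whole pipeline can be exercised without
    running a structure predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
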