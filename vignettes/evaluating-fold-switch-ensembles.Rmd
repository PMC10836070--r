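---
title: "Evaluating predicted ensembles of fold-switching proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted ensembles of fold-switching proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldswitchr)
```

## The problem

Fold-switching (metamorphic) proteins — KaiB, RfaH's C-terminal domain,
Mad2 — remodel their secondary and tertiary structure between two distinct,
experimentally determined folds. A structure predictor run in its default
configuration returns the dominant fold; two families of protocols coax it
into sampling the alternative fold as well:

* **sequence clustering**: cluster the multiple sequence alignment (MSA) by
  sequence similarity and predict once per cluster;
* **random subsampling**: predict from shallow, uniformly subsampled MSAs
  (depths of order 1-64 cluster sequences, with twice as many extra
  sequences).

Comparing such protocols fairly requires a fixed evaluation pipeline: given
a directory of predicted models carrying per-residue confidences (plDDT in
the PDB B-factor column) and the two reference conformations, classify each
model, decide whether the protein looks metamorphic or single-folding, flag
high-confidence false positives, and summarize ensembles with comparable
statistics. `foldswitchr` implements that pipeline, together with a
synthetic-data generator so every stage is testable with known ground truth
and without running a predictor.

## Dual-reference classification

For each model the fold-switching region is extracted, superposed
independently onto the same region of each reference with a Kabsch
least-squares fit (proper rotations only; reflections are never admitted),
and two all-heavy-atom RMSDs are recorded. The classification rule, with
default thresholds:

* the model is labelled with the nearer reference if that RMSD is at most
  `accurate_rmsd` = 3 Å, otherwise *neither*; an exact tie is broken toward
  the ground state with a warning;
* *accurate* additionally requires the mean plDDT over the region to be at
  least `accurate_plddt` = 55;
* *high-confidence* means plDDT ≥ `high_conf_plddt` = 70, regardless of
  geometry — a high-confidence model of a conformation without experimental
  support, or of neither conformation (e.g. a hybrid helix/sheet artifact),
  is a *high-confidence false positive*;
* RMSD beyond `poor_rmsd` = 5 Å marks a model as poor in reports.

Two open choices are made explicit and exposed as flags. The superposition
is fitted on the fold-switching region only (`fit_whole = TRUE` fits on the
whole shared chain and still scores the region); and the confidence entering
the accuracy rule is averaged over the region (a whole-model mean is
available through `mean_plddt(m)`). All-heavy-atom matching intersects atom
names within paired residues, so backbone-only models and side-chain
mismatches in mutants degrade gracefully; `atom_mode = "ca_only"` is the
deliberate fallback for mutant comparisons.

## From calls to verdicts and ensemble statistics

A conformation counts as **predicted** when at least one model carries its
label with both the accurate and high-confidence flags. Both conformations
predicted → *metamorphic*; exactly one → *single-folder*; none →
*undetermined*. This reproduces the two failure modes the evaluation is
designed to expose: a confident accurate model of an experimentally
unobserved conformation makes a single folder look metamorphic, and is
flagged as a false positive at the same time.

Ensembles are scored on one decision per (protein, conformation) pair:
predicted as above, observed when the conformation is experimentally
confirmed. From the resulting 2×2 table the package reports TP/FP/TN/FN,
the Matthews correlation coefficient, `%success` = (TP+TN)/total, the
model-level success rate (accurate models / all models, all models in the
denominator), and the number of distinct predictor runs behind the ensemble.
Per-model units for the confusion table are possible by calling
`confusion()` directly on per-model decisions. The success rate is reported
both at full precision and rounded to the nearest integer percent, the
convention under which 10/250 prints as `4%` and 5/21 as `24%`.

The MCC needs a convention for degenerate tables: when a protein's observed
set leaves no negative decisions (both conformations confirmed), a perfect
evaluation yields TP = 2, TN = FP = FN = 0 and the closed form is 0/0. We
score an error-free table as 1, a table with no correct decision as −1, and
any other zero-marginal table as 0. This keeps "perfect ensemble → MCC 1"
true for metamorphic proteins while leaving mixed degenerate tables at the
conservative 0.

## MSA handling

A3M input is normalized by deleting lowercase characters, the standard
convention for insertions relative to the query; the query row then defines
the column space and all rows have equal length. Pairwise identity divides
matches by columns ungapped in *both* sequences, so deletions do not dilute
identity; the function is symmetric and equals 1 on any gap-free
self-comparison.

Sequence clustering uses density-based (DBSCAN) semantics on the fractional
Hamming distance between rows — the fraction of columns at which two rows
differ, a monotone transform of the Euclidean distance between their
one-hot encodings, so `eps` lives on the interpretable [0, 1] scale.
`min_samples` defaults to 3. Because no canonical radius exists for
arbitrary alignments, `scan_eps()` scans a user-supplied grid and keeps the
radius maximizing the number of clusters with at least `min_samples`
members, breaking ties toward the fewest noise points and then the smaller
radius; the tie-break matters because a too-small radius can fragment a
subfamily into the same number of micro-clusters while labelling most rows
noise.

Random subsampling keeps the query first and draws
`max_seq + max_extra_seq − 1` further rows uniformly **without**
replacement (the with/without choice is not prescribed anywhere; without
replacement matches a subsampled-alignment file handed to a predictor,
which contains each sequence at most once). Every stochastic operation
takes an explicit integer seed and restores the caller's RNG state; there
is no hidden global randomness, which is what makes byte-identical report
reruns possible.

## What the synthetic generator emulates

`make_fold_pair()` builds one sequence twice from backbone dihedrals by
sequential internal-coordinate construction (ideal bond lengths N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; trans peptides): a helical hairpin over
the fold-switching region versus an extended strand hairpin, i.e. the
α→β character of real fold switches. Construction verifies the two
conformers are separated by more than 5 Å RMSD over the region and fails
otherwise. Chains carry backbone atoms only (N, CA, C, O): side chains add
nothing to the logic under test, and the atom-name intersection in the
mapper makes backbone-only models first-class citizens.

`make_decoy()` perturbs a base conformer with i.i.d. Gaussian noise of
per-coordinate σ = target/√3, from E[RMSD²] = 3σ²; the small shrinkage
introduced by re-superposition is absorbed by the 10% calibration
tolerance, and measured mean error at targets 1–8 Å is ~1%. Hybrid decoys
splice ground coordinates before a split residue with alternative
coordinates after it, rigidly re-joined over the three junction residues —
the part-helix/part-sheet artifact class. plDDT profiles are written to the
B-factor column exactly as prediction software does.

`synth_msa()` plants two subfamilies: founders differing at
⌈divergence × length⌉ positions (default 0.6), members mutating each
position with probability 0.05 to a uniformly chosen other residue. At
those defaults intra-subfamily distances concentrate near
1 − (1 − 0.05)² ≈ 0.1 and inter-subfamily distances near 0.6, so any radius
between the modes (the tests use 0.3) recovers the planted labels with
adjusted Rand index 1. What the generator deliberately does *not* emulate:
phylogenetic correlation within subfamilies, gaps and alignment errors,
physically relaxed decoys (no Ramachandran sampling beyond the two dihedral
sets, no clash relief), or any dependence of plDDT on model quality — so
green tests demonstrate that the *evaluation machinery* is correct, not
that any predictor is accurate on real proteins.

## Worked example

```{r example}
refs <- make_fold_pair(40, seed = 1)
models <- file.path(tempdir(), "models")
specs <- c(
  lapply(1:6, function(s) decoy_spec("ground", 1.5, plddt = 85, seed = s)),
  lapply(7:12, function(s) decoy_spec("alternative", 1.5, plddt = 85, seed = s)),
  list(decoy_spec("hybrid", 0, plddt = 80, seed = 13, hybrid_split = 30)))
make_ensemble(refs, specs, models)

cfg <- run_config("synthetic", refs$ground, refs$alternative, refs$region,
                  truth = c("ground", "alternative"), method = "subsample")
res <- run_evaluation(cfg, models)
res$summary
head(res$per_model, 3)
```

The hybrid decoy lands beyond 3 Å of both references but carries plDDT 80,
so it appears as one high-confidence false positive without changing the
per-conformation decisions.

## Numerical choices and limitations

* Problem sizes in tests and the acceptance script — 40-residue chains,
  20-residue fold-switching regions, ensembles of ~7–12 decoys, alignments
  of 30–1000 rows, 20–200 seeds per property — were chosen as the smallest
  sizes at which the asserted statistics are stable.
* plDDT scale: B-factors all ≤ 1.5 are treated as fractional confidences
  and multiplied by 100 (real plDDTs below 1.5 across an entire model do
  not occur in practice).
* Degenerate superposition inputs (fewer than 3 atom pairs, collinear point
  sets) raise errors rather than returning an arbitrary frame.
* The adjusted Rand index used to check clustering recovery comes from an
  independent implementation (`mclust`), not from this package.
* Confusion-table units, `%success`, and the dashed-box ("in-box") RMSD of
  the false-positive rule are this package's documented choices where the
  field has not fixed a definition; all are parameters, not constants.
* RMSD is the only structural metric (no TM-score/GDT/lDDT), hydrogens are
  ignored throughout, and mmCIF input is out of scope.
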