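# Synthetic-data generator: every input the evaluation pipeline consumes,
# with known ground truth — two-conformation reference pairs built from
# backbone dihedrals, decoy ensembles at controlled RMSD/plDDT, hybrid
# conformers, and two-subfamily alignments.

# ideal backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
OMEGA_TRANS <- 180

# place atom D given A-B-C, bond length |C-D|, angle B-C-D, dihedral A-B-C-D
place_atom <- function(A, B, C, length, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(chi),
          length * sin(th) * sin(chi))
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  as.numeric(cbind(bc, m2, n) %*% d2 + C)
}

#' Build a backbone model from a sequence and dihedral angles
#'
#' Places backbone atoms N, CA, C, O by sequential internal-coordinate
#' construction with ideal bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom) and angles, trans peptide bonds (omega = 180), and the supplied
#' phi/psi angles. Residues are numbered 1..L. `phi[1]` is unused (the first
#' residue has no preceding carbonyl); `psi[L]` only orients the terminal
#' carbonyl oxygen.
#'
#' @param sequence one-letter amino-acid string, length >= 4.
#' @param phi,psi numeric vectors of backbone dihedrals in degrees, one per
#'   residue (scalars are recycled).
#' @param plddt per-residue confidence to store (scalar or vector), default
#'   100 (an idealized "experimental" chain).
#' @return a [structure_model] with 4 atoms per residue.
#' @export
build_chain <- function(sequence, phi, psi, plddt = 100) {
  seq_v <- strsplit(toupper(sequence), "")[[1]]
  L <- length(seq_v)
  if (L < 4L) stop("sequence must have at least 4 residues", call. = FALSE)
  unknown <- setdiff(seq_v, names(AA_THREE))
  if (length(unknown) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  phi <- rep_len(phi, L)
  psi <- rep_len(psi, L)
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  # seed the first residue in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(L)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND_N_CA, ANGLE_C_N_CA, OMEGA_TRANS)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  atoms <- data.frame(
    resno = rep(seq_len(L), each = 4L),
    resid = rep(unname(AA_THREE[seq_v]), each = 4L),
    elety = rep(c("N", "CA", "C", "O"), L),
    x = as.numeric(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.numeric(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.numeric(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3]))),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, rep_len(plddt, L), chain_id = "A",
                  source = "build_chain")
}

# canonical dihedral sets
DIHEDRALS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135),
  turn1 = c(phi = -60, psi = -30),
  turn2 = c(phi = -90, psi = 0)
)

# hairpin dihedral track over 1..L: `mode` arms with a 2-residue turn mid-region
hairpin_dihedrals <- function(L, region, mode) {
  arm <- DIHEDRALS[[mode]]
  phi <- rep(DIHEDRALS$helix["phi"], L)
  psi <- rep(DIHEDRALS$helix["psi"], L)
  idx <- region[1]:region[2]
  phi[idx] <- arm["phi"]
  psi[idx] <- arm["psi"]
  mid <- floor((region[1] + region[2]) / 2)
  phi[mid] <- DIHEDRALS$turn1["phi"]; psi[mid] <- DIHEDRALS$turn1["psi"]
  phi[mid + 1] <- DIHEDRALS$turn2["phi"]; psi[mid + 1] <- DIHEDRALS$turn2["psi"]
  list(phi = unname(phi), psi = unname(psi))
}

#' Generate a synthetic two-conformation reference pair
#'
#' Builds the same sequence twice: a helical hairpin over the fold-switching
#' region for the "ground" conformation and an extended (strand) hairpin for
#' the "alternative" — the classic alpha-helix vs beta-sheet fold switch.
#' Construction fails unless the two conformers are separated by more than
#' `min_separation` Angstrom RMSD over the region, so downstream
#' classification always has two genuinely distinct targets.
#'
#' @param length chain length, >= 20.
#' @param region fold-switching residue interval; default the C-terminal
#'   half of the chain.
#' @param seed seed for the (deterministic) random sequence.
#' @param min_separation required inter-conformer region RMSD (Angstrom),
#'   default 5.
#' @return a [reference_pair].
#' @export
make_fold_pair <- function(length, region = NULL, seed = 1L,
                           min_separation = 5) {
  length <- as.integer(length)
  if (length < 20L) stop("`length` must be >= 20", call. = FALSE)
  region <- as.integer(region %||% c(floor(length / 2) + 1L, length))
  if (region[1] < 1L || region[2] > length || region[1] > region[2]) {
    stop("`region` must be a non-empty interval inside 1..length",
         call. = FALSE)
  }
  seq_str <- with_seed(seed,
    paste(sample(AA_LETTERS, length, replace = TRUE), collapse = ""))
  dg <- hairpin_dihedrals(length, region, "helix")
  da <- hairpin_dihedrals(length, region, "strand")
  ground <- build_chain(seq_str, dg$phi, dg$psi)
  alt <- build_chain(seq_str, da$phi, da$psi)
  sep <- {
    pr <- map_atoms(extract_region(ground, region),
                    extract_region(alt, region))
    kabsch_superpose(pr$X, pr$Y)$rmsd
  }
  if (sep <= min_separation) {
    stop(sprintf(
      "reference conformers are not separable: region RMSD %.2f <= %.2f A",
      sep, min_separation), call. = FALSE)
  }
  reference_pair(ground, alt, region)
}

#' Decoy specification
#'
#' @param base `"ground"`, `"alternative"` or `"hybrid"` (ground coordinates
#'   before `hybrid_split`, alternative after).
#' @param target_rmsd intended RMSD (Angstrom) of the decoy from its base
#'   conformer, >= 0.
#' @param plddt per-residue confidence to write (scalar or vector), 0-100.
#' @param seed integer seed for the coordinate noise.
#' @param hybrid_split residue number at which a hybrid decoy switches from
#'   ground to alternative coordinates (required for `base = "hybrid"`).
#' @param run_id identifier of the prediction run the decoy emulates.
#' @return object of class `decoy_spec`.
#' @export
decoy_spec <- function(base = c("ground", "alternative", "hybrid"),
                       target_rmsd = 0, plddt = 80, seed = 0L,
                       hybrid_split = NULL, run_id = 1L) {
  base <- match.arg(base)
  if (target_rmsd < 0) stop("`target_rmsd` must be >= 0", call. = FALSE)
  if (any(plddt < 0 | plddt > 100)) {
    stop("`plddt` must lie in [0, 100]", call. = FALSE)
  }
  if (base == "hybrid" && is.null(hybrid_split)) {
    stop("hybrid decoys require `hybrid_split`", call. = FALSE)
  }
  structure(list(base = base, target_rmsd = target_rmsd, plddt = plddt,
                 seed = as.integer(seed), hybrid_split = hybrid_split,
                 run_id = run_id),
            class = "decoy_spec")
}

#' Generate a decoy model from a reference pair
#'
#' Copies the base conformer and perturbs every coordinate with i.i.d.
#' zero-mean Gaussian noise of standard deviation `target_rmsd / sqrt(3)`
#' (so the expected squared deviation per atom equals `target_rmsd^2`;
#' downstream superposition absorbs a small shrinkage). A `"hybrid"` base
#' splices ground coordinates up to `hybrid_split` with alternative
#' coordinates after it, re-joined by rigidly aligning the alternative
#' conformer onto the ground conformer over the three residues at the
#' junction — emulating the incorrect part-helix/part-sheet artifacts
#' predictors produce. The requested plDDT profile is written per residue.
#'
#' @param refs a [reference_pair].
#' @param spec a [decoy_spec].
#' @return a [structure_model], deterministic per `spec$seed`.
#' @export
make_decoy <- function(refs, spec) {
  stopifnot(inherits(refs, "reference_pair"), inherits(spec, "decoy_spec"))
  base <- switch(spec$base,
                 ground = refs$ground,
                 alternative = refs$alternative,
                 hybrid = hybrid_base(refs, spec$hybrid_split))
  atoms <- base$atoms
  sigma <- spec$target_rmsd / sqrt(3)
  if (sigma > 0) {
    noise <- with_seed(spec$seed,
      matrix(stats::rnorm(nrow(atoms) * 3L, sd = sigma), ncol = 3L))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  structure_model(atoms, rep_len(spec$plddt, length(base$plddt)),
                  chain_id = base$chain_id,
                  source = paste0("decoy:", spec$base))
}

# splice ground (<= split) with alternative (> split), aligning the
# alternative conformer onto ground over the junction residues
hybrid_base <- function(refs, split) {
  g <- refs$ground
  a <- refs$alternative
  resno <- model_resno(g)
  split <- as.integer(split)
  if (split <= min(resno) || split >= max(resno)) {
    stop("`hybrid_split` must fall strictly inside the chain", call. = FALSE)
  }
  junction <- c(split - 1L, split + 1L)
  fit <- map_atoms(extract_region(a, junction), extract_region(g, junction))
  sup <- kabsch_superpose(fit$X, fit$Y)
  atoms <- g$atoms
  after <- atoms$resno > split
  a_xyz <- as.matrix(a$atoms[a$atoms$resno > split, c("x", "y", "z")])
  moved <- sweep(a_xyz %*% t(sup$rotation), 2, sup$translation, "+")
  atoms[after, c("x", "y", "z")] <- moved
  structure_model(atoms, g$plddt, chain_id = g$chain_id, source = "hybrid")
}

#' Generate an ensemble of decoy models on disk
#'
#' Writes one PDB file per spec (plDDT in B-factors, via [write_model()])
#' plus a JSON manifest recording each decoy's generator truth: base
#' conformer, target RMSD, plDDT, seed and run id. The manifest is what
#' end-to-end recovery tests and run accounting consume.
#'
#' @param refs a [reference_pair].
#' @param specs non-empty list of [decoy_spec]s.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame (also written to
#'   `manifest.json` in `dir`).
#' @export
make_ensemble <- function(refs, specs, dir) {
  stopifnot(inherits(refs, "reference_pair"))
  if (length(specs) == 0L) stop("`specs` must be non-empty", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    file = sprintf("model_%03d.pdb", seq_along(specs)),
    base = vapply(specs, `[[`, character(1), "base"),
    target_rmsd = vapply(specs, `[[`, numeric(1), "target_rmsd"),
    plddt = vapply(specs, function(s) mean(s$plddt), numeric(1)),
    seed = vapply(specs, `[[`, integer(1), "seed"),
    run_id = vapply(specs, function(s) as.character(s$run_id), character(1)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(specs)) {
    write_model(make_decoy(refs, specs[[i]]), file.path(dir, manifest$file[i]))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' MSA generator specification
#'
#' @param n_per_subfamily sequences per subfamily, >= 1.
#' @param length alignment length.
#' @param founder_divergence fraction of positions at which the two
#'   subfamily founders differ, in `[0, 1]`.
#' @param mutation_rate per-position mutation probability within a
#'   subfamily, in `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `msa_spec`.
#' @export
msa_spec <- function(n_per_subfamily, length, founder_divergence = 0.6,
                     mutation_rate = 0.05, seed = 0L) {
  if (n_per_subfamily < 1L) stop("`n_per_subfamily` must be >= 1", call. = FALSE)
  if (founder_divergence < 0 || founder_divergence > 1) {
    stop("`founder_divergence` must lie in [0, 1]", call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("`mutation_rate` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_per_subfamily = as.integer(n_per_subfamily),
                 length = as.integer(length),
                 founder_divergence = founder_divergence,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "msa_spec")
}

#' Generate a two-subfamily alignment with known ground truth
#'
#' Two founder sequences differ at `ceiling(founder_divergence * length)`
#' positions; each subfamily member independently mutates every position
#' with probability `mutation_rate` to a uniformly chosen different
#' residue. The query (founder A, unmutated) is prepended as row 1. The
#' returned alignment carries the generator labels in its ids (`A_...` /
#' `B_...`) and in `attr(, "subfamily")` (`"query"`, `"A"`, `"B"`), which is
#' what clustering-recovery tests compare against.
#'
#' @param spec an [msa_spec].
#' @return an [alignment], deterministic per `spec$seed`.
#' @export
synth_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_spec"))
  L <- spec$length
  n <- spec$n_per_subfamily
  with_seed(spec$seed, {
    founder_a <- sample(AA_LETTERS, L, replace = TRUE)
    n_div <- ceiling(spec$founder_divergence * L)
    div_pos <- sample.int(L, n_div)
    founder_b <- founder_a
    founder_b[div_pos] <- vapply(founder_a[div_pos], function(r) {
      sample(setdiff(AA_LETTERS, r), 1L)
    }, character(1))
    mutate <- function(founder) {
      s <- founder
      hit <- stats::runif(L) < spec$mutation_rate
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(r) {
          sample(setdiff(AA_LETTERS, r), 1L)
        }, character(1))
      }
      paste(s, collapse = "")
    }
    rows_a <- vapply(seq_len(n), function(i) mutate(founder_a), character(1))
    rows_b <- vapply(seq_len(n), function(i) mutate(founder_b), character(1))
    aln <- alignment(
      ids = c("query",
              sprintf("A_%04d", seq_len(n)),
              sprintf("B_%04d", seq_len(n))),
      rows = c(paste(founder_a, collapse = ""), rows_a, rows_b),
      query_index = 1L
    )
    attr(aln, "subfamily") <- c("query", rep("A", n), rep("B", n))
    aln
  })
}
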