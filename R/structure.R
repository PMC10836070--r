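#' Single-chain structural model with per-residue confidence
#'
#' A `structure_model` holds one chain of a (predicted or experimental)
#' protein structure: an atom table with residue numbers, 3-letter residue
#' names, atom names and coordinates in Angstrom, plus a per-residue
#' confidence (plDDT, 0-100 scale) as structure predictors emit in the PDB
#' B-factor column.
#'
#' @param atoms data.frame with columns `resno`, `resid`, `elety`, `x`, `y`,
#'   `z` (one row per atom; residue numbers strictly increasing along the
#'   chain, every residue carrying a CA atom).
#' @param plddt numeric vector of per-residue confidences in `[0, 100]`, one
#'   per distinct residue number (in residue order).
#' @param chain_id single character chain identifier.
#' @param source file path or generator tag the model came from.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, plddt, chain_id = "A", source = "memory") {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
  resno <- unique(atoms$resno)
  if (is.unsorted(resno, strictly = TRUE)) {
    stop("residue numbers must be strictly increasing", call. = FALSE)
  }
  has_ca <- vapply(split(atoms$elety, factor(atoms$resno, levels = resno)),
                   function(e) "CA" %in% e, logical(1))
  if (!all(has_ca)) {
    stop("residue(s) without a CA atom: ",
         paste(resno[!has_ca], collapse = ", "), call. = FALSE)
  }
  plddt <- as.numeric(plddt)
  if (length(plddt) != length(resno)) {
    stop("`plddt` must have one value per residue", call. = FALSE)
  }
  if (any(plddt < 0 | plddt > 100)) {
    stop("plDDT values must lie in [0, 100]", call. = FALSE)
  }
  names(plddt) <- resno
  structure(list(atoms = atoms, plddt = plddt, chain_id = chain_id,
                 source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d residues, %d atoms, chain %s, mean plDDT %.1f\n",
              length(x$plddt), nrow(x$atoms), x$chain_id, mean(x$plddt)))
  invisible(x)
}

# residue numbers of a model, in chain order
model_resno <- function(m) as.integer(names(m$plddt))

# one-letter sequence of a model
model_sequence <- function(m) {
  resno <- model_resno(m)
  resid <- m$atoms$resid[match(resno, m$atoms$resno)]
  one <- AA_ONE[resid]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Read a predicted or experimental model from a PDB file
#'
#' Parses ATOM records (first model of multi-model files; alternate locations
#' other than blank/`A` discarded; hydrogens dropped) and takes the CA
#' B-factor of each residue as its plDDT. If every B-factor is at most 1.5
#' the values are interpreted as fractional confidences and multiplied by
#' 100. Residues lacking a CA atom are dropped with a warning.
#'
#' @param path a PDB file.
#' @param chain optional chain id to select; default takes the first chain.
#' @return a [structure_model].
#' @export
read_model <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  ch <- chain %||% at$chain[1]
  at <- at[at$chain %in% ch, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", ch, " in ", path,
                           call. = FALSE)
  at <- at[!grepl("^H", trimws(at$elety)), , drop = FALSE] # drop hydrogens
  resno <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(resno, ca$resno)
  if (length(missing_ca) > 0L) {
    warning("dropping residue(s) without CA in ", basename(path), ": ",
            paste(missing_ca, collapse = ", "), call. = FALSE)
    at <- at[!at$resno %in% missing_ca, , drop = FALSE]
    resno <- unique(at$resno)
  }
  if (nrow(at) == 0L) stop("no complete residues in ", path, call. = FALSE)
  plddt <- ca$b[match(resno, ca$resno)]
  # predictors write plDDT either on the 0-100 or the 0-1 scale
  if (all(plddt <= 1.5)) plddt <- plddt * 100
  atoms <- data.frame(resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure_model(atoms, plddt, chain_id = ch, source = path)
}

#' Write a model to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals); each atom's
#' B-factor carries the plDDT of its residue, the convention used by
#' structure-prediction software. Round-trips through [read_model()].
#'
#' @param m a [structure_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "structure_model"))
  a <- m$atoms
  b <- unname(m$plddt[as.character(a$resno)])
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = rep(m$chain_id, nrow(a)),
                   o = rep(1, nrow(a)), b = b)
  invisible(path)
}

#' Extract a residue-number interval from a model
#'
#' @param m a [structure_model].
#' @param interval inclusive 1-based residue-number interval, length-2
#'   numeric `c(from, to)`.
#' @return a [structure_model] restricted to residues inside the interval.
#' @export
extract_region <- function(m, interval) {
  stopifnot(inherits(m, "structure_model"), length(interval) == 2L)
  interval <- as.integer(interval)
  resno <- model_resno(m)
  keep <- resno >= interval[1] & resno <= interval[2]
  if (!any(keep)) {
    stop("interval [", interval[1], ", ", interval[2],
         "] does not overlap model residues (",
         min(resno), "-", max(resno), ")", call. = FALSE)
  }
  atoms <- m$atoms[m$atoms$resno %in% resno[keep], , drop = FALSE]
  structure_model(atoms, unname(m$plddt[keep]), chain_id = m$chain_id,
                  source = m$source)
}

#' Mean per-residue confidence
#'
#' Unweighted mean plDDT over an interval (or the whole model). The accuracy
#' rule of the evaluation averages confidence over the fold-switching region.
#'
#' @param m a [structure_model].
#' @param interval optional inclusive residue interval; `NULL` = all residues.
#' @return mean plDDT (scalar).
#' @export
mean_plddt <- function(m, interval = NULL) {
  stopifnot(inherits(m, "structure_model"))
  if (is.null(interval)) return(mean(m$plddt))
  mean(extract_region(m, interval)$plddt)
}

#' Pair atoms between two models for superposition
#'
#' Residues are paired in chain order (sequences are compared and a warning
#' is raised when they are not identical, as in mutant evaluation, but
#' pairing proceeds); within each residue pair, atoms are matched by atom
#' name, keeping the intersection present in both. `atom_mode = "all_heavy"`
#' uses every shared non-hydrogen atom, `"ca_only"` only CA.
#'
#' @param a,b [structure_model]s covering the same region.
#' @param atom_mode `"all_heavy"` (default) or `"ca_only"`.
#' @return list with `X` and `Y`, two N x 3 coordinate matrices in identical
#'   atom order, and `n_atoms = N`.
#' @export
map_atoms <- function(a, b, atom_mode = c("all_heavy", "ca_only")) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  ra <- model_resno(a)
  rb <- model_resno(b)
  n_res <- min(length(ra), length(rb))
  if (length(ra) != length(rb)) {
    warning("models have different residue counts (", length(ra), " vs ",
            length(rb), "); pairing the first ", n_res, call. = FALSE)
  }
  sa <- strsplit(model_sequence(a), "")[[1]][seq_len(n_res)]
  sb <- strsplit(model_sequence(b), "")[[1]][seq_len(n_res)]
  if (any(sa != sb)) {
    warning("paired residues differ at ", sum(sa != sb),
            " position(s); matching atoms by name anyway", call. = FALSE)
  }
  Xs <- vector("list", n_res)
  Ys <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    aa <- a$atoms[a$atoms$resno == ra[i], , drop = FALSE]
    bb <- b$atoms[b$atoms$resno == rb[i], , drop = FALSE]
    common <- if (atom_mode == "ca_only") "CA" else intersect(aa$elety, bb$elety)
    common <- setdiff(common, grep("^H", common, value = TRUE))
    Xs[[i]] <- as.matrix(aa[match(common, aa$elety), c("x", "y", "z")])
    Ys[[i]] <- as.matrix(bb[match(common, bb$elety), c("x", "y", "z")])
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  if (is.null(X) || nrow(X) < 3L) {
    stop("fewer than 3 matched atoms between models", call. = FALSE)
  }
  dimnames(X) <- dimnames(Y) <- NULL
  list(X = X, Y = Y, n_atoms = nrow(X))
}
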