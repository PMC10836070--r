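#' Query-anchored multiple sequence alignment
#'
#' An `alignment` is a character matrix view of an MSA: a vector of unique
#' sequence identifiers and equal-length aligned rows over the alphabet of the
#' 20 amino acids, `X` and the gap character `-`. The row at `query_index`
#' (default 1) is the query and defines the column space: A3M input is
#' normalized by deleting lowercase insertion characters so every row has the
#' query's length.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of aligned sequences, same length as `ids`.
#' @param query_index integer, which row is the query (1-based).
#' @return An object of class `alignment` with elements `ids`, `rows`,
#'   `query_index`.
#' @export
alignment <- function(ids, rows, query_index = 1L) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows)) {
    stop("`ids` and `rows` must have the same length", call. = FALSE)
  }
  if (length(rows) < 1L) stop("alignment must contain at least one row", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("sequence identifiers must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(range(widths), collapse = "-"), ")", call. = FALSE)
  }
  query_index <- as.integer(query_index)
  stopifnot(query_index >= 1L, query_index <= length(rows))
  bad <- vapply(rows, function(r) {
    any(!strsplit(r, "")[[1]] %in% ALN_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) contain characters outside the alignment alphabet: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, query_index = query_index),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns (query: %s)\n",
              length(x$rows), nchar(x$rows[1]), x$ids[x$query_index]))
  invisible(x)
}

#' @export
length.alignment <- function(x) length(x$rows)

#' Read a FASTA or A3M multiple sequence alignment
#'
#' For `format = "a3m"` lowercase characters mark insertions relative to the
#' query and are deleted during normalization (the standard A3M convention),
#' so every returned row has the query's length. For `format = "fasta"` all
#' records must already be equal length.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"a3m"`. Default guesses from the file
#'   extension, falling back to `"fasta"`.
#' @return An [alignment] with the first record as query.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse ", path, " as ",
                                           format, ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  ids <- names(set)
  rows <- as.character(set)
  if (format == "a3m") {
    # drop insertion states (lowercase) relative to the query
    rows <- gsub("[a-z]", "", rows)
  } else {
    widths <- nchar(rows)
    if (length(unique(widths)) != 1L) {
      stop("fasta alignment rows have unequal lengths in ", path, call. = FALSE)
    }
  }
  alignment(ids = ids, rows = rows, query_index = 1L)
}

#' Write an alignment in A3M/FASTA format
#'
#' The query row is written first; ids and residues are preserved verbatim so
#' `write_a3m()` followed by [read_alignment()] round-trips exactly.
#'
#' @param aln an [alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  ord <- c(aln$query_index, setdiff(seq_along(aln$rows), aln$query_index))
  lines <- as.vector(rbind(paste0(">", aln$ids[ord]), aln$rows[ord]))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# alignment rows as a character matrix (n_rows x L)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

#' One-hot encode an alignment
#'
#' Each column becomes a block of 22 channels (20 amino acids, `X`, gap);
#' exactly one channel per block is 1, so every row of the result sums to the
#' alignment length. This is the substrate the sequence clusterer operates on.
#'
#' @param aln an [alignment].
#' @return numeric matrix of shape `n_rows x (L * 22)`, with rownames from
#'   `aln$ids`.
#' @export
one_hot_encode <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  m <- aln_matrix(aln)
  L <- ncol(m)
  A <- length(ALN_ALPHABET)
  idx <- matrix(match(m, ALN_ALPHABET), nrow = nrow(m))
  out <- matrix(0, nrow = nrow(m), ncol = L * A)
  for (j in seq_len(L)) {
    out[cbind(seq_len(nrow(m)), (j - 1L) * A + idx[, j])] <- 1
  }
  rownames(out) <- aln$ids
  out
}

#' Pairwise sequence identity
#'
#' Fraction of matching positions over columns where neither sequence has a
#' gap. Symmetric in its arguments.
#'
#' @param a,b aligned sequences of equal length (character scalars).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) {
    stop("sequences have different lengths (", length(av), " vs ",
         length(bv), ")", call. = FALSE)
  }
  keep <- av != "-" & bv != "-"
  if (!any(keep)) {
    stop("identity undefined: no columns where both sequences are ungapped",
         call. = FALSE)
  }
  mean(av[keep] == bv[keep])
}
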