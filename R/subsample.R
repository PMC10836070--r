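#' Subsampling depth specification
#'
#' Depth parameters for shallow random MSA subsampling, named after the
#' ColabFold knobs they feed: `max_seq` caps the cluster sequences and
#' `max_extra_seq` the extra sequences handed to the predictor. The protocol
#' default ties `max_extra_seq = 2 * max_seq`; the depths used for the three
#' benchmark fold switchers are `max_seq` = 1 (KaiB), 8 (Mad2), 64 (RfaH).
#'
#' @param max_seq positive integer.
#' @param max_extra_seq non-negative integer; default `2 * max_seq`.
#' @param seed integer seed for the random draw.
#' @return object of class `subsample_spec`.
#' @export
subsample_spec <- function(max_seq, max_extra_seq = 2L * max_seq, seed = 0L) {
  max_seq <- as.integer(max_seq)
  max_extra_seq <- as.integer(max_extra_seq)
  if (is.na(max_seq) || max_seq < 1L) stop("`max_seq` must be >= 1", call. = FALSE)
  if (is.na(max_extra_seq) || max_extra_seq < 0L) {
    stop("`max_extra_seq` must be >= 0", call. = FALSE)
  }
  structure(list(max_seq = max_seq, max_extra_seq = max_extra_seq,
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

#' Randomly subsample an alignment to shallow depth
#'
#' Keeps the query row first and draws the remaining
#' `max_seq + max_extra_seq - 1` rows uniformly without replacement from the
#' non-query rows. Shallow depths are what induce conformational diversity in
#' the downstream predictor; this is the random-sampling (CF-random style)
#' counterpart to sequence clustering. If the alignment is smaller than the
#' requested depth all rows are returned. Deterministic per `spec$seed`.
#'
#' @param aln an [alignment].
#' @param spec a [subsample_spec].
#' @return an [alignment] whose rows are a subset of `aln`'s, query first.
#' @export
random_subsample <- function(aln, spec) {
  stopifnot(inherits(aln, "alignment"), inherits(spec, "subsample_spec"))
  depth <- spec$max_seq + spec$max_extra_seq
  others <- setdiff(seq_along(aln$rows), aln$query_index)
  n_draw <- min(depth - 1L, length(others))
  picked <- if (n_draw > 0L) {
    with_seed(spec$seed, sort(sample(others, n_draw, replace = FALSE)))
  } else {
    integer(0)
  }
  keep <- c(aln$query_index, picked)
  alignment(ids = aln$ids[keep], rows = aln$rows[keep], query_index = 1L)
}
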