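#' Density-based clustering of aligned sequences
#'
#' Clusters alignment rows with DBSCAN semantics on the fractional Hamming
#' distance between rows (number of differing columns divided by alignment
#' length; identical to a scaled L2 distance between one-hot encodings). A
#' point with at least `min_samples` neighbours within `eps` (itself included)
#' is a core point; clusters are the connected components of core points plus
#' their border points; everything else is noise, labelled `-1`. This is the
#' sequence-similarity clustering stage that cluster-then-predict protocols
#' (AF-cluster style) apply to an MSA before running a structure predictor
#' per cluster.
#'
#' Border points reachable from several clusters are assigned to the cluster
#' of the first core point that reaches them in row order, which makes the
#' result deterministic for fixed input.
#'
#' @param aln an [alignment].
#' @param eps neighbourhood radius as a fraction of columns in `[0, 1]`.
#' @param min_samples minimum neighbourhood size (including the point itself)
#'   for a core point. Default 3.
#' @return An object of class `cluster_result`: list with `labels` (integer
#'   per row, `-1` = noise, clusters numbered from 0 in order of discovery),
#'   `eps`, `min_samples`.
#' @export
cluster_sequences <- function(aln, eps, min_samples = 3L) {
  stopifnot(inherits(aln, "alignment"))
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("`eps` must be a positive number", call. = FALSE)
  }
  min_samples <- as.integer(min_samples)
  n <- length(aln$rows)
  if (n < min_samples) {
    stop("alignment has fewer rows (", n, ") than `min_samples` (",
         min_samples, ")", call. = FALSE)
  }
  d <- hamming_dist(aln)
  labels <- dbscan_labels(d, eps, min_samples)
  structure(list(labels = labels, eps = eps, min_samples = min_samples),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(setdiff(unique(x$labels), -1L))
  cat(sprintf("cluster_result: %d clusters, %d noise points (eps=%g, min_samples=%d)\n",
              k, sum(x$labels == -1L), x$eps, x$min_samples))
  invisible(x)
}

# fractional Hamming distance matrix between alignment rows
hamming_dist <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- colMeans(t(m) != m[i, ])
    d[i, ] <- di
  }
  d
}

# DBSCAN on a precomputed distance matrix; labels: -1 noise, clusters 0,1,...
dbscan_labels <- function(d, eps, min_samples) {
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nbrs) >= min_samples
  labels <- rep(0L, n) # 0 = unvisited, -1 = noise, >0 = cluster id
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (!core[i]) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nbrs[[i]], i)
    k <- 1L
    while (k <= length(seeds)) {
      j <- seeds[k]
      k <- k + 1L
      if (labels[j] == -1L) labels[j] <- cl # border point rescued from noise
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) seeds <- c(seeds, setdiff(nbrs[[j]], seeds))
    }
  }
  ifelse(labels > 0L, labels - 1L, -1L)
}

#' Scan eps values for the sequence clusterer
#'
#' Runs [cluster_sequences()] over a grid of `eps` values and returns the one
#' maximizing the number of clusters with at least `min_samples` members;
#' ties are broken toward the fewest noise points, then toward the smaller
#' `eps`. This mirrors how cluster-based protocols tune their neighbourhood
#' radius when no value is prescribed.
#'
#' @param aln an [alignment].
#' @param lo,hi,step grid of eps values `seq(lo, hi, by = step)`.
#' @param min_samples passed to [cluster_sequences()].
#' @return list with `best_eps`, `best` (the winning `cluster_result`) and
#'   `scan` (data.frame of eps vs cluster count).
#' @export
scan_eps <- function(aln, lo, hi, step, min_samples = 3L) {
  stopifnot(lo > 0, hi >= lo, step > 0)
  grid <- seq(lo, hi, by = step)
  results <- lapply(grid, function(e) cluster_sequences(aln, e, min_samples))
  counts <- vapply(results, function(r) {
    tab <- table(r$labels[r$labels != -1L])
    sum(tab >= r$min_samples)
  }, integer(1))
  noise <- vapply(results, function(r) sum(r$labels == -1L), integer(1))
  best <- order(-counts, noise, grid)[1]
  list(best_eps = grid[best], best = results[[best]],
       scan = data.frame(eps = grid, n_clusters = counts))
}
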