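## Clustering of accessibility trajectories, quantile binning for heatmap
## display, coefficient-of-variation profiles and mean-increase curves.

#' Cluster accessibility trajectories by k-means
#'
#' Clusters the peaks x stages FPKM matrix with `stats::kmeans` (k = 5,
#' 10 random starts, up to 1000 iterations by default). Labels are
#' renumbered by descending final-stage centroid so cluster 1 is always the
#' most accessible at the last stage, giving stable figure ordering. The
#' fraction of total variance explained by between-cluster differences is
#' reported alongside.
#'
#' @param fpkm_matrix Numeric matrix, peaks x stages.
#' @param k Number of clusters, default 5.
#' @param n_starts Random starts, default 10.
#' @param max_iter Maximum iterations, default 1000.
#' @param seed RNG seed for reproducible starts.
#' @param log_transform Cluster log2(x + 1) values instead of raw FPKM.
#' @return list: `labels` (1..k per peak), `centroids` (k x stages, on the
#'   clustered scale), `between_var_fraction`, `totss`, `betweenss`,
#'   `withinss`, and the call parameters.
#' @export
cluster_dynamics <- function(fpkm_matrix, k = 5L, n_starts = 10L,
                             max_iter = 1000L, seed = 1L,
                             log_transform = FALSE) {
  x <- as.matrix(fpkm_matrix)
  if (log_transform) x <- log2(x + 1)
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct rows")
  km <- with_stream(seed, "kmeans",
                    kmeans(x, centers = k, nstart = n_starts,
                           iter.max = max_iter))
  ## stable presentation order: descending centroid at the final stage
  ord <- order(km$centers[, ncol(x)], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  bf <- if (km$totss > 0) km$betweenss / km$totss else 0
  list(labels = setNames(labels, rownames(x)), centroids = centroids,
       between_var_fraction = bf, totss = km$totss,
       betweenss = km$betweenss, withinss = sum(km$withinss),
       k = k, n_starts = n_starts, max_iter = max_iter, seed = seed,
       log_transform = log_transform)
}

#' Bin matrix values into joint quantiles
#'
#' Rank-based mapping of all matrix entries jointly onto integer bins
#' 0..`n_quantiles` (low to high), the transformation used for heatmap
#' display. Ties share a bin (minimum rank), so a constant matrix collapses
#' to bin 0; the mapping is monotone in the values.
#'
#' @param x Numeric matrix (or vector) of finite values.
#' @param n_quantiles Number of quantile steps, default 100.
#' @return Integer matrix of the same shape with values in 0..n_quantiles.
#' @export
quantile_bin <- function(x, n_quantiles = 100L) {
  v <- as.vector(x)
  stopifnot(all(is.finite(v)))
  n <- length(v)
  r <- rank(v, ties.method = "min")
  ## integer numerator first: exact where (r-1)(q+1) is a multiple of n
  b <- pmin(as.integer(floor((r - 1) * (n_quantiles + 1) / n)),
            as.integer(n_quantiles))
  out <- x
  out[] <- b
  storage.mode(out) <- "integer"
  out
}

#' Coefficient of variation of trajectories, per element class
#'
#' CV = stage-wise standard deviation / mean per peak (sample sd, n-1
#' denominator, by default). Zero-mean peaks are excluded and counted.
#'
#' @param fpkm_matrix Peaks x stages matrix.
#' @param classes Character vector of element classes per row (e.g.
#'   "promoter"/"enhancer"/"other"); NULL for a single class.
#' @param sd_type "sample" (n-1) or "population" (n).
#' @return data.frame peak, class, cv; attribute `n_zero_mean` counts
#'   excluded peaks.
#' @export
cv_profile <- function(fpkm_matrix, classes = NULL,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(fpkm_matrix)
  if (ncol(x) < 2) stop("need >= 2 stages")
  if (is.null(classes)) classes <- rep("all", nrow(x))
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (sd_type == "population") s <- s * sqrt((ncol(x) - 1) / ncol(x))
  keep <- m > 0
  out <- data.frame(
    peak = if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x),
    class = classes, cv = ifelse(keep, s / m, NA_real_),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_zero_mean") <- sum(!keep)
  out
}

#' Mean accessibility change between consecutive stages, per region class
#'
#' For each genomic bin, the change in coverage between consecutive stage
#' tracks is averaged within a class of bins: genome-wide, or bins
#' overlapping a supplied region set (promoters, enhancers, ...).
#'
#' @param stage_tracks Ordered named list of `coverage_track`s (one per
#'   stage, same grid).
#' @param region_classes Named list of BED-style region tables; the class
#'   "genome" (all bins) is always included.
#' @return Matrix classes x transitions of mean per-bin change.
#' @export
mean_increase_profile <- function(stage_tracks, region_classes = list()) {
  stopifnot(length(stage_tracks) >= 2)
  for (t in stage_tracks[-1]) check_same_grid(stage_tracks[[1]], t)
  tr0 <- stage_tracks[[1]]
  bs <- tr0$bin_size
  ## class membership per bin, as one logical vector over the unrolled grid
  bin_class <- list(genome = rep(TRUE, sum(lengths(tr0$values))))
  for (cl in names(region_classes)) {
    memb <- logical(0)
    for (chrom in names(tr0$values)) {
      n_bins <- length(tr0$values[[chrom]])
      bins <- data.frame(chrom = chrom,
                         start = (seq_len(n_bins) - 1L) * bs,
                         end = seq_len(n_bins) * bs)
      memb <- c(memb, overlaps_any_bed(bins, region_classes[[cl]]))
    }
    bin_class[[cl]] <- memb
  }
  stages <- names(stage_tracks)
  trans <- paste(stages[-length(stages)], stages[-1], sep = "->")
  out <- matrix(NA_real_, length(bin_class), length(trans),
                dimnames = list(names(bin_class), trans))
  unroll <- function(tr) unlist(tr$values, use.names = FALSE)
  prev <- unroll(stage_tracks[[1]])
  for (j in seq_along(trans)) {
    curr <- unroll(stage_tracks[[j + 1]])
    d <- curr - prev
    for (cl in names(bin_class)) out[cl, j] <- mean(d[bin_class[[cl]]])
    prev <- curr
  }
  out
}
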