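## Peak calling against a genomic-DNA control, replicate confirmation and
## cross-stage consensus building. Peaks are BED-style data.frames with
## summit (bp offset into the peak) and score (-log10 q at the summit bin).

#' Call accessible regions with a Poisson enrichment test
#'
#' A self-contained reference peak caller: per bin, the treatment fragment
#' count is tested against a Poisson null whose rate is the maximum of a
#' local control mean (control scaled to the treatment library size,
#' averaged over a sliding window) and the genome-wide scaled control mean.
#' P-values are BH-adjusted across all bins; significant bins closer than
#' `gap_bins` are merged; peaks narrower than `min_width` are discarded.
#' The summit is the offset of the maximum treatment bin. With
#' `control = NULL` the genome-wide treatment mean serves as the null rate.
#'
#' @param treatment `coverage_track` with raw `fragment_count` statistics.
#' @param control Matching control track (e.g. tagmented genomic DNA), or
#'   NULL.
#' @param fdr Benjamini-Hochberg threshold, default 0.05.
#' @param min_width Minimum peak width in bp, default 100.
#' @param gap_bins Merge significant bins separated by at most this many
#'   non-significant bins, default 1.
#' @param local_halfwidth_bp Half-width of the local background window,
#'   default 2500 bp.
#' @return Peaks as a data.frame: chrom, start, end, name, score
#'   (-log10 q at summit), strand, summit.
#' @export
call_peaks <- function(treatment, control = NULL, fdr = 0.05,
                       min_width = 100L, gap_bins = 1L,
                       local_halfwidth_bp = 2500L) {
  stopifnot(inherits(treatment, "coverage_track"))
  if (treatment$stat != "fragment_count" || treatment$normalization != "raw")
    stop("call_peaks needs a raw fragment_count track")
  if (!is.null(control)) check_same_grid(treatment, control)
  bs <- treatment$bin_size
  w <- max(1L, round(local_halfwidth_bp / bs))
  all_p <- list()
  lambdas <- list()
  for (chrom in names(treatment$values)) {
    x <- treatment$values[[chrom]]
    if (!is.null(control)) {
      ctl <- control$values[[chrom]] *
        (treatment$library_size / max(control$library_size, 1))
      if (length(ctl) > 2 * w + 1) {
        loc <- as.numeric(stats::filter(ctl, rep(1 / (2 * w + 1), 2 * w + 1),
                                        sides = 2))
        loc[is.na(loc)] <- mean(ctl)
      } else {
        loc <- rep(mean(ctl), length(ctl))
      }
      lam <- pmax(loc, mean(ctl))
    } else {
      lam <- rep(mean(x), length(x))
    }
    lam <- pmax(lam, 1e-8)
    all_p[[chrom]] <- ppois(x - 1, lam, lower.tail = FALSE)
    lambdas[[chrom]] <- lam
  }
  q <- p.adjust(unlist(all_p, use.names = FALSE), method = "BH")
  qs <- split(q, rep(names(all_p), lengths(all_p)))[names(all_p)]

  peaks <- list()
  for (chrom in names(treatment$values)) {
    x <- treatment$values[[chrom]]
    sig <- which(qs[[chrom]] < fdr & x > 0)
    if (!length(sig)) next
    grp <- cumsum(c(1L, diff(sig) > gap_bins + 1L))
    for (g in unique(grp)) {
      b <- sig[grp == g]
      start <- (min(b) - 1L) * bs
      end <- min(max(b) * bs, treatment$chrom_sizes[[chrom]])
      if (end - start < min_width) next
      seg <- x[min(b):max(b)]
      smax <- min(b) + which.max(seg) - 1L
      summit <- as.integer((smax - 1L) * bs + bs %/% 2 - start)
      score <- -log10(max(min(qs[[chrom]][b]), 1e-300))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end,
        name = sprintf("peak_%s_%d", chrom, start),
        score = score, strand = ".", summit = summit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(peaks)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), summit = integer()))
  }
  do.call(rbind, peaks)
}

overlaps_any_bed <- function(query, subject) {
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(bed_to_granges(query), bed_to_granges(subject),
                       ignore.strand = TRUE)
}

#' Keep pooled peaks confirmed in every replicate
#'
#' A peak called on pooled replicates is retained iff it overlaps (>= 1 bp)
#' at least one peak called in each individual replicate.
#'
#' @param pooled Peak table from pooled replicates.
#' @param replicate_peaks List of per-replicate peak tables (length >= 1).
#' @return The confirmed subset of `pooled`.
#' @export
confirm_replicated <- function(pooled, replicate_peaks) {
  stopifnot(length(replicate_peaks) >= 1)
  if (!nrow(pooled)) return(pooled)
  keep <- rep(TRUE, nrow(pooled))
  for (rep_pk in replicate_peaks) keep <- keep & overlaps_any_bed(pooled, rep_pk)
  out <- pooled[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge replicated peaks across stages into a consensus set
#'
#' Single-linkage merge of all input intervals at >= 1 bp overlap (abutting
#' half-open intervals are NOT merged). A consensus peak is flagged
#' "present" in a stage iff it overlaps a replicated peak of that stage by
#' >= 1 bp.
#'
#' @param stage_peaks Named list of per-stage replicated peak tables; names
#'   are the stage labels.
#' @return list with `peaks` (consensus intervals with `name`) and
#'   `presence` (logical matrix consensus x stage).
#' @export
build_consensus <- function(stage_peaks) {
  stopifnot(is.list(stage_peaks), !is.null(names(stage_peaks)))
  all_pk <- do.call(rbind, lapply(stage_peaks, function(p)
    p[c("chrom", "start", "end")]))
  if (is.null(all_pk) || !nrow(all_pk)) {
    return(list(peaks = data.frame(chrom = character(), start = integer(),
                                   end = integer(), name = character()),
                presence = matrix(logical(), 0, length(stage_peaks),
                                  dimnames = list(NULL, names(stage_peaks)))))
  }
  gr <- bed_to_granges(all_pk)
  ## min.gapwidth = 0: only intervals sharing >= 1 base are merged
  cons <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  peaks <- granges_to_bed(cons)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$name <- sprintf("consensus_%s_%d", peaks$chrom, peaks$start)
  presence <- vapply(stage_peaks, function(p) overlaps_any_bed(peaks, p),
                     logical(nrow(peaks)))
  presence <- matrix(presence, nrow = nrow(peaks),
                     dimnames = list(peaks$name, names(stage_peaks)))
  stopifnot(all(rowSums(presence) >= 1))
  list(peaks = peaks, presence = presence)
}
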