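## Fragment processing: Tn5 cut-site correction, NFR split, coverage tracks
## and region matrices. Fragments live in BED-style data.frames
## (chrom, start, end; 0-based half-open), optionally with mapq/sample columns.

#' Adjust fragment coordinates to Tn5 insertion points
#'
#' The Tn5 transposase inserts in a staggered fashion, so alignment ends do
#' not coincide with the chromatin-accessible positions. The standard
#' correction shifts the fragment start by +4 bp and the fragment end by
#' -5 bp, i.e. adjusted length = raw length - 9. Fragments whose adjusted
#' length would be < 1 bp are dropped and counted.
#'
#' An optional mapping-quality filter (`min_mapq`, applied when a `mapq`
#' column is present) and a contig blacklist mirror the usual upstream
#' alignment filters.
#'
#' @param fragments BED-style data.frame of raw fragment intervals.
#' @param shift_start,shift_end Coordinate shifts in bp (defaults +4 / -5).
#' @param min_mapq Minimum mapping quality; only applied if a `mapq` column
#'   exists. Default 30.
#' @param blacklist Character vector of contig names to drop (e.g. "chrM").
#' @return The adjusted fragments with a `length` column; attributes
#'   `n_dropped` (degenerate after shift) and `n_filtered` (mapq/blacklist)
#'   record what was removed.
#' @export
adjust_cut_sites <- function(fragments, shift_start = 4L, shift_end = -5L,
                             min_mapq = 30L, blacklist = character()) {
  stopifnot(all(fragments$start < fragments$end))
  n0 <- nrow(fragments)
  keep <- rep(TRUE, n0)
  if ("mapq" %in% names(fragments)) keep <- keep & fragments$mapq >= min_mapq
  if (length(blacklist)) keep <- keep & !fragments$chrom %in% blacklist
  n_filtered <- sum(!keep)
  out <- fragments[keep, , drop = FALSE]
  out$start <- out$start + as.integer(shift_start)
  out$end <- out$end + as.integer(shift_end)
  degenerate <- out$start >= out$end
  n_dropped <- sum(degenerate)
  out <- out[!degenerate, , drop = FALSE]
  out$length <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Split adjusted fragments at the nucleosome-free size cutoff
#'
#' Sub-nucleosomal ("NFR") fragments report open chromatin; larger fragments
#' wrap one or more nucleosomes. A fragment is NFR iff its adjusted length is
#' `<=` the cutoff (130 bp by default, chosen from typical ATAC fragment-length
#' profiles). The two sets partition the input.
#'
#' @param fragments Adjusted fragments (see [adjust_cut_sites()]).
#' @param nfr_cutoff Length cutoff in bp; default 130.
#' @return list with elements `nfr` and `nucleosomal`.
#' @export
split_by_size <- function(fragments, nfr_cutoff = 130L) {
  if (nfr_cutoff < 1) stop("nfr_cutoff must be >= 1")
  len <- if ("length" %in% names(fragments)) fragments$length else
    fragments$end - fragments$start
  is_nfr <- len <= nfr_cutoff
  list(nfr = fragments[is_nfr, , drop = FALSE],
       nucleosomal = fragments[!is_nfr, , drop = FALSE])
}

#' Fragment length histogram
#'
#' Summarises the fragment-length distribution, the report used to choose
#' (or sanity-check) the NFR cutoff.
#'
#' @param fragments Fragment table (adjusted or raw).
#' @param binwidth Histogram bin width in bp.
#' @return data.frame with `length_bin` (left edge) and `count`.
#' @export
fragment_length_histogram <- function(fragments, binwidth = 10L) {
  len <- if ("length" %in% names(fragments)) fragments$length else
    fragments$end - fragments$start
  bin <- floor(len / binwidth) * binwidth
  tab <- table(bin)
  data.frame(length_bin = as.integer(names(tab)), count = as.integer(tab))
}

#' Build a binned coverage track from fragments
#'
#' Every fragment contributes over its full width. In `stat = "base_overlap"`
#' mode a bin accumulates the number of fragment-bases overlapping it; in
#' `stat = "fragment_count"` mode it counts fragments overlapping the bin by
#' >= 1 bp (integer counts, the input for Poisson peak calling). RPKM
#' normalization divides by bin kilobases and library size in millions
#' (base_overlap values are first converted to mean per-base depth), making
#' tracks invariant to joint scaling of fragments and library size.
#'
#' @param fragments Fragment table.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp, default 20.
#' @param normalization "raw" or "rpkm".
#' @param stat "base_overlap" or "fragment_count".
#' @param library_size Total fragments in the library; defaults to
#'   `nrow(fragments)`.
#' @return A `coverage_track`: list of per-chromosome numeric vectors plus
#'   grid metadata. Fragments extending beyond chromosome ends are clipped
#'   and counted in attribute `n_clipped`.
#' @export
make_coverage <- function(fragments, chrom_sizes, bin_size = 20L,
                          normalization = c("rpkm", "raw"),
                          stat = c("base_overlap", "fragment_count"),
                          library_size = NULL) {
  normalization <- match.arg(normalization)
  stat <- match.arg(stat)
  if (is.null(library_size)) library_size <- nrow(fragments)
  n_clipped <- 0L
  values <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    n_bins <- as.integer(ceiling(len / bin_size))
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (!nrow(fr)) {
      values[[chrom]] <- numeric(n_bins)
      next
    }
    s <- pmax(fr$start, 0L)
    e <- pmin(fr$end, len)
    clip <- s != fr$start | e != fr$end
    n_clipped <- n_clipped + sum(clip)
    ok <- s < e
    s <- s[ok]; e <- e[ok]
    ir <- IRanges::IRanges(start = s + 1L, end = e)
    if (stat == "base_overlap") {
      cov <- IRanges::coverage(ir, width = len)
      pad <- n_bins * bin_size
      if (pad > len) cov <- c(cov, S4Vectors::Rle(0L, pad - len))
      v <- IRanges::viewSums(
        IRanges::Views(cov, start = seq(1L, pad, by = bin_size),
                       width = bin_size))
    } else {
      bins <- IRanges::IRanges(
        start = seq(1L, n_bins * bin_size, by = bin_size), width = bin_size)
      v <- IRanges::countOverlaps(bins, ir)
    }
    values[[chrom]] <- as.numeric(v)
  }
  if (normalization == "rpkm") {
    scale <- if (stat == "base_overlap") {
      1 / (bin_size * max(library_size, 1) / 1e6)
    } else {
      1 / ((bin_size / 1000) * max(library_size, 1) / 1e6)
    }
    values <- lapply(values, function(v) v * scale)
  }
  structure(
    list(values = values, bin_size = as.integer(bin_size),
         chrom_sizes = chrom_sizes, normalization = normalization,
         stat = stat, library_size = library_size),
    class = "coverage_track", n_clipped = n_clipped)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin %d bp, %s (%s), library %g fragments\n",
              length(x$values), x$bin_size, x$normalization, x$stat,
              x$library_size))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values))) {
    stop("coverage tracks are not on the same bin grid")
  }
}

#' Per-bin log2 ratio of two coverage tracks
#'
#' Used to compare, e.g., mutant against wild-type accessibility. Both
#' tracks must share the bin grid. A symmetric pseudocount keeps empty bins
#' at exactly 0.
#'
#' @param track_a,track_b `coverage_track` objects on the same grid.
#' @param pseudocount Added to both numerator and denominator; default 1.
#' @return A `coverage_track` of log2((a + eps) / (b + eps)) values.
#' @export
log2_ratio_track <- function(track_a, track_b, pseudocount = 1) {
  check_same_grid(track_a, track_b)
  vals <- mapply(function(a, b) log2((a + pseudocount) / (b + pseudocount)),
                 track_a$values, track_b$values, SIMPLIFY = FALSE)
  out <- track_a
  out$values <- vals
  out$normalization <- "log2_ratio"
  out
}

#' Extract a per-region signal matrix from a coverage track
#'
#' Two anchoring modes, mirroring standard heatmap layouts: `"center"`
#' extracts a fixed window around each region's anchor point (its midpoint,
#' or a `summit` offset column if present; TSS-style single-point regions
#' work naturally), and `"scale"` resamples each region to a fixed target
#' width (default 1000 bp) by linear interpolation. Rows of minus-strand
#' regions are reversed so that all rows read 5' to 3'. Positions outside
#' the chromosome are filled with `fill` (default 0), recorded in the
#' attributes.
#'
#' @param track A `coverage_track`.
#' @param regions BED-style data.frame; optional `strand`, `summit` columns.
#' @param anchor "center" or "scale".
#' @param window_bp Window width for center mode (default 2000).
#' @param target_width_bp Target width for scale mode (default 1000).
#' @param fill Fill value for out-of-bounds columns.
#' @return Numeric matrix, one row per region; attributes record the layout.
#' @export
region_matrix <- function(track, regions, anchor = c("center", "scale"),
                          window_bp = 2000L, target_width_bp = 1000L,
                          fill = 0) {
  anchor <- match.arg(anchor)
  bs <- track$bin_size
  n_cols <- if (anchor == "center") as.integer(window_bp / bs)
            else as.integer(target_width_bp / bs)
  out <- matrix(fill, nrow = nrow(regions), ncol = n_cols)
  strand <- if ("strand" %in% names(regions)) regions$strand else
    rep("+", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- track$values[[regions$chrom[i]]]
    if (is.null(v)) next
    if (anchor == "center") {
      mid <- if ("summit" %in% names(regions) && !is.na(regions$summit[i])) {
        regions$start[i] + regions$summit[i]
      } else (regions$start[i] + regions$end[i]) %/% 2
      first_bin <- floor((mid - window_bp / 2) / bs)
      idx <- first_bin + seq_len(n_cols)   # 0-based bin indices
      ok <- idx >= 0 & idx < length(v)
      row <- rep(fill, n_cols)
      row[ok] <- v[idx[ok] + 1L]
    } else {
      b0 <- floor(regions$start[i] / bs)
      b1 <- ceiling(regions$end[i] / bs) - 1L
      b0 <- max(b0, 0L); b1 <- min(b1, length(v) - 1L)
      src <- v[(b0:b1) + 1L]
      row <- if (length(src) == n_cols) src
             else if (length(src) < 2) rep(if (length(src)) src else fill, n_cols)
             else approx(seq_along(src), src, n = n_cols)$y
    }
    if (strand[i] == "-") row <- rev(row)
    out[i, ] <- row
  }
  if (!is.null(regions$name)) rownames(out) <- regions$name
  attr(out, "anchor") <- anchor
  attr(out, "bin_size") <- bs
  attr(out, "window_bp") <- if (anchor == "center") window_bp else target_width_bp
  attr(out, "fill") <- fill
  out
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start <- (nz - 1L) * track$bin_size
    end <- pmin(nz * track$bin_size, track$chrom_sizes[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom, start, end, v[nz]), con)
  }
  invisible(path)
}
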