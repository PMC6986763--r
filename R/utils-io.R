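#' @import methods
#' @importFrom stats median p.adjust pnorm ppois pt quantile rbinom rlnorm
#'   rnbinom rnorm rpois runif sd setNames var approx complete.cases
#'   fisher.test kmeans lm coef rank t.test wilcox.test rmultinom cor
#' @importFrom utils read.table write.table head combn
NULL

## Interval tables use BED conventions throughout: 0-based, half-open [start, end).
## GRanges (1-based, closed) are used internally for overlap machinery only.

#' Convert a BED-style interval table to GRanges
#'
#' Columns `chrom`, `start`, `end` (0-based half-open) are required; `strand`
#' and any other columns are carried over as metadata.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `strand`.
#' @return A [GenomicRanges::GRanges] object (1-based, closed coordinates).
#' @export
bed_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}

#' Convert GRanges back to a BED-style data.frame
#' @param gr A GRanges object.
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
granges_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' Read fragments or peaks from a BED file
#'
#' Accepts 3- to 6-column BED. Columns beyond the third are mapped to
#' `name`, `score`, `strand`.
#'
#' @param path Path to an uncompressed BED file.
#' @return data.frame with `chrom`, `start`, `end` and optional extra columns.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  if (ncol(df) < 3) stop("BED file must have at least 3 columns: ", path)
  bad <- !is.numeric(df[[2]]) | !is.numeric(df[[3]]) | df[[2]] >= df[[3]]
  if (any(bad)) {
    stop(sprintf("corrupt BED line %d in %s", which(bad)[1], path))
  }
  names(df)[1:3] <- c("chrom", "start", "end")
  extras <- c("name", "score", "strand")
  if (ncol(df) > 3) {
    names(df)[4:min(6, ncol(df))] <- extras[seq_len(min(3, ncol(df) - 3))]
  }
  df
}

#' Write a BED file
#' @param df data.frame with `chrom`, `start`, `end` plus optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  ## BED columns are positional: stop at the first missing one
  keep <- c("chrom", "start", "end")
  for (col in c("name", "score", "strand")) {
    if (col %in% cols) keep <- c(keep, col) else break
  }
  write.table(df[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "")
}

#' @export
write_tsv_table <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_as), df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Each output file of the generator gets its own RNG stream so that
#' regenerating one file never perturbs the others. The derivation is a
#' small stable hash of the label folded into the master seed, kept within
#' the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param label Character stream label.
#' @return An integer seed.
#' @export
stream_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, label))
  expr
}

#' Write a JSON run manifest
#' @param x Named list of run metadata (config, seed, file hashes ...).
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
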