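## PWM handling, best-hit scanning with exact score p-values, score binning
## against mutant effect, and presence/absence motif enrichment.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object from counts or probabilities
#'
#' Adds a pseudocount, normalises columns, and derives the log2-odds matrix
#' against the background. An N (or any unknown base) contributes zero
#' log-odds when scanning.
#'
#' @param counts 4 x width numeric matrix (rows A, C, G, T).
#' @param id,name Motif identifiers.
#' @param background Background base frequencies, default uniform.
#' @param pseudocount Added to every count, default 0.8 (0.2 per base per
#'   observation-equivalent).
#' @return Object of class `pwm`: probs, logodds, width, background,
#'   consensus.
#' @export
pwm_from_counts <- function(counts, id = "motif", name = id,
                            background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 3)
  rownames(counts) <- DNA_BASES
  probs <- sweep(counts + pseudocount / 4, 2,
                 colSums(counts + pseudocount / 4), "/")
  stopifnot(abs(colSums(probs) - 1) < 1e-6)
  lo <- log2(probs / background)
  consensus <- paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  structure(list(id = id, name = name, probs = probs, logodds = lo,
                 width = ncol(probs), background = background,
                 consensus = consensus),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s): width %d, consensus %s\n", x$id, x$name,
              x$width, x$consensus))
  invisible(x)
}

#' Read motifs in JASPAR text format
#'
#' Parses the ">ID name" header + 4 bracketed count rows layout.
#'
#' @param path Path to a JASPAR-format file.
#' @param ... Passed to [pwm_from_counts()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]]
    id <- hdr[1]; name <- if (length(hdr) > 1) hdr[2] else id
    rows <- lines[(s + 1):(s + 4)]
    counts <- t(vapply(rows, function(r) {
      nums <- sub("^[ACGTacgt]\\s*\\[", "", r)
      nums <- sub("\\].*$", "", nums)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(sub("\\].*$", "",
      sub("^[ACGTacgt]\\s*\\[", "", rows[1]))), "\\s+")[[1]]))))
    out[[id]] <- pwm_from_counts(counts, id = id, name = name, ...)
  }
  out
}

#' Read motifs in MEME text format
#'
#' Parses `MOTIF` blocks with letter-probability matrices.
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_line <- grep("^Background letter frequencies", lines)
  if (length(bg_line) && bg_line[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_line[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (sum(!is.na(vals)) == 4) bg <- vals[!is.na(vals)]
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- hdr[2]; name <- if (length(hdr) > 2) hdr[3] else id
    m <- s + 1
    while (m <= length(lines) && !grepl("letter-probability", lines[m])) m <- m + 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[m]))
    probs <- t(vapply(lines[(m + 1):(m + w)], function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    out[[id]] <- pwm_from_counts(t(probs) * 100, id = id, name = name,
                                 background = bg)
  }
  out
}

#' Built-in synthetic core-factor motifs
#'
#' Loads the synthetic POU-, SOX- and POU-SOX-composite-like matrices
#' shipped with the package. These are constructed stand-ins with the
#' structural character of the canonical published motifs (octamer-like,
#' HMG-box-like, and their composite), NOT copies of any database entry;
#' use them for simulation and tests.
#'
#' @return Named list of `pwm` objects.
#' @export
default_motifs <- function() {
  read_jaspar(system.file("extdata", "synthetic_core_motifs.jaspar",
                          package = "atacprime"))
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

## log-odds scores at every offset of one sequence (one strand);
## unknown bases contribute 0
scan_scores <- function(seq_chars, lo) {
  w <- ncol(lo)
  L <- length(seq_chars)
  if (L < w) return(numeric(0))
  idx <- match(seq_chars, DNA_BASES)   # NA for N
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    contrib <- ifelse(is.na(b), 0, lo[cbind(b, j)])
    sc <- sc + contrib
  }
  sc
}

#' Exact PWM score distribution under the background model
#'
#' Dynamic programming over positions on an integer-rounded score lattice
#' (granularity `granularity` log2-odds units): the exact null distribution
#' of single-offset scores used to convert scores to p-values.
#'
#' @param pwm A `pwm` object.
#' @param granularity Rounding step for the score lattice, default 0.01.
#' @return list: `score` (sorted support), `prob`, and `pvalue`
#'   (upper-tail P(S >= score)).
#' @export
pwm_score_distribution <- function(pwm, granularity = 0.01) {
  lat <- round(pwm$logodds / granularity)
  dist <- c(`0` = 1)
  for (j in seq_len(pwm$width)) {
    keys <- as.numeric(names(dist))
    new <- new.env(hash = TRUE)
    for (b in 1:4) {
      pv <- pwm$background[b]
      kk <- keys + lat[b, j]
      for (i in seq_along(kk)) {
        key <- as.character(kk[i])
        prev <- if (is.null(new[[key]])) 0 else new[[key]]
        new[[key]] <- prev + dist[[i]] * pv
      }
    }
    dist <- unlist(as.list(new))
  }
  score <- as.numeric(names(dist)) * granularity
  ord <- order(score)
  score <- score[ord]
  prob <- unname(dist[ord])
  pvalue <- rev(cumsum(rev(prob)))
  list(score = score, prob = prob, pvalue = pvalue,
       granularity = granularity)
}

score_to_pvalue <- function(dist, s) {
  ## P(S >= s) on the lattice; snap s down by half a granule for robustness
  vapply(s, function(x) {
    i <- findInterval(x - dist$granularity / 2, dist$score) + 1L
    if (i > length(dist$pvalue)) 0 else dist$pvalue[i]
  }, numeric(1))
}

#' Best PWM hit per sequence
#'
#' Scans both strands of each sequence at every offset with log2-odds
#' scores (N contributes 0) and keeps the per-sequence maximum. Hits are
#' flagged significant when the exact background p-value of the best score
#' is at most `p_threshold` (low-stringency 0.05 by default).
#'
#' @param sequences Character vector or `Biostrings::DNAStringSet` (e.g.
#'   200 bp summit-centered windows).
#' @param pwm A `pwm` object.
#' @param p_threshold Hit-calling threshold on the score p-value.
#' @return data.frame: seq_id, offset (0-based, on the forward strand),
#'   strand, score, p_value, hit.
#' @export
scan_best_hit <- function(sequences, pwm, p_threshold = 0.05) {
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (any(nchar(sequences) < pwm$width)) {
    stop("sequence shorter than motif width")
  }
  dist <- pwm_score_distribution(pwm)
  rows <- lapply(names(sequences), function(id) {
    fwd_chars <- strsplit(toupper(sequences[[id]]), "")[[1]]
    rev_chars <- strsplit(revcomp(toupper(sequences[[id]])), "")[[1]]
    sf <- scan_scores(fwd_chars, pwm$logodds)
    sr <- scan_scores(rev_chars, pwm$logodds)
    L <- length(fwd_chars)
    best_f <- which.max(sf); best_r <- which.max(sr)
    if (sf[best_f] >= sr[best_r]) {
      off <- best_f - 1L; strand <- "+"; sc <- sf[best_f]
    } else {
      ## offset reported on the forward strand
      off <- L - pwm$width - (best_r - 1L); strand <- "-"; sc <- sr[best_r]
    }
    data.frame(seq_id = id, offset = off, strand = strand, score = sc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- score_to_pvalue(dist, out$score)
  out$hit <- out$p_value <= p_threshold
  rownames(out) <- NULL
  out
}

#' Mutant effect across motif-score bins
#'
#' Divides best-hit motif scores into `n_bins` equal-frequency bins (10 by
#' default, low to high) and summarises the distribution of mutant
#' accessibility log2FC per bin.
#'
#' @param scores Best-hit score per region.
#' @param mutant_log2fc Aligned per-region log2FC.
#' @param n_bins Default 10.
#' @return list: `bin` per region, `summary` (bin, n, median, mean).
#' @export
score_bins_vs_effect <- function(scores, mutant_log2fc, n_bins = 10L) {
  stopifnot(length(scores) == length(mutant_log2fc))
  if (length(scores) < n_bins) stop("fewer regions than bins")
  bin <- quintile_bins(scores, n_bins)
  summary <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    median = vapply(seq_len(n_bins), function(b)
      median(mutant_log2fc[bin == b]), numeric(1)),
    mean = vapply(seq_len(n_bins), function(b)
      mean(mutant_log2fc[bin == b]), numeric(1)))
  list(bin = bin, summary = summary)
}

#' Motif enrichment in top-opening regions
#'
#' Regions are sorted by accessibility increase and the top fraction (20%
#' by default) forms the foreground; the background is either supplied or
#' the remaining regions. Each motif is tested for presence/absence
#' enrichment (>= 1 hit at `p_threshold`) with a one-sided Fisher exact
#' test, BH-adjusted across motifs. With a `families` map, a family-level
#' summary reports the minimal adjusted p-value and the maximal foreground
#' hit percentage per family.
#'
#' @param delta_access Accessibility increase per region.
#' @param sequences Aligned sequences (character or DNAStringSet).
#' @param pwms Named list of `pwm` objects.
#' @param top_fraction Foreground fraction, default 0.20.
#' @param background_sequences Optional explicit background set.
#' @param p_threshold Hit-calling threshold, default 0.05.
#' @param families Optional named character vector motif id -> family.
#' @return list: `table` (per-motif counts, fractions, odds ratio, p,
#'   adjusted p, ordered by p), `family` summary or NULL.
#' @export
enrichment_top_regions <- function(delta_access, sequences, pwms,
                                   top_fraction = 0.20,
                                   background_sequences = NULL,
                                   p_threshold = 0.05, families = NULL) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  stopifnot(length(delta_access) == length(sequences))
  n_top <- max(1L, floor(length(sequences) * top_fraction))
  ord <- order(delta_access, decreasing = TRUE)
  fg <- sequences[ord[seq_len(n_top)]]
  bg <- if (is.null(background_sequences)) sequences[ord[-seq_len(n_top)]]
        else {
          if (inherits(background_sequences, "DNAStringSet"))
            background_sequences <- as.character(background_sequences)
          background_sequences
        }
  if (!length(fg)) stop("empty foreground")
  if (length(bg) < length(fg)) {
    stop("need at least one background region per foreground region")
  }
  ## presence calls use a sequence-level p-value: the best-hit position
  ## p corrected for the number of scanned offsets on both strands, so a
  ## random sequence is not a "hit" merely by length
  seq_hits <- function(seqs, pwm) {
    h <- scan_best_hit(seqs, pwm, p_threshold)
    n_off <- 2 * (nchar(seqs) - pwm$width + 1)
    sum((1 - (1 - h$p_value)^n_off) <= p_threshold)
  }
  tab <- do.call(rbind, lapply(names(pwms), function(id) {
    fh <- seq_hits(fg, pwms[[id]])
    bh <- seq_hits(bg, pwms[[id]])
    m <- matrix(c(fh, length(fg) - fh, bh, length(bg) - bh), 2)
    ft <- fisher.test(m, alternative = "greater")
    data.frame(motif = id, fg_hits = fh, fg_n = length(fg),
               bg_hits = bh, bg_n = length(bg),
               fg_fraction = fh / length(fg), bg_fraction = bh / length(bg),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  tab$q_value <- p.adjust(tab$p_value, "BH")
  tab <- tab[order(tab$p_value), ]
  rownames(tab) <- NULL
  fam <- NULL
  if (!is.null(families)) {
    tab$family <- unname(families[tab$motif])
    fam <- do.call(rbind, lapply(split(tab, tab$family), function(d)
      data.frame(family = d$family[1], min_q = min(d$q_value),
                 max_fg_percent = 100 * max(d$fg_fraction),
                 stringsAsFactors = FALSE)))
    rownames(fam) <- NULL
  }
  list(table = tab, family = fam)
}
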