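## Independent brute-force oracles and small fixture generators. These stay
## deliberately naive (double loops, full enumeration) so they cannot share
## a bug with the implementations they check.

bf_overlaps <- function(s1, e1, s2, e2) {
  ## >= 1 shared base under half-open arithmetic
  max(s1, s2) < min(e1, e2)
}

## all-pairs fragment-over-peak counting
bf_count_overlaps <- function(peaks, frags) {
  out <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(frags))) {
      if (peaks$chrom[i] == frags$chrom[j] &&
          bf_overlaps(peaks$start[i], peaks$end[i],
                      frags$start[j], frags$end[j])) {
        out[i] <- out[i] + 1L
      }
    }
  }
  out
}

## consensus merging as connected components of the >=1 bp-overlap graph
bf_consensus <- function(df) {
  n <- nrow(df)
  if (!n) return(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- df$chrom[i] == df$chrom[j] &&
      bf_overlaps(df$start[i], df$end[i], df$start[j], df$end[j])
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    d <- df[comp == cc, , drop = FALSE]
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## trajectory archetypes with distinct positive early increases, for the
## priming power analyses (linear ramps: increase from stage 1 to stage 3
## equals the stated delta)
ramp_profiles <- function(n_stages, deltas = c(8, 5, 3, 1.5, 0.6)) {
  t(vapply(deltas, function(d)
    1 + d * (seq_len(n_stages) - 1) / 2, numeric(n_stages)))
}

## nearest-TSS search with the same distance convention, by full scan
bf_nearest_tss <- function(el, tss, link_max) {
  best <- NULL
  for (j in seq_len(nrow(tss))) {
    if (tss$chrom[j] != el$chrom) next
    p <- tss$pos[j]
    d <- if (p >= el$start && p < el$end) 0
         else if (p < el$start) el$start - p else p - (el$end - 1)
    if (is.null(best) || d < best$d ||
        (d == best$d && (tss$pos[j] < best$pos ||
                         (tss$pos[j] == best$pos &&
                          tss$gene_id[j] < best$gene)))) {
      best <- list(d = d, gene = tss$gene_id[j], pos = tss$pos[j])
    }
  }
  if (is.null(best) || best$d > link_max) NULL else best
}

## quantile binning straight from the empirical CDF of strictly-smaller counts
bf_quantile_bin <- function(v, nq) {
  n <- length(v)
  vapply(v, function(x) min(floor(sum(v < x) * (nq + 1) / n), nq), numeric(1))
}

## exhaustive PWM scan over offsets x strands
bf_scan_pwm <- function(seq, pwm) {
  score_at <- function(chars) {
    w <- pwm$width
    best <- -Inf; best_off <- NA
    for (o in 0:(length(chars) - w)) {
      sc <- 0
      for (j in 1:w) {
        b <- match(chars[o + j], c("A", "C", "G", "T"))
        sc <- sc + if (is.na(b)) 0 else unname(pwm$logodds[b, j])
      }
      if (sc > best) { best <- sc; best_off <- o }
    }
    list(score = best, offset = best_off)
  }
  fwd <- score_at(strsplit(seq, "")[[1]])
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
  rev_ <- score_at(strsplit(rc, "")[[1]])
  if (fwd$score >= rev_$score) {
    list(score = fwd$score, strand = "+", offset = fwd$offset)
  } else {
    list(score = rev_$score, strand = "-",
         offset = nchar(seq) - pwm$width - rev_$offset)
  }
}

## random fixtures ------------------------------------------------------------

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                           max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## minimal coverage_track constructor for hand-built bin vectors
toy_track <- function(values, bin_size = 10L, library_size = 1e6,
                      stat = "fragment_count", normalization = "raw") {
  if (!is.list(values)) values <- list(chr1 = values)
  structure(list(values = lapply(values, as.numeric),
                 bin_size = as.integer(bin_size),
                 chrom_sizes = setNames(lengths(values) * bin_size,
                                        names(values)),
                 normalization = normalization, stat = stat,
                 library_size = library_size),
            class = "coverage_track")
}

tiny_config <- function(seed = 1L, fragment_depth = 30000, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 400000L,
             n_genes = 12L, n_regions = 24L,
             fragment_depth = fragment_depth, ...)
}
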