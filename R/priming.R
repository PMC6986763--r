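## Priming statistics: quintile binning of accessibility increase against
## later expression, the 5x5 increase-by-mutant-effect grid, TF-binding
## enrichment by mutant-effect bin, and the supporting rank/ t tests.

#' Equal-frequency quantile bins with deterministic tie handling
#'
#' Items are stably sorted by (value, id) and split positionally into
#' `n_bins` groups whose sizes differ by at most one, so the binning is
#' invariant to input order. Bin 1 holds the smallest values.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins, default 5 (20% quintiles).
#' @param ids Optional unique ids used as tie-break; defaults to position.
#' @return Integer vector of bin indices 1..n_bins, attribute `edges` gives
#'   the interior cut values.
#' @export
quintile_bins <- function(x, n_bins = 5L, ids = NULL) {
  n <- length(x)
  if (n < n_bins) stop("fewer items than bins")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(x, ids)
  bin_sorted <- as.integer(floor((seq_len(n) - 1) * n_bins / n)) + 1L
  out <- integer(n)
  out[ord] <- bin_sorted
  edges <- vapply(seq_len(n_bins - 1L), function(b)
    max(x[out == b]), numeric(1))
  attr(out, "edges") <- edges
  out
}

#' One-sided Wilcoxon rank-sum test
#'
#' Rank-sum test of `a` against `b`. For small samples (both n <= 8) the
#' p-value is computed by exact enumeration of all rank assignments (valid
#' under ties); otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @param alternative "greater" (a tends larger than b) or "less".
#' @return list of class `group_comparison`: statistic (Mann-Whitney U of
#'   `a`), p_value, alternative, method, n.
#' @export
wilcoxon_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); n <- na + nb
  comb <- c(a, b)
  r <- rank(comb)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(comb)) == 1L) {
    warning("all values tied across both samples")
    return(structure(list(statistic = U, p_value = 1,
                          alternative = alternative,
                          method = "degenerate", n = c(na, nb)),
                     class = "group_comparison"))
  }
  if (na <= 8 && nb <= 8) {
    idx <- combn(n, na)
    us <- apply(idx, 2, function(j) sum(r[j])) - na * (na + 1) / 2
    p <- if (alternative == "greater") mean(us >= U) else mean(us <= U)
    method <- "exact enumeration"
  } else {
    ties <- table(comb)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p <- if (alternative == "greater") {
      pnorm((U - 0.5 - mu) / sigma, lower.tail = FALSE)
    } else {
      pnorm((U + 0.5 - mu) / sigma)
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = U, p_value = min(max(p, .Machine$double.xmin), 1),
                 alternative = alternative, method = method, n = c(na, nb)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alternative: %s; n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Later expression across quintiles of prior accessibility increase
#'
#' Elements are sorted into 20% quintiles of their accessibility increase;
#' the outcome (expression of the linked gene at a later stage) is
#' summarised per bin, and adjacent bins (plus bin 1 vs bin 5) are compared
#' with one-sided Wilcoxon tests under the alternative that higher-increase
#' bins have stochastically greater outcomes.
#'
#' @param delta_access Accessibility increase per element.
#' @param outcome Later-stage expression of the linked gene, aligned with
#'   `delta_access` (genes linked to several elements repeat).
#' @param n_bins Number of quantile bins, default 5.
#' @param min_items Refuse fewer items than this, default 10.
#' @return list: `bin` (per-item index), `summary` (per-bin n, median,
#'   mean), `tests` (data.frame of one-sided Wilcoxon comparisons).
#' @export
quintile_outcome <- function(delta_access, outcome, n_bins = 5L,
                             min_items = 10L) {
  stopifnot(length(delta_access) == length(outcome))
  if (length(delta_access) < min_items) {
    stop("too few items (", length(delta_access), ") for quantile binning")
  }
  bin <- quintile_bins(delta_access, n_bins)
  summary <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    median = vapply(seq_len(n_bins), function(b) median(outcome[bin == b]),
                    numeric(1)),
    mean = vapply(seq_len(n_bins), function(b) mean(outcome[bin == b]),
                  numeric(1)))
  pairs <- rbind(cbind(seq_len(n_bins - 1L) + 1L, seq_len(n_bins - 1L)),
                 c(n_bins, 1L))
  tests <- data.frame(
    higher_bin = pairs[, 1], lower_bin = pairs[, 2],
    p_value = apply(pairs, 1, function(pr)
      wilcoxon_one_sided(outcome[bin == pr[1]], outcome[bin == pr[2]],
                         "greater")$p_value))
  list(bin = bin, summary = summary, tests = tests)
}

#' Priming grid: outcome by accessibility increase and mutant effect
#'
#' Bins elements independently into 20% quantiles of (i) accessibility
#' increase (columns, ascending: column 5 = largest increase) and (ii)
#' accessibility change in TF mutants (rows, ascending log2FC: row 1 =
#' largest loss), and aggregates the outcome per cell with the median (or
#' the mean of z-scored values for signal variants such as H3K27ac, where
#' the signal is z-scored across all elements before averaging). Empty
#' cells are NA, not zero.
#'
#' @param delta_access Accessibility increase per element (column axis).
#' @param mutant_log2fc Mutant-vs-wild-type log2 fold change per element
#'   (row axis); for several mutants pass the per-element average
#'   (see [average_mutant_effect()]).
#' @param outcome Outcome per element (linked-gene expression or a signal).
#' @param statistic "median" or "mean_z".
#' @param n_bins Bins per axis, default 5.
#' @return list: `grid` (n_bins x n_bins), `n` (cell counts),
#'   `row_bins`/`col_bins` per item.
#' @export
priming_grid <- function(delta_access, mutant_log2fc, outcome,
                         statistic = c("median", "mean_z"), n_bins = 5L) {
  statistic <- match.arg(statistic)
  stopifnot(length(delta_access) == length(outcome),
            length(mutant_log2fc) == length(outcome))
  col_bin <- quintile_bins(delta_access, n_bins)
  row_bin <- quintile_bins(mutant_log2fc, n_bins)
  y <- if (statistic == "mean_z") (outcome - mean(outcome)) / sd(outcome)
       else outcome
  grid <- matrix(NA_real_, n_bins, n_bins,
                 dimnames = list(mutant_effect = paste0("loss_bin", seq_len(n_bins)),
                                 increase = paste0("incr_bin", seq_len(n_bins))))
  n <- matrix(0L, n_bins, n_bins, dimnames = dimnames(grid))
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    sel <- row_bin == i & col_bin == j
    n[i, j] <- sum(sel)
    if (any(sel)) {
      grid[i, j] <- if (statistic == "median") median(y[sel]) else mean(y[sel])
    }
  }
  list(grid = grid, n = n, row_bins = row_bin, col_bins = col_bin,
       statistic = statistic)
}

#' Average per-element mutant effect over several mutants
#'
#' @param lfc_matrix Elements x mutants log2FC matrix.
#' @param method "mean" (default) or "min" (strongest loss).
#' @return Numeric vector per element.
#' @export
average_mutant_effect <- function(lfc_matrix, method = c("mean", "min")) {
  method <- match.arg(method)
  m <- as.matrix(lfc_matrix)
  if (method == "mean") rowMeans(m) else apply(m, 1, min)
}

#' TF-binding signal across mutant-effect quintiles
#'
#' Elements are binned into 20% quintiles of mutant accessibility change
#' (bin 1 = greatest loss). ChIP signal is normalized either as ChIP/Input
#' or against the genome-wide mean (for factors without an input sample),
#' and summarised per bin; adjacent bins are compared with one-sided
#' Wilcoxon tests under the alternative that greater-loss bins carry higher
#' signal.
#'
#' @param mutant_log2fc Per-element mutant log2FC.
#' @param chip Per-element ChIP signal (vector, or matrix with one column
#'   per TF).
#' @param input Matching input signal, required for "chip_over_input".
#' @param normalization "chip_over_input" or "genome_mean".
#' @param n_bins Default 5.
#' @return list: `bin` per element, `summary` (TF x bin medians), `tests`.
#' @export
tf_enrichment_by_bin <- function(mutant_log2fc, chip, input = NULL,
                                 normalization = c("chip_over_input",
                                                   "genome_mean"),
                                 n_bins = 5L) {
  normalization <- match.arg(normalization)
  chip <- as.matrix(chip)
  if (is.null(colnames(chip))) colnames(chip) <- paste0("TF", seq_len(ncol(chip)))
  if (normalization == "chip_over_input") {
    if (is.null(input)) {
      stop("no input signal available; use normalization = \"genome_mean\"")
    }
    sig <- chip / as.matrix(input)
  } else {
    sig <- sweep(chip, 2, colMeans(chip), "/")
  }
  bin <- quintile_bins(mutant_log2fc, n_bins)
  summary <- do.call(rbind, lapply(colnames(sig), function(tf) {
    data.frame(tf = tf, bin = seq_len(n_bins),
               n = as.integer(tabulate(bin, n_bins)),
               median = vapply(seq_len(n_bins), function(b)
                 median(sig[bin == b, tf]), numeric(1)))
  }))
  tests <- do.call(rbind, lapply(colnames(sig), function(tf) {
    do.call(rbind, lapply(seq_len(n_bins - 1L), function(b) {
      data.frame(tf = tf, greater_loss_bin = b, other_bin = b + 1L,
                 p_value = wilcoxon_one_sided(sig[bin == b, tf],
                                              sig[bin == b + 1L, tf],
                                              "greater")$p_value)
    }))
  }))
  list(bin = bin, summary = summary, tests = tests,
       normalization = normalization)
}

#' Mutant effect at elements of regulated vs non-regulated genes
#'
#' Two-sample Welch t-test comparing element-level mutant log2FC between
#' elements linked to TF-regulated genes and all other elements.
#'
#' @param mutant_log2fc Per-element log2FC.
#' @param regulated Logical per element: linked gene is downregulated upon
#'   TF loss.
#' @param alternative Passed to [stats::t.test()]; default "two.sided".
#' @return `group_comparison` with the Welch statistic, df and p-value.
#' @export
mutant_effect_by_target <- function(mutant_log2fc, regulated,
                                    alternative = "two.sided") {
  stopifnot(length(mutant_log2fc) == length(regulated))
  if (sum(regulated) < 2 || sum(!regulated) < 2) {
    stop("each gene class needs >= 2 elements for a Welch t-test")
  }
  tt <- t.test(mutant_log2fc[regulated], mutant_log2fc[!regulated],
               var.equal = FALSE, alternative = alternative)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, alternative = alternative,
                 method = "Welch two-sample t-test",
                 n = c(sum(regulated), sum(!regulated)),
                 mean_regulated = mean(mutant_log2fc[regulated]),
                 mean_other = mean(mutant_log2fc[!regulated])),
            class = "group_comparison")
}

#' Mutant effect by bound-TF combination
#'
#' Splits elements by which core factors bind them (the 7 non-empty subsets
#' of Pou5f3/Sox19b/Nanog plus "unbound") and summarises the mutant log2FC
#' distribution per combination. Each bound combination is compared with
#' the unbound reference by a one-sided Wilcoxon test (alternative: bound
#' sites lose more accessibility).
#'
#' @param mutant_log2fc Per-element log2FC.
#' @param bound_by Character per element: comma-separated core-TF names
#'   ("" = unbound).
#' @param core_tfs Factor names defining the combination universe.
#' @return list: `summary` (combination, n, median), `tests` (combination
#'   vs unbound). Empty combinations are skipped and listed in `skipped`.
#' @export
bound_site_effect_by_combination <- function(mutant_log2fc, bound_by,
                                             core_tfs = CORE_TFS) {
  stopifnot(length(mutant_log2fc) == length(bound_by))
  norm_combo <- function(s) {
    tfs <- intersect(core_tfs, strsplit(s, ",")[[1]])
    if (!length(tfs)) "unbound" else paste(tfs, collapse = "+")
  }
  combo <- vapply(bound_by, norm_combo, character(1), USE.NAMES = FALSE)
  all_subsets <- unlist(lapply(seq_along(core_tfs), function(m)
    apply(combn(core_tfs, m), 2, paste, collapse = "+")))
  levels <- c(all_subsets, "unbound")
  present <- levels[levels %in% combo]
  skipped <- setdiff(all_subsets, present)
  summary <- do.call(rbind, lapply(present, function(g) {
    v <- mutant_log2fc[combo == g]
    data.frame(combination = g, n = length(v), median = median(v),
               mean = mean(v), stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if ("unbound" %in% present) {
    ref <- mutant_log2fc[combo == "unbound"]
    tests <- do.call(rbind, lapply(setdiff(present, "unbound"), function(g) {
      data.frame(combination = g, reference = "unbound",
                 p_value = wilcoxon_one_sided(mutant_log2fc[combo == g], ref,
                                              "less")$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(combination = combo, summary = summary, tests = tests,
       skipped = skipped)
}
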