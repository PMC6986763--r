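## NFR fragment counting over consensus peaks, FPKM, and negative-binomial
## differential accessibility with total-fragment-count size factors.

#' Count nucleosome-free fragments over consensus peaks
#'
#' A fragment increments a peak iff it overlaps it by >= 1 bp; a fragment
#' spanning two peaks increments both. Only fragments with length
#' `<= nfr_cutoff` (130 bp default) are counted, but the per-sample library
#' size recorded for size factors is the TOTAL fragment count of the sample.
#' The peak set must be non-overlapping (consensus contract).
#'
#' @param peaks Non-overlapping peak table (chrom, start, end, name).
#' @param fragment_sets Named list of per-sample fragment tables.
#' @param nfr_cutoff Fragment-length cutoff in bp; `Inf` to count all.
#' @return Integer matrix peaks x samples with attribute `library_sizes`
#'   (total fragments per sample) and `widths` (peak widths in bp).
#' @export
count_over_peaks <- function(peaks, fragment_sets, nfr_cutoff = 130L) {
  stopifnot(is.list(fragment_sets), !is.null(names(fragment_sets)))
  pk_gr <- bed_to_granges(peaks[c("chrom", "start", "end")])
  if (nrow(peaks) > 1 &&
      any(IRanges::countOverlaps(pk_gr, pk_gr, ignore.strand = TRUE) > 1)) {
    stop("peak set contains overlapping intervals; expected a consensus set")
  }
  counts <- vapply(fragment_sets, function(fr) {
    len <- if ("length" %in% names(fr)) fr$length else fr$end - fr$start
    fr <- fr[len <= nfr_cutoff, , drop = FALSE]
    if (!nrow(fr)) return(integer(nrow(peaks)))
    IRanges::countOverlaps(pk_gr, bed_to_granges(fr[c("chrom", "start", "end")]),
                           ignore.strand = TRUE)
  }, integer(nrow(peaks)))
  counts <- matrix(counts, nrow = nrow(peaks),
                   dimnames = list(peaks$name, names(fragment_sets)))
  attr(counts, "library_sizes") <-
    vapply(fragment_sets, nrow, integer(1))
  attr(counts, "widths") <- setNames(peaks$end - peaks$start, peaks$name)
  counts
}

#' Fragments per kilobase per million (FPKM)
#'
#' value = count / (peak width in kb) / (library size in millions). With a
#' `stage_map` the per-replicate FPKM columns are averaged into per-stage
#' columns.
#'
#' @param counts Count matrix from [count_over_peaks()] (or any matrix).
#' @param widths Peak widths in bp; taken from the matrix attribute if NULL.
#' @param library_sizes Per-sample total fragments; attribute if NULL.
#' @param stage_map Optional character vector mapping each column to a stage
#'   label; replicate columns of the same stage are averaged.
#' @return Numeric FPKM matrix.
#' @export
fpkm <- function(counts, widths = NULL, library_sizes = NULL,
                 stage_map = NULL) {
  if (is.null(widths)) widths <- attr(counts, "widths")
  if (is.null(library_sizes)) library_sizes <- attr(counts, "library_sizes")
  stopifnot(all(widths > 0))
  if (any(library_sizes <= 0)) stop("zero library size")
  x <- sweep(counts, 1, widths / 1000, "/")
  x <- sweep(x, 2, library_sizes / 1e6, "/")
  if (!is.null(stage_map)) {
    stopifnot(length(stage_map) == ncol(x))
    stages <- unique(stage_map)
    x <- vapply(stages, function(s)
      rowMeans(x[, stage_map == s, drop = FALSE]), numeric(nrow(x)))
    x <- matrix(x, nrow = nrow(counts),
                dimnames = list(rownames(counts), stages))
  }
  x
}

## --- negative-binomial differential test ------------------------------------

## IRLS fit of log mu = b0 + b1 * x + log(sf) with fixed NB dispersion alpha.
nb_irls <- function(k, sf, x, alpha, max_iter = 25L, tol = 1e-8) {
  X <- cbind(1, x)
  ## moment start from per-group ratio estimators
  q0 <- sum(k[x == 0]) / sum(sf[x == 0])
  q1 <- sum(k[x == 1]) / sum(sf[x == 1])
  b <- c(log(max(q0, 1e-8)), log(max(q1, 1e-8)) - log(max(q0, 1e-8)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b) + log(sf)
    mu <- pmin(exp(eta), 1e12)
    W <- mu / (1 + alpha * mu)
    z <- (eta - log(sf)) + (k - mu) / mu
    XtW <- t(X * W)
    b_new <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(b_new)) break
    if (max(abs(b_new - b)) < tol) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  eta <- drop(X %*% b) + log(sf)
  mu <- pmin(exp(eta), 1e12)
  W <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e)
    matrix(NA_real_, 2, 2))
  list(beta = b, se = sqrt(diag(cov)))
}

#' Differential accessibility between two conditions
#'
#' Negative-binomial test per peak. Size factors default to the per-sample
#' total fragment count (rescaled to geometric mean 1 so fold changes stay
#' on the per-fragment scale). Dispersions are estimated per peak by method
#' of moments, a mean-dispersion trend a0 + a1/mean is fitted across peaks,
#' and per-peak estimates are shrunk toward the trend in log space. The
#' condition coefficient is tested with a Wald statistic referred to a t
#' distribution whose degrees of freedom add the dispersion prior df to the
#' residual df (moderated-test convention), which keeps the type-I error
#' near nominal in small designs. Calls use
#' |log2FC| >= `lfc_threshold` at BH `fdr` ("two_sided" mode) or only the
#' decrease side ("decrease_only").
#'
#' @param counts Integer matrix peaks x samples.
#' @param condition Factor/character of length ncol(counts); the FIRST level
#'   is the reference (wild-type / untreated), so depletion in the second
#'   level gives negative log2FC.
#' @param size_factors Per-sample size factors; default attribute
#'   `library_sizes` of `counts` (total fragment counts).
#' @param lfc_threshold Absolute log2 fold-change call threshold, default 1.5.
#' @param fdr BH threshold, default 0.05.
#' @param mode "two_sided" or "decrease_only".
#' @return data.frame with peak, base_mean, log2_fold_change, se, dispersion,
#'   p_value, q_value, call. Peaks with zero counts everywhere are excluded;
#'   their ids are in attribute `excluded`.
#' @export
differential_accessibility <- function(counts, condition,
                                       size_factors = NULL,
                                       lfc_threshold = 1.5, fdr = 0.05,
                                       mode = c("two_sided", "decrease_only")) {
  mode <- match.arg(mode)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2, length(condition) == ncol(counts))
  if (is.null(size_factors)) size_factors <- attr(counts, "library_sizes")
  if (is.null(size_factors)) stop("size_factors required (no library_sizes attribute)")
  stopifnot(all(size_factors > 0), length(size_factors) == ncol(counts))
  sf <- size_factors / exp(mean(log(size_factors)))
  x <- as.integer(condition == levels(condition)[2])
  n <- ncol(counts)
  if (min(table(condition)) < 2) {
    warning("a condition has a single sample; dispersion is pooled across peaks")
  }

  keep <- rowSums(counts) > 0
  excluded <- rownames(counts)[!keep]
  k <- counts[keep, , drop = FALSE]
  if (is.null(rownames(k))) rownames(k) <- paste0("peak_", which(keep))

  ## normalized counts and method-of-moments dispersion
  y <- sweep(k, 2, sf, "/")
  mu_cond <- cbind(rowMeans(y[, x == 0, drop = FALSE]),
                   rowMeans(y[, x == 1, drop = FALSE]))
  fitted_y <- mu_cond[, x + 1, drop = FALSE]
  df_res <- n - 2L
  s2 <- rowSums((y - fitted_y)^2) / max(df_res, 1)
  base_mean <- rowMeans(y)
  shot <- base_mean * mean(1 / sf)
  disp_mom <- pmin(pmax((s2 - shot) / pmax(base_mean, 1e-8)^2, 1e-8), 10)

  ## mean-dispersion trend: alpha(mu) = a0 + a1/mu, fitted robustly by
  ## one reweighted pass that discards extreme per-peak estimates
  trend_at <- function(mu) rep(mean(disp_mom), length(mu))
  use <- base_mean > 0.5 & disp_mom > 1e-7
  if (sum(use) >= 10) {
    fit <- lm(disp_mom[use] ~ I(1 / base_mean[use]))
    r <- abs(stats::residuals(fit))
    keep2 <- r <= quantile(r, 0.9)
    fit <- lm(disp_mom[use][keep2] ~ I(1 / base_mean[use][keep2]))
    a0 <- max(coef(fit)[1], 1e-6); a1 <- max(coef(fit)[2], 0)
    trend_at <- function(mu) a0 + a1 / pmax(mu, 1e-8)
  }
  disp_trend <- trend_at(base_mean)
  ## log-space shrinkage: residual df against a fixed prior weight; the
  ## prior df also widens the Wald reference distribution below
  w_prior <- 3
  disp <- exp((df_res * log(pmax(disp_mom, disp_trend / 100)) +
                 w_prior * log(disp_trend)) / (df_res + w_prior))

  res <- matrix(NA_real_, nrow(k), 2)
  for (i in seq_len(nrow(k))) {
    f <- nb_irls(k[i, ], sf, x, disp[i])
    res[i, ] <- c(f$beta[2], f$se[2])
  }
  lfc <- res[, 1] / log(2)
  se_lfc <- res[, 2] / log(2)
  tstat <- res[, 1] / res[, 2]
  ## moderated reference: residual df plus the dispersion prior df
  p <- 2 * pt(-abs(tstat), df = max(df_res, 1) + w_prior)
  q <- p.adjust(p, method = "BH")
  call <- rep("unaffected", nrow(k))
  call[!is.na(q) & q < fdr & lfc <= -lfc_threshold] <- "decrease"
  if (mode == "two_sided") {
    call[!is.na(q) & q < fdr & lfc >= lfc_threshold] <- "increase"
  }
  out <- data.frame(
    peak = rownames(k), base_mean = base_mean,
    log2_fold_change = lfc, se = se_lfc, dispersion = disp,
    p_value = p, q_value = q, call = call,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "reference_level") <- levels(condition)[1]
  out
}

#' Volcano-style summary table
#'
#' Convenience join of a differential result with per-peak TF-binding
#' annotation, the table behind volcano plots of mutant effects.
#'
#' @param diff_result Output of [differential_accessibility()].
#' @param bound_by Optional named character vector (peak -> comma-separated
#'   TF list; "" for unbound).
#' @return data.frame with log2FC, -log10 q and `bound_by` columns.
#' @export
volcano_table <- function(diff_result, bound_by = NULL) {
  out <- data.frame(
    peak = diff_result$peak,
    log2_fold_change = diff_result$log2_fold_change,
    neg_log10_q = -log10(pmax(diff_result$q_value, 1e-300)),
    call = diff_result$call, stringsAsFactors = FALSE)
  out$bound_by <- if (is.null(bound_by)) "" else
    unname(bound_by[match(out$peak, names(bound_by))])
  out$bound_by[is.na(out$bound_by)] <- ""
  out
}
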