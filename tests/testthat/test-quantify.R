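test_that("counting respects the >= 1 bp rule and the NFR length filter", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 400L),
                      end = c(300L, 600L), name = c("p1", "p2"))
  frags <- data.frame(
    chrom = "chr1",
    start = c(150L, 250L, 250L, 500L),
    end = c(250L, 381L, 450L, 630L))   # lengths 100, 131, 200, 130
  counts <- count_over_peaks(peaks, list(s1 = frags), nfr_cutoff = 130)
  ## fully inside -> +1; length 131 -> excluded; spanning fragment would hit
  ## both, but it is 200 bp so also excluded; 130 bp fragment counted
  expect_equal(unname(counts[, "s1"]), c(1L, 1L))
  ## library size records ALL fragments, not only NFR
  expect_equal(unname(attr(counts, "library_sizes")["s1"]), 4L)
  ## spanning fragment increments both peaks when within the cutoff
  counts2 <- count_over_peaks(peaks, list(s1 = frags), nfr_cutoff = Inf)
  expect_equal(unname(counts2[, "s1"]), c(3L, 2L))
})

test_that("counting matches the all-pairs brute-force oracle", {
  set.seed(5)
  for (i in 1:8) {
    peaks <- bf_consensus(rand_intervals(12))   # non-overlapping set
    peaks$name <- paste0("pk", seq_len(nrow(peaks)))
    frags <- rand_intervals(60)
    counts <- count_over_peaks(peaks, list(a = frags), nfr_cutoff = Inf)
    expect_equal(unname(counts[, "a"]), bf_count_overlaps(peaks, frags))
  }
})

test_that("overlapping peak sets are rejected", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 150L),
                      end = c(300L, 400L), name = c("a", "b"))
  fr <- data.frame(chrom = "chr1", start = 1L, end = 50L)
  expect_error(count_over_peaks(peaks, list(x = fr)), "overlap")
})

test_that("FPKM follows its closed form and invariances", {
  counts <- matrix(c(10L, 20L), 1, 2, dimnames = list("pk", c("a", "b")))
  f <- fpkm(counts, widths = 1000, library_sizes = c(a = 1e6, b = 1e6))
  expect_equal(unname(f[1, ]), c(10, 20))
  ## joint doubling leaves FPKM unchanged
  f2 <- fpkm(counts * 2L, widths = 1000, library_sizes = c(a = 2e6, b = 2e6))
  expect_equal(f, f2)
  ## replicate averaging equals the mean of per-replicate FPKM
  cm <- matrix(c(10L, 30L, 6L), 1, 3,
               dimnames = list("pk", c("s1_r1", "s1_r2", "s2_r1")))
  fs <- fpkm(cm, widths = 500, library_sizes = c(2e6, 2e6, 1e6),
             stage_map = c("s1", "s1", "s2"))
  by_rep <- fpkm(cm, widths = 500, library_sizes = c(2e6, 2e6, 1e6))
  expect_equal(unname(fs[, "s1"]), mean(by_rep[1, 1:2]))
  expect_error(fpkm(cm, widths = 500, library_sizes = c(0, 1, 1)), "library")
})

test_that("differential test honors sign convention and label symmetry", {
  set.seed(2)
  n <- 300
  mu <- exp(runif(n, log(30), log(400)))
  k <- matrix(rnbinom(4 * n, mu = rep(mu, 4), size = 25), n, 4,
              dimnames = list(paste0("pk", 1:n), NULL))
  ## plant depletion in condition B for the first 50 peaks
  k[1:50, 3:4] <- rnbinom(100, mu = rep(mu[1:50] / 8, 2), size = 25)
  cond <- factor(c("wt", "wt", "mut", "mut"), levels = c("wt", "mut"))
  d <- differential_accessibility(k, cond, size_factors = rep(1, 4))
  expect_true(mean(d$log2_fold_change[1:50]) < -2)   # depletion -> negative
  ## swapping labels negates the fold change and preserves p-values
  d2 <- differential_accessibility(k, factor(as.character(cond),
                                             levels = c("mut", "wt")),
                                   size_factors = rep(1, 4))
  expect_equal(d$log2_fold_change, -d2$log2_fold_change, tolerance = 1e-6)
  expect_equal(d$p_value, d2$p_value, tolerance = 1e-6)
  ## BH monotone in p rank
  ord <- order(d$p_value)
  expect_true(all(diff(d$q_value[ord]) > -1e-12))
})

test_that("identical counts give zero fold change; all-zero peaks are excluded", {
  k <- matrix(rep(c(50L, 50L, 50L, 50L), each = 3), 3, 4,
              dimnames = list(c("a", "b", "c"), NULL))
  k[2, ] <- 0L
  d <- differential_accessibility(
    k, factor(c("x", "x", "y", "y")), size_factors = rep(1, 4))
  expect_equal(attr(d, "excluded"), "b")
  expect_equal(d$log2_fold_change, rep(0, 2), tolerance = 1e-8)
  expect_true(all(d$call == "unaffected"))
})

test_that("fold-change estimates agree with DESeq2 on planted data", {
  suppressPackageStartupMessages({
    library(DESeq2)
  })
  set.seed(9)
  n <- 400
  mu <- exp(runif(n, log(50), log(500)))
  k <- matrix(rnbinom(4 * n, mu = rep(mu, 4), size = 20), n, 4,
              dimnames = list(paste0("pk", 1:n),
                              c("wt1", "wt2", "mut1", "mut2")))
  k[1:80, 3:4] <- rnbinom(160, mu = rep(mu[1:80] / 4, 2), size = 20)
  cond <- factor(c("wt", "wt", "mut", "mut"), levels = c("wt", "mut"))
  d <- differential_accessibility(k, cond, size_factors = rep(1e6, 4))
  dds <- DESeqDataSetFromMatrix(k, S4Vectors::DataFrame(condition = cond),
                                ~condition)
  sizeFactors(dds) <- rep(1, 4)
  dds <- suppressMessages(DESeq(dds, quiet = TRUE))
  res <- results(dds)
  expect_gt(cor(d$log2_fold_change, res$log2FoldChange), 0.98)
  ## strong calls agree on the depleted block
  expect_gt(mean(sign(d$log2_fold_change[1:80]) ==
                   sign(res$log2FoldChange[1:80])), 0.95)
})

test_that("volcano table joins binding annotation onto results", {
  d <- data.frame(peak = c("a", "b"), base_mean = c(1, 2),
                  log2_fold_change = c(-2, 0.1), se = c(0.1, 0.1),
                  dispersion = c(0.01, 0.01), p_value = c(1e-5, 0.5),
                  q_value = c(1e-4, 0.6),
                  call = c("decrease", "unaffected"))
  v <- volcano_table(d, bound_by = c(a = "Pou5f3", b = ""))
  expect_equal(v$bound_by, c("Pou5f3", ""))
  expect_equal(v$neg_log10_q[1], 4)
})
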