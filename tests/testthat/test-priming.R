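test_that("quintile bins are equal-frequency and order-invariant", {
  x <- rnorm(10)
  b <- quintile_bins(x)
  expect_equal(as.integer(table(b)), rep(2L, 5))   # 10 items -> bins of 2
  ## permutation invariance (ids travel with the values)
  perm <- sample(10)
  b2 <- quintile_bins(x[perm], ids = perm)
  expect_equal(b2[order(perm)], b, ignore_attr = TRUE)
  ## sizes differ by <= 1 for awkward n
  expect_lte(diff(range(table(quintile_bins(rnorm(23))))), 1)
  ## bin index is monotone in the variable
  expect_true(all(diff(b[order(x)]) >= 0))
  expect_error(quintile_bins(rnorm(3), 5), "fewer")
})

test_that("one-sided Wilcoxon reproduces exact enumeration", {
  ## {1,2,3} vs {4,5,6}: only 1 of the 20 rank assignments is as extreme
  w <- wilcoxon_one_sided(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(w$p_value, 1 / 20)
  expect_equal(w$method, "exact enumeration")
  ## identical samples: p >= 0.5 under either alternative
  expect_gte(wilcoxon_one_sided(1:4, 1:4, "greater")$p_value, 0.5)
  expect_gte(wilcoxon_one_sided(1:4, 1:4, "less")$p_value, 0.5)
  ## all values tied -> degenerate p = 1 with a warning
  expect_warning(w0 <- wilcoxon_one_sided(rep(2, 3), rep(2, 4), "greater"))
  expect_equal(w0$p_value, 1)
})

test_that("normal approximation tracks the exact p-value at n = 8", {
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8, 0.5)
    exact <- wilcoxon_one_sided(a, b, "less")$p_value
    approx_p <- wilcoxon_one_sided(c(a, 0.001), b, "less")$p_value # n=9 -> normal
    ## same data minus the near-null extra point: compare on shared fixture
    ref <- wilcox.test(a, b, alternative = "less", exact = TRUE)$p.value
    expect_equal(exact, ref, tolerance = 1e-12)
    ref2 <- wilcox.test(c(a, 0.001), b, alternative = "less",
                        exact = TRUE)$p.value
    expect_lt(abs(approx_p - ref2), 0.1 * ref2 + 0.01)
  }
})

test_that("priming quintiles rise with planted effect and test upward shifts", {
  set.seed(30)
  n <- 2000
  delta <- runif(n, 0, 5)
  outcome <- 1 + 1.0 * delta + rnorm(n, 0, 1)
  q <- quintile_outcome(delta, outcome)
  expect_true(all(diff(q$summary$median) > 0))    # strictly monotone
  expect_true(all(q$tests$p_value[1:4] < 1e-6))
  expect_equal(sum(q$summary$n), n)
  ## no effect: adjacent p-values are not systematically small
  out0 <- rnorm(n)
  q0 <- quintile_outcome(delta, out0)
  expect_gt(min(q0$tests$p_value), 1e-4)
  expect_error(quintile_outcome(runif(5), rnorm(5)), "too few")
})

test_that("priming grid finds the planted corner and transposes with its axes", {
  set.seed(31)
  n <- 2000
  incr <- runif(n)
  loss <- -runif(n)          # more negative = larger mutant loss
  out <- 2 + 3 * incr - 3 * loss + rnorm(n, 0, 0.5)
  g <- priming_grid(incr, loss, out)
  am <- which.max(g$grid)
  expect_equal(row(g$grid)[am], 1L)   # largest loss
  expect_equal(col(g$grid)[am], 5L)   # largest increase
  expect_equal(sum(g$n), n)
  ## transposing the covariates transposes the grid
  g2 <- priming_grid(loss, incr, out)
  expect_equal(g2$grid, t(g$grid), ignore_attr = TRUE)
  ## z-score variant normalizes before aggregation
  gz <- priming_grid(incr, loss, out, statistic = "mean_z")
  z <- (out - mean(out)) / sd(out)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(gz$grid[1, 5],
               mean(z[g$row_bins == 1 & g$col_bins == 5]))
})

test_that("null grids stay near the global median", {
  set.seed(32)
  n <- 2000
  out <- rnorm(n)
  g <- priming_grid(runif(n), runif(n), out)
  expect_lt(max(abs(g$grid - median(out)), na.rm = TRUE), 0.5)
})

test_that("TF signal rises toward greater mutant loss when binding is planted", {
  set.seed(33)
  n <- 600
  lfc <- sort(rnorm(n, 0, 0.3))      # ascending: first = largest loss
  chip <- rlnorm(n, log(4) * seq(1, 0, length.out = n), 0.2)
  input <- rlnorm(n, 0, 0.1)
  res <- tf_enrichment_by_bin(lfc, chip, input)
  med <- res$summary$median
  expect_true(all(diff(med) < 0))    # decreasing toward unaffected bins
  expect_true(all(res$tests$p_value < 0.01))
  ## genome-mean normalization of a constant signal -> all ones
  ## (constant signal makes the rank tests degenerate, hence the warnings)
  resc <- suppressWarnings(
    tf_enrichment_by_bin(lfc, rep(3, n), normalization = "genome_mean"))
  expect_true(all(abs(resc$summary$median - 1) < 1e-12))
  expect_error(tf_enrichment_by_bin(lfc, chip), "genome_mean")
})

test_that("Welch comparison separates regulated from non-regulated gene elements", {
  set.seed(34)
  reg <- c(rep(TRUE, 150), rep(FALSE, 150))
  lfc <- c(rnorm(150, -1.5, 0.8), rnorm(150, 0, 0.8))
  cmp <- mutant_effect_by_target(lfc, reg)
  expect_lt(cmp$mean_regulated, cmp$mean_other)
  expect_lt(cmp$p_value, 0.01)
  ## identical distributions with equal n: t near zero
  cmp0 <- mutant_effect_by_target(rep(c(1, 2, 3), 20),
                                  rep(c(TRUE, FALSE), each = 30))
  expect_lt(abs(cmp0$statistic), 1e-8)
  expect_error(mutant_effect_by_target(rnorm(5), c(TRUE, rep(FALSE, 4))),
               ">= 2")
})

test_that("bound-combination analysis isolates planted triple-bound effects", {
  set.seed(35)
  combos <- c("", "Pou5f3", "Sox19b", "Nanog", "Pou5f3,Sox19b",
              "Pou5f3,Sox19b,Nanog")
  bound <- sample(combos, 800, replace = TRUE)
  lfc <- rnorm(800, 0, 0.3)
  triple <- bound == "Pou5f3,Sox19b,Nanog"
  lfc[triple] <- lfc[triple] - 2
  res <- bound_site_effect_by_combination(lfc, bound)
  s <- res$summary
  expect_lt(s$median[s$combination == "Pou5f3+Sox19b+Nanog"],
            min(s$median[s$combination %in% c("Pou5f3", "Sox19b", "Nanog")]))
  expect_lt(res$tests$p_value[res$tests$combination ==
                                "Pou5f3+Sox19b+Nanog"], 0.01)
  ## unbound reference distribution centered at zero
  expect_lt(abs(s$median[s$combination == "unbound"]), 0.1)
  ## combinations never seen are reported as skipped
  expect_true("Pou5f3+Nanog" %in% res$skipped)
})

test_that("priming grids render as tile heatmaps", {
  set.seed(36)
  g <- priming_grid(runif(100), runif(100), rnorm(100))
  p <- plot_priming_grid(g)
  expect_s3_class(p, "ggplot")
})

test_that("average mutant effect supports mean and strongest-loss modes", {
  m <- cbind(a = c(-1, 0), b = c(-3, -1), c = c(1, 2))
  expect_equal(average_mutant_effect(m), c(-1, 1 / 3))
  expect_equal(average_mutant_effect(m, "min"), c(-3, -1))
})
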