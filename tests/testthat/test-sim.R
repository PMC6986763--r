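test_that("annotation respects configured counts and is seed-deterministic", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 400000,
                    n_genes = 10, n_regions = 20)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$tss), 10L)
  expect_equal(nrow(ann$regions), 20L)
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann$tss, ann2$tss)
  expect_identical(ann$regions, ann2$regions)
  ## sizing error when the chromosome cannot host the genes
  expect_error(simulate_annotation(
    sim_config(n_chroms = 1, chrom_length = 50000, n_genes = 30,
               n_regions = 30)), "too short")
})

test_that("planted promoters are TSS-proximal, planted enhancers distal", {
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_length = 900000,
                    n_genes = 50, n_regions = 100, fraction_enhancer = 1)
  ann <- simulate_annotation(cfg)
  expect_true(all(ann$regions$is_enhancer))
  ## brute-force pairwise distances: every region >= 1 kb from every TSS
  for (i in seq_len(nrow(ann$regions))) {
    d <- vapply(ann$tss$pos, function(p) {
      if (p >= ann$regions$start[i] && p < ann$regions$end[i]) 0
      else min(abs(p - ann$regions$start[i]),
               abs(p - (ann$regions$end[i] - 1)))
    }, numeric(1))
    expect_gte(min(d), 1000)
  }
  ## every planted enhancer carries >= 1 core and >= 1 developmental factor
  expect_true(all(nzchar(ann$regions$core_tfs)))
  expect_true(all(nzchar(ann$regions$dev_tfs)))
  ## links respect nearest-TSS semantics within 20 kb
  lk <- link_to_genes(ann$regions, ann$tss)
  m <- match(ann$regions$name, lk$element)
  expect_true(all(!is.na(m)))
  expect_equal(lk$gene_id[m], ann$regions$gene_id)
})

test_that("fragment generation is deterministic, conservative and condition-aware", {
  cfg <- tiny_config(seed = 9)
  ann <- simulate_annotation(cfg)
  fr1 <- simulate_fragments(cfg, ann$truth, ann$regions, "wt",
                            cfg$stages[2], 1)
  fr2 <- simulate_fragments(cfg, ann$truth, ann$regions, "wt",
                            cfg$stages[2], 1)
  expect_identical(fr1, fr2)
  ## conservation: fragments emitted = region draws + background draws
  expect_equal(nrow(fr1),
               sum(attr(fr1, "region_counts")) + attr(fr1, "n_background"))
  ## unknown condition label
  expect_error(simulate_fragments(cfg, ann$truth, ann$regions, "sox2",
                                  cfg$stages[1]), "unknown condition")
  ## zero depth -> empty set
  cfg0 <- tiny_config(seed = 9, fragment_depth = 0)
  fr0 <- simulate_fragments(cfg0, ann$truth, ann$regions, "wt",
                            cfg$stages[1], 1)
  expect_equal(nrow(fr0), 0L)
})

test_that("flat trajectories give stage-independent mean counts", {
  flat <- matrix(5, 1, 7)
  cfg <- sim_config(seed = 10, n_chroms = 1, chrom_length = 400000,
                    n_genes = 12, n_regions = 24,
                    cluster_profiles = matrix(5, 2, 7),
                    amplitude_jitter = 0, fragment_depth = 5000)
  ann <- simulate_annotation(cfg)
  ## >= 50 replicate draws of one region's count at two stages
  draws <- function(stage) vapply(1:50, function(r)
    attr(simulate_fragments(cfg, ann$truth, ann$regions, "wt", stage, r),
         "region_counts")[["region0001"]], numeric(1))
  a <- draws(cfg$stages[1])
  b <- draws(cfg$stages[5])
  se <- sqrt(var(a) / 50 + var(b) / 50)
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
})

test_that("mutant_effect = 0 leaves mutant counts distributionally wild-type", {
  cfg <- tiny_config(seed = 12, mutant_effect = 0)
  ann <- simulate_annotation(cfg)
  pvals <- vapply(1:20, function(r) {
    wt <- attr(simulate_fragments(cfg, ann$truth, ann$regions, "wt",
                                  cfg$stages[3], r), "region_counts")
    mu <- attr(simulate_fragments(cfg, ann$truth, ann$regions, "pou5f3",
                                  cfg$stages[3], r + 1000), "region_counts")
    t.test(wt, mu, paired = TRUE)$p.value
  }, numeric(1))
  ## two-sample test non-significant at alpha = 0.01 in >= 95% of draws
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("expression carries the planted priming signal (and only then)", {
  big <- sim_config(seed = 13, n_chroms = 4, chrom_length = 8000000,
                    n_genes = 2000, n_regions = 2000, priming_beta = 0,
                    tf_activation = 0)
  ann <- simulate_annotation(big)
  ex0 <- simulate_expression(big, ann$truth)
  keep <- !attr(ex0, "never_expressed")
  rho0 <- cor(attr(ex0, "delta_access")[keep], ex0$sphere[keep],
              method = "spearman")
  expect_lt(abs(rho0), 0.1)
  ## large effect, vanishing noise: rank correlation approaches 1
  big2 <- sim_config(seed = 13, n_chroms = 4, chrom_length = 8000000,
                     n_genes = 2000, n_regions = 2000, priming_beta = 20,
                     noise_sd = 1e-4, tf_activation = 0)
  ex1 <- simulate_expression(big2, ann$truth)
  keep1 <- !attr(ex1, "never_expressed")
  rho1 <- cor(attr(ex1, "delta_access")[keep1], ex1$sphere[keep1],
              method = "spearman")
  expect_gt(rho1, 0.95)
  ## never-expressed genes stay below the silent cutoff at every stage
  silent <- ex0[attr(ex0, "never_expressed"), big$stages]
  expect_true(all(rowSums(silent) < 0.1))
})

test_that("ChIP peaks, signal and sequences reflect the planted binding", {
  cfg <- sim_config(seed = 14, n_chroms = 4, chrom_length = 1000000,
                    n_genes = 250, n_regions = 700, fraction_enhancer = 0.95)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_and_sequence(cfg, ann$truth, ann$regions)
  ## bound regions are covered by exactly their factors' peak files
  i <- which(ann$regions$is_enhancer)[1]
  reg <- ann$regions[i, ]
  tfs_with_peak <- names(chip$peaks)[vapply(chip$peaks, function(p)
    nrow(p) > 0 &&
      any(p$chrom == reg$chrom & p$start < reg$end & p$end > reg$start),
    logical(1))]
  expect_setequal(tfs_with_peak,
                  c(strsplit(reg$core_tfs, ",")[[1]],
                    strsplit(reg$dev_tfs, ",")[[1]]))
  ## planted motif positions carry the exact PWM consensus
  pwms <- default_motifs()
  mp <- chip$motif_positions
  for (j in seq_len(min(nrow(mp), 25))) {
    cons <- pwms[[mp$tf[j]]]$consensus
    expect_equal(substr(chip$sequences[[mp$region[j]]], mp$offset[j] + 1,
                        mp$offset[j] + nchar(cons)), cons)
  }
  ## unbound ChIP/Input centred at 1 (n >= 500 unbound region-TF pairs)
  ratio <- chip$chip_signal / chip$input_signal
  unbound_vals <- unlist(lapply(colnames(ratio), function(tf) {
    bound <- grepl(tf, paste(ann$regions$core_tfs, ann$regions$dev_tfs))
    ratio[!bound, tf]
  }))
  expect_gte(length(unbound_vals), 500)
  expect_gt(median(unbound_vals), 0.8)
  expect_lt(median(unbound_vals), 1.25)
  ## PWM wider than the region errors out
  wide <- pwm_from_counts(matrix(25, 4, 600), id = "wide")
  expect_error(simulate_chip_and_sequence(
    cfg, ann$truth, ann$regions, pwms = list(wide = wide)), "width")
})

test_that("a written simulation is byte-identical under the same seed", {
  cfg <- tiny_config(seed = 15, n_replicates = 1)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_simulation(simulate_experiment(cfg), d1)
  write_simulation(simulate_experiment(cfg), d2)
  f1 <- list.files(d1)
  expect_true(length(f1) > 10)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
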