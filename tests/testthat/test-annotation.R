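toy_tss <- function() {
  data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
             pos = c(10000L, 60000L), strand = c("+", "-"),
             stringsAsFactors = FALSE)
}

test_that("promoters are 2 kb windows centered on the TSS, clipped at edges", {
  tss <- toy_tss()
  pr <- define_promoters(tss)
  expect_equal(pr$start[1], 9000L)
  expect_equal(pr$end[1], 11000L)
  expect_equal(nrow(pr), nrow(tss))                 # conservation
  ## TSS close to the chromosome start: clipped and flagged
  pr2 <- define_promoters(data.frame(gene_id = "g", chrom = "chr1",
                                     pos = 300L, strand = "+"))
  expect_equal(pr2$start, 0L)
  expect_equal(pr2$end, 1300L)
  expect_true(pr2$clipped)
})

test_that("enhancer rule: distal AND core AND developmental ChIP support", {
  tss <- toy_tss()
  peaks <- data.frame(
    chrom = "chr1",
    start = c(20000L, 30000L, 10300L),
    end = c(20400L, 30400L, 10700L),
    name = c("pk_both", "pk_core_only", "pk_proximal"))
  nanog <- data.frame(chrom = "chr1", start = c(20100L, 30100L, 10350L),
                      end = c(20300L, 30300L, 10600L))
  mxtx2 <- data.frame(chrom = "chr1", start = c(20150L, 10400L),
                      end = c(20250L, 10500L))
  enh <- define_enhancers(peaks, tss, core_chip = list(Nanog = nanog),
                          dev_chip = list(Mxtx2 = mxtx2))
  ## distal + Nanog + Mxtx2 -> enhancer with recorded supports
  expect_equal(enh$name, "pk_both")
  expect_equal(enh$core_support, "Nanog")
  expect_equal(enh$dev_support, "Mxtx2")
  ## pk_core_only lacks a developmental factor; pk_proximal is 300 bp from
  ## a TSS despite full support -> both excluded
  expect_false("pk_core_only" %in% enh$name)
  expect_false("pk_proximal" %in% enh$name)
  expect_warning(define_enhancers(peaks, tss, list(), list()), "empty")
})

test_that("distal threshold uses point-to-interval distance", {
  tss <- data.frame(gene_id = "g", chrom = "chr1", pos = 5000L, strand = "+")
  chip <- list(X = data.frame(chrom = "chr1", start = c(5900L, 6200L),
                              end = c(6500L, 6300L)))
  ## peak edge exactly 1000 bp from the TSS point: kept
  pk <- data.frame(chrom = "chr1", start = 6000L, end = 6400L, name = "edge")
  expect_equal(nrow(define_enhancers(pk, tss, chip, chip)), 1L)
  ## 999 bp away: excluded
  pk2 <- data.frame(chrom = "chr1", start = 5999L, end = 6400L, name = "in")
  expect_equal(nrow(define_enhancers(pk2, tss, chip, chip)), 0L)
})

test_that("gene linking respects the 20 kb threshold and ties break deterministically", {
  tss <- toy_tss()
  els <- data.frame(chrom = "chr1",
                    start = c(29200L, 81200L), end = c(29400L, 81400L),
                    name = c("near", "far"))
  ## 'near': 19,200 bp gap to g1's TSS (10,000) -> linked
  ## 'far': 21,200 bp gap to g2's TSS (60,000) -> unlinked
  lk <- link_to_genes(els, tss)
  expect_equal(lk$element, "near")
  expect_equal(lk$gene_id, "g1")
  expect_equal(lk$distance, 29200 - 10000)
  ## equidistant TSSs: lower coordinate wins, then gene id
  tss2 <- data.frame(gene_id = c("b", "a"), chrom = "chr1",
                     pos = c(1000L, 3099L), strand = "+")
  el <- data.frame(chrom = "chr1", start = 2000L, end = 2100L, name = "e")
  lk2 <- link_to_genes(el, tss2)
  expect_equal(lk2$gene_id, "b")   # pos 1000 < 3099 at equal distance
})

test_that("linking matches the brute-force nearest-TSS oracle", {
  set.seed(13)
  for (i in 1:10) {
    tss <- data.frame(gene_id = sprintf("g%02d", 1:8),
                      chrom = sample(c("chr1", "chr2"), 8, TRUE),
                      pos = sample.int(50000, 8), strand = "+")
    els <- rand_intervals(12, max_pos = 60000)
    els$name <- sprintf("e%02d", 1:12)
    lk <- link_to_genes(els, tss, link_max = 20000)
    for (j in seq_len(nrow(els))) {
      bf <- bf_nearest_tss(els[j, ], tss, 20000)
      row <- lk[lk$element == els$name[j], ]
      if (is.null(bf)) {
        expect_equal(nrow(row), 0L)
      } else {
        expect_equal(row$gene_id, bf$gene)
        expect_equal(row$distance, bf$d)
        expect_lte(row$distance, 20000)
      }
    }
  }
})

test_that("gene classes follow the expression cutoffs", {
  expr <- data.frame(
    gene_id = c("on_late", "on_both", "silent", "edge"),
    sphere = c(0.5, 1.2, 0.02, 1.0),
    shield = c(1.5, 2.0, 0.03, 0.2))
  cls <- classify_gene_sets(expr, reference_stage = "sphere",
                            later_stage = "shield")
  ## RPKM exactly 1.0 counts as expressed
  expect_true(cls$expressed.sphere[cls$gene_id == "edge"])
  ## expressed late but not at reference -> late-activated
  expect_equal(cls$gene_id[cls$late_activated], "on_late")
  ## expressed at both stages -> not late-activated
  expect_false(cls$late_activated[cls$gene_id == "on_both"])
  ## summed RPKM below 0.1 -> never expressed
  expect_equal(cls$gene_id[cls$never_expressed], "silent")
  expect_error(classify_gene_sets(expr, reference_stage = "nope"),
               "missing stage")
})

test_that("promoter and enhancer classes cannot share an interval", {
  ## distal_min (1000) >= half promoter window: an enhancer is >= 1 kb from
  ## every TSS, every promoter base is < 1 kb from its TSS
  tss <- toy_tss()
  pr <- define_promoters(tss)
  chip <- list(X = data.frame(chrom = "chr1", start = 0L, end = 100000L))
  cand <- rbind(pr[c("chrom", "start", "end")],
                data.frame(chrom = "chr1", start = 20000L, end = 20400L))
  cand$name <- c("p1", "p2", "distal")
  enh <- define_enhancers(cand, tss, chip, chip)
  expect_equal(enh$name, "distal")
})

test_that("planted enhancers are recovered from ChIP support with high precision/recall", {
  cfg <- tiny_config(seed = 4)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_and_sequence(cfg, ann$truth, ann$regions)
  enh <- define_enhancers(ann$regions, ann$tss,
                          core_chip = chip$peaks[c("Pou5f3", "Sox19b", "Nanog")],
                          dev_chip = chip$peaks[setdiff(names(chip$peaks),
                                                        c("Pou5f3", "Sox19b",
                                                          "Nanog"))])
  truth_pos <- ann$regions$name[ann$regions$is_enhancer]
  tp <- sum(enh$name %in% truth_pos)
  precision <- tp / nrow(enh)
  recall <- tp / length(truth_pos)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
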