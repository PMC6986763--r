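## End-to-end orchestration on synthetic data: simulate -> fragments ->
## peaks -> consensus -> counts/FPKM -> clustering -> differential ->
## elements/links -> priming statistics -> motif analysis, with TSV/BED
## outputs and a JSON manifest.

stage_of_sample <- function(names) {
  vapply(strsplit(names, "_"), function(x) x[2], character(1))
}

#' Standard demonstration configuration
#'
#' The package's reference synthetic study: a 6 x 1.1 Mb genome with 400
#' genes and 1000 accessible regions (600 TF-bound distal elements),
#' sampled at 600,000 fragments per library (a few hundred fragments per
#' region). Large enough that the planted priming structure
#' is resolved by the 5 x 5 median grid, small enough to run end to end in
#' a few minutes.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L) {
  sim_config(seed = seed, n_chroms = 6L, chrom_length = 1100000L,
             n_genes = 400L, n_regions = 1000L, fragment_depth = 6e5)
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates a synthetic experiment from `config`, processes every sample
#' (Tn5 cut-site adjustment, mapq filter, NFR split), calls peaks per
#' wild-type stage against the genomic-DNA control with replicate
#' confirmation, builds the consensus peak set with per-stage presence,
#' counts NFR fragments and computes per-stage FPKM, clusters trajectories
#' (k = 5), tests differential accessibility for each core-TF mutant,
#' defines promoters/enhancers and links them to genes, computes the
#' priming quintile and 5x5 grid statistics plus TF-enrichment by
#' mutant-effect bin, and runs the motif best-hit/score-bin/enrichment
#' analyses on the region sequences. All tables are written under
#' `outdir` when given, along with a manifest echoing the config and seed.
#'
#' @param config A [sim_config()]; its defaults are the package's standard
#'   demonstration conditions.
#' @param outdir Output directory for TSV/BED/JSON artifacts, or NULL to
#'   skip writing.
#' @param bin_size Coverage bin size in bp (default 20).
#' @param nfr_cutoff NFR fragment-length cutoff (default 130).
#' @param fdr Peak-calling and differential FDR (default 0.05).
#' @param lfc_threshold Differential call threshold (default 1.5).
#' @param k Number of trajectory clusters (default 5).
#' @param verbose Print stage progress.
#' @return list with the intermediate and final objects: `sim`,
#'   `consensus`, `counts`, `fpkm_stage`, `clusters`, `differential`
#'   (per mutant), `elements`, `links`, `quintiles`, `grid`,
#'   `tf_enrichment`, `motifs`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         bin_size = 20L, nfr_cutoff = 130L, fdr = 0.05,
                         lfc_threshold = 1.5, k = 5L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating experiment (seed %d)", config$seed)
  sim <- simulate_experiment(config)
  chrom_sizes <- sim$chrom_sizes
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, file.path(outdir, "simulated_inputs"))
  }

  say("processing fragments")
  adjusted <- lapply(sim$samples, adjust_cut_sites)
  control_adj <- adjust_cut_sites(sim$control)
  ## raw fragment sets are no longer needed in memory
  sim$samples <- NULL
  sim$control <- NULL
  count_track <- function(fr) make_coverage(fr, chrom_sizes, bin_size,
                                            normalization = "raw",
                                            stat = "fragment_count")
  nfr_sets <- lapply(adjusted, function(fr) split_by_size(fr, nfr_cutoff)$nfr)
  control_track <- count_track(split_by_size(control_adj, nfr_cutoff)$nfr)

  say("calling peaks per wild-type stage")
  wt_names <- grep("^wt_", names(adjusted), value = TRUE)
  stage_peaks <- list()
  for (stage in config$stages) {
    reps <- wt_names[stage_of_sample(wt_names) == stage]
    pooled_frags <- do.call(rbind, nfr_sets[reps])
    pooled <- call_peaks(count_track(pooled_frags), control_track, fdr = fdr)
    rep_peaks <- lapply(reps, function(r)
      call_peaks(count_track(nfr_sets[[r]]), control_track, fdr = fdr))
    stage_peaks[[stage]] <- confirm_replicated(pooled, rep_peaks)
  }
  rm(nfr_sets, control_track)
  consensus <- build_consensus(stage_peaks)
  say("%d consensus peaks", nrow(consensus$peaks))

  say("counting and normalizing")
  counts <- count_over_peaks(consensus$peaks, adjusted, nfr_cutoff)
  rm(adjusted, control_adj)
  wt_cols <- grep("^wt_", colnames(counts), value = TRUE)
  fpkm_stage <- fpkm(counts[, wt_cols, drop = FALSE],
                     widths = attr(counts, "widths"),
                     library_sizes = attr(counts, "library_sizes")[wt_cols],
                     stage_map = stage_of_sample(wt_cols))

  say("clustering trajectories")
  clusters <- if (nrow(fpkm_stage) > k) {
    cluster_dynamics(fpkm_stage, k = k, seed = config$seed)
  } else NULL

  say("differential accessibility per mutant")
  mutants <- setdiff(unique(sub("_.*", "", colnames(counts))), "wt")
  wt_mut_stage <- wt_names[stage_of_sample(wt_names) == sim$mutant_stage]
  differential <- list()
  for (m in mutants) {
    mcols_ <- grep(paste0("^", m, "_"), colnames(counts), value = TRUE)
    cols <- c(wt_mut_stage, mcols_)
    differential[[m]] <- differential_accessibility(
      counts[, cols, drop = FALSE],
      condition = factor(rep(c("wt", m), c(length(wt_mut_stage),
                                           length(mcols_))),
                         levels = c("wt", m)),
      size_factors = attr(counts, "library_sizes")[cols],
      lfc_threshold = lfc_threshold, fdr = fdr)
  }

  say("defining regulatory elements")
  promoters <- define_promoters(sim$tss, chrom_sizes = chrom_sizes)
  core_chip <- sim$chip$peaks[CORE_TFS]
  dev_chip <- sim$chip$peaks[DEV_TFS]
  enhancers <- define_enhancers(consensus$peaks, sim$tss, core_chip,
                                dev_chip)
  links <- link_to_genes(consensus$peaks, sim$tss)

  say("priming statistics")
  i_early <- config$stages[1]
  i_oblong <- sim$mutant_stage
  late_col <- config$stages[min(4L, length(config$stages))]
  delta <- fpkm_stage[, i_oblong] - fpkm_stage[, i_early]
  lfc_mat <- vapply(mutants, function(m) {
    d <- differential[[m]]
    d$log2_fold_change[match(rownames(fpkm_stage), d$peak)]
  }, numeric(nrow(fpkm_stage)))
  avg_lfc <- average_mutant_effect(lfc_mat)
  ## priming statistics over putative enhancers (TF-supported elements)
  idx <- match(rownames(fpkm_stage), links$element)
  linked <- !is.na(idx) & !is.na(avg_lfc) &
    rownames(fpkm_stage) %in% enhancers$name
  outcome <- sim$expression[[late_col]][
    match(links$gene_id[idx[linked]], sim$expression$gene_id)]
  quintiles <- grid <- NULL
  if (sum(linked) >= 25) {
    quintiles <- quintile_outcome(delta[linked], outcome)
    grid <- priming_grid(delta[linked], avg_lfc[linked], outcome)
  }
  ## TF enrichment across mutant-effect bins, on truth regions matched to peaks
  region_of_peak <- function(peaks) {
    hit <- GenomicRanges::findOverlaps(bed_to_granges(peaks),
                                       bed_to_granges(sim$regions),
                                       select = "first", ignore.strand = TRUE)
    sim$regions$name[hit]
  }
  peak_region <- region_of_peak(consensus$peaks)
  ok <- !is.na(peak_region) & !is.na(avg_lfc)
  tf_enr <- NULL
  if (sum(ok) >= 25) {
    dev_sig <- sim$chip$chip_signal[peak_region[ok], DEV_TFS[1:4], drop = FALSE]
    dev_in <- sim$chip$input_signal[peak_region[ok], DEV_TFS[1:4], drop = FALSE]
    tf_enr <- tf_enrichment_by_bin(avg_lfc[ok], dev_sig, dev_in)
  }

  say("motif analyses")
  pwms <- default_motifs()
  seqs <- sim$chip$sequences[peak_region[ok]]
  motifs <- NULL
  if (length(seqs) >= 20) {
    best <- scan_best_hit(seqs, pwms[["Pou5f3"]])
    sb <- score_bins_vs_effect(best$score, avg_lfc[ok],
                               n_bins = min(10L, floor(length(seqs) / 3)))
    enr <- enrichment_top_regions(delta[ok], seqs, pwms)
    motifs <- list(best_hits = best, score_bins = sb, enrichment = enr)
  }

  result <- list(sim = sim, stage_peaks = stage_peaks, consensus = consensus,
                 counts = counts, fpkm_stage = fpkm_stage,
                 clusters = clusters, differential = differential,
                 promoters = promoters, enhancers = enhancers,
                 links = links, delta_access = delta,
                 mutant_lfc = lfc_mat, avg_mutant_lfc = avg_lfc,
                 quintiles = quintiles, grid = grid,
                 tf_enrichment = tf_enr, motifs = motifs)

  if (!is.null(outdir)) {
    write_bed(consensus$peaks, file.path(outdir, "consensus_peaks.bed"))
    write_tsv_table(as.data.frame(consensus$presence),
                    file.path(outdir, "presence.tsv"), rownames_as = "peak")
    write_tsv_table(as.data.frame(counts), file.path(outdir, "counts.tsv"),
                    rownames_as = "peak")
    write_tsv_table(as.data.frame(fpkm_stage),
                    file.path(outdir, "fpkm_stage.tsv"), rownames_as = "peak")
    if (!is.null(clusters)) {
      write_tsv_table(data.frame(peak = names(clusters$labels),
                                 cluster = clusters$labels),
                      file.path(outdir, "cluster_labels.tsv"))
      write_tsv_table(as.data.frame(clusters$centroids),
                      file.path(outdir, "cluster_centroids.tsv"),
                      rownames_as = "cluster")
    }
    for (m in names(differential)) {
      write_tsv_table(differential[[m]],
                      file.path(outdir, sprintf("differential_%s.tsv", m)))
    }
    write_bed(promoters, file.path(outdir, "promoters.bed"))
    if (nrow(enhancers)) write_bed(enhancers,
                                   file.path(outdir, "enhancers.bed"))
    write_tsv_table(links, file.path(outdir, "gene_links.tsv"))
    if (!is.null(quintiles)) {
      write_tsv_table(quintiles$summary,
                      file.path(outdir, "priming_quintiles.tsv"))
      write_tsv_table(quintiles$tests,
                      file.path(outdir, "priming_quintile_tests.tsv"))
    }
    if (!is.null(grid)) {
      write_tsv_table(as.data.frame(grid$grid),
                      file.path(outdir, "priming_grid.tsv"),
                      rownames_as = "mutant_effect_bin")
      write_tsv_table(as.data.frame(grid$n),
                      file.path(outdir, "priming_grid_n.tsv"),
                      rownames_as = "mutant_effect_bin")
    }
    if (!is.null(motifs)) {
      write_tsv_table(motifs$best_hits, file.path(outdir, "motif_best_hits.tsv"))
      write_tsv_table(motifs$enrichment$table,
                      file.path(outdir, "motif_enrichment.tsv"))
    }
    run_id <- sprintf("atacprime_seed%d", config$seed)
    cfg <- config
    cfg$cluster_profiles <- apply(cfg$cluster_profiles, 1, paste,
                                  collapse = ",")
    write_manifest(
      list(run_id = run_id, seed = config$seed, config = unclass(cfg),
           parameters = list(bin_size = bin_size, nfr_cutoff = nfr_cutoff,
                             fdr = fdr, lfc_threshold = lfc_threshold, k = k),
           n_consensus_peaks = nrow(consensus$peaks)),
      file.path(outdir, "manifest.json"))
  }
  result
}

#' Heatmap of a priming grid
#'
#' Simple ggplot tile rendering of the 5x5 grid (requires ggplot2).
#'
#' @param grid Output of [priming_grid()].
#' @return A ggplot object.
#' @export
plot_priming_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- expand.grid(mutant_effect_bin = seq_len(nrow(grid$grid)),
                    increase_bin = seq_len(ncol(grid$grid)))
  df$value <- grid$grid[cbind(df$mutant_effect_bin, df$increase_bin)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$increase_bin,
                                   y = .data$mutant_effect_bin,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "accessibility increase (quintile, low to high)",
                  y = "mutant accessibility change (quintile, largest loss first)",
                  fill = grid$statistic)
}
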