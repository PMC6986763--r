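## Synthetic-data generator: genome annotation, staged fragment sets with
## planted accessibility dynamics, TF-bound enhancers with mutant depletion,
## expression tables with a tunable priming effect, ChIP peaks/signals and
## sequences with planted motifs. Every output records its ground truth and
## draws from its own labelled RNG stream.

#' Simulation configuration
#'
#' Defines the study design emulated by the generator: a staged wild-type
#' ATAC time course (seven embryonic stages by default, from pre-ZGA
#' 256-cell to 80% epiboly), replicate structure, five accessibility
#' trajectory archetypes, TF-bound distal enhancers whose accessibility
#' collapses in the corresponding maternal-zygotic mutant, and gene
#' expression whose late-stage level depends on the prior accessibility
#' increase of linked elements with effect size `priming_beta`.
#'
#' @param seed Master seed; all streams derive from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 1 Mb).
#' @param n_genes,n_regions Numbers of genes/TSSs and accessible regions.
#' @param stages Ordered stage labels (>= 2).
#' @param n_replicates Replicates per stage/condition.
#' @param cluster_profiles k x stages matrix of expected accessibility
#'   weights; default five archetypes (early-opening, ZGA-opening, two
#'   late-opening, constitutive-moderate).
#' @param fraction_enhancer Probability that a region is a TF-bound distal
#'   element rather than a promoter.
#' @param mutant_effect log2 depletion applied to bound regions in mutant
#'   samples (default 2, i.e. 4-fold loss).
#' @param priming_beta Effect size linking accessibility increase
#'   (256-cell to oblong) of linked elements to late expression.
#' @param noise_sd Expression noise sd (RPKM units).
#' @param nb_dispersion Negative-binomial dispersion of fragment counts.
#' @param fragment_depth Expected fragments per sample.
#' @param region_width Width of planted regions in bp.
#' @param background_fraction Fraction of fragments scattered outside
#'   regions.
#' @param nfr_fraction In-region fraction of sub-nucleosomal fragments.
#' @param silent_fraction Fraction of genes planted as never expressed.
#' @param tf_activation Additional late expression (RPKM) per unit of
#'   TF load (bound core factors x dependence strength), coupling
#'   expression to TF dependence.
#' @param tf_strength_range Range of the per-gene TF-dependence strength
#'   multiplier applied to both mutant depletion and activation; set to
#'   `c(1, 1)` for a uniform planted depletion of exactly
#'   `-mutant_effect` log2 units.
#' @param amplitude_jitter Half-width of the per-gene uniform amplitude
#'   multiplier on trajectories (peak heights vary continuously in real
#'   data); 0 gives exactly the archetype profiles.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1000000L,
                       n_genes = 60L, n_regions = 120L,
                       stages = c("c256", "high", "oblong", "sphere",
                                  "dome", "shield", "epi80"),
                       n_replicates = 2L,
                       cluster_profiles = NULL,
                       fraction_enhancer = 0.35, mutant_effect = 2,
                       priming_beta = 1, noise_sd = 0.5,
                       nb_dispersion = 0.03, fragment_depth = 20000,
                       region_width = 400L, background_fraction = 0.5,
                       nfr_fraction = 0.7, silent_fraction = 0.15,
                       tf_activation = 3.0, tf_strength_range = c(0.3, 1),
                       amplitude_jitter = 0.4) {
  if (is.null(cluster_profiles)) {
    cluster_profiles <- default_cluster_profiles(length(stages))
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_regions = as.integer(n_regions), stages = stages,
              n_replicates = as.integer(n_replicates),
              cluster_profiles = cluster_profiles,
              fraction_enhancer = fraction_enhancer,
              mutant_effect = mutant_effect, priming_beta = priming_beta,
              noise_sd = noise_sd, nb_dispersion = nb_dispersion,
              fragment_depth = fragment_depth,
              region_width = as.integer(region_width),
              background_fraction = background_fraction,
              nfr_fraction = nfr_fraction,
              silent_fraction = silent_fraction,
              tf_activation = tf_activation,
              tf_strength_range = tf_strength_range,
              amplitude_jitter = amplitude_jitter)
  with(cfg, {
    stopifnot(n_chroms > 0, chrom_length > 0, n_genes > 0, n_regions > 0,
              n_replicates > 0, length(stages) >= 2,
              all(cluster_profiles >= 0),
              ncol(cluster_profiles) == length(stages),
              fraction_enhancer >= 0, fraction_enhancer <= 1,
              fragment_depth >= 0, nb_dispersion >= 0, region_width > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Default accessibility trajectory archetypes
#'
#' Five well-separated profiles over the stage axis: already accessible
#' pre-ZGA and rising fast; opening during ZGA; two late/gastrulation
#' openers with shifted onsets; and a constitutive moderate profile.
#'
#' @param n_stages Number of stages.
#' @return 5 x n_stages non-negative matrix of expected accessibility
#'   weights (arbitrary units proportional to expected NFR fragments).
#' @export
default_cluster_profiles <- function(n_stages) {
  s <- seq(0, 1, length.out = n_stages)
  logi <- function(mid, lo, hi) lo + (hi - lo) * stats::plogis((s - mid) * 12)
  rbind(
    c1 = 4 + 12 * stats::plogis((s - 0.15) * 10),
    c2 = logi(0.35, 0.5, 12),
    c3 = logi(0.60, 0.5, 10),
    c4 = logi(0.85, 0.5, 9),
    c5 = rep(3, n_stages))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d chrom(s) x %g bp, %d genes, %d regions,",
                     " %d stages x %d reps, depth %g, seed %d\n"),
              x$n_chroms, x$chrom_length, x$n_genes, x$n_regions,
              length(x$stages), x$n_replicates, x$fragment_depth, x$seed))
  invisible(x)
}

#' @export
sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

GENE_SPACING <- 15000L    # bp between consecutive TSS loci
ENH_SLOT_BASE <- 1800L    # first enhancer slot offset from its TSS
ENH_SLOT_STEP <- 1600L    # spacing between slots of the same gene

#' Generate the synthetic gene and region annotation
#'
#' Places TSSs on a regular jittered grid, then places accessible regions:
#' promoter-type regions centered on a TSS, enhancer-type regions at least
#' 1 kb from every TSS but within nearest-TSS linking range (< 20 kb) of
#' their own gene. Each region gets a trajectory cluster label; enhancers
#' get a bound-TF set (>= 1 core, >= 1 developmental factor). Deterministic
#' for a fixed config seed.
#'
#' @param config A `sim_config`.
#' @return list: `tss` (gene_id, chrom, pos, strand), `regions` (BED table
#'   with name, cluster, is_enhancer, core_tfs, dev_tfs, gene_id),
#'   `truth` (region trajectories, enhancer-gene links, flags,
#'   amanitin-sensitive region id).
#' @export
simulate_annotation <- function(config) {
  genes_per_chrom <- ceiling(config$n_genes / config$n_chroms)
  need <- 5000 + genes_per_chrom * GENE_SPACING + 5000
  if (need > config$chrom_length) {
    stop(sprintf("chromosome too short: need %d bp for %d genes per chromosome",
                 need, genes_per_chrom))
  }
  n_prom <- min(round((1 - config$fraction_enhancer) * config$n_regions),
                config$n_genes)
  n_enh <- config$n_regions - n_prom
  max_slots <- ceiling(n_enh / config$n_genes)
  if (ENH_SLOT_BASE + max_slots * ENH_SLOT_STEP > 8000) {
    stop("too many regions per gene: enhancer slots would leave nearest-TSS range")
  }
  with_stream(config$seed, "annotation", {
    gene_idx <- seq_len(config$n_genes)
    chrom <- paste0("chr", ((gene_idx - 1) %/% genes_per_chrom) + 1)
    slot <- ((gene_idx - 1) %% genes_per_chrom)
    pos <- 5000L + slot * GENE_SPACING + sample(0:1000, config$n_genes,
                                                replace = TRUE)
    tss <- data.frame(gene_id = sprintf("gene%03d", gene_idx),
                      chrom = chrom, pos = pos,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
    k <- nrow(config$cluster_profiles)
    half <- config$region_width %/% 2
    reg_idx <- seq_len(config$n_regions)
    ## promoter-type regions: one each at the first n_prom genes (randomly
    ## chosen); enhancer-type regions: round-robin over all genes, several
    ## slots per gene if needed
    prom_genes <- sample(config$n_genes, n_prom)
    is_enh <- rep(c(FALSE, TRUE), c(n_prom, n_enh))
    gene_of <- integer(config$n_regions)
    slot_of <- integer(config$n_regions)
    gene_of[!is_enh] <- prom_genes
    if (n_enh > 0) {
      e_idx <- seq_len(n_enh)
      gene_of[is_enh] <- ((e_idx - 1) %% config$n_genes) + 1
      slot_of[is_enh] <- ((e_idx - 1) %/% config$n_genes) + 1
    }
    center <- integer(config$n_regions)
    for (i in reg_idx) {
      p <- tss$pos[gene_of[i]]
      center[i] <- if (!is_enh[i]) p else {
        p + ENH_SLOT_BASE + (slot_of[i] - 1L) * ENH_SLOT_STEP +
          sample(0:300, 1)
      }
    }
    ## a gene's regulatory elements open coordinately and share its TF
    ## dependence: trajectory cluster and bound-factor set are drawn per
    ## gene and inherited by its elements
    gene_cluster <- sample(seq_len(k), config$n_genes, replace = TRUE)
    gene_core <- vapply(seq_len(config$n_genes), function(g) {
      ## mostly single-factor binding, so each mutant affects a modest
      ## share of the library (as in a genome-scale peak set)
      n_core <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      paste(sample(CORE_TFS, n_core), collapse = ",")
    }, character(1))
    gene_dev <- vapply(seq_len(config$n_genes), function(g)
      paste(sample(DEV_TFS, sample(1:2, 1)), collapse = ","), character(1))
    gene_strength <- runif(config$n_genes, config$tf_strength_range[1],
                           config$tf_strength_range[2])
    gene_amp <- runif(config$n_genes, 1 - config$amplitude_jitter,
                      1 + config$amplitude_jitter)
    cluster <- gene_cluster[gene_of]
    core_tfs <- dev_tfs <- character(config$n_regions)
    core_tfs[is_enh] <- gene_core[gene_of[is_enh]]
    dev_tfs[is_enh] <- gene_dev[gene_of[is_enh]]
    regions <- data.frame(
      chrom = tss$chrom[gene_of], start = center - half,
      end = center + half,
      name = sprintf("region%04d", reg_idx),
      cluster = cluster, is_enhancer = is_enh,
      core_tfs = core_tfs, dev_tfs = dev_tfs,
      gene_id = tss$gene_id[gene_of], stringsAsFactors = FALSE)
    trajectories <- config$cluster_profiles[cluster, , drop = FALSE] *
      gene_amp[gene_of]
    dimnames(trajectories) <- list(regions$name, config$stages)
    links <- data.frame(element = regions$name[is_enh],
                        gene_id = regions$gene_id[is_enh],
                        stringsAsFactors = FALSE)
    truth <- list(
      region_cluster_labels = setNames(cluster, regions$name),
      region_is_enhancer = setNames(is_enh, regions$name),
      region_bound_by = setNames(core_tfs, regions$name),
      region_dev_by = setNames(dev_tfs, regions$name),
      enhancer_gene_links = links,
      trajectories = trajectories,
      region_gene = setNames(regions$gene_id, regions$name),
      region_strength = setNames(gene_strength[gene_of], regions$name),
      gene_tf_strength = setNames(gene_strength, tss$gene_id),
      amanitin_sensitive = regions$name[1])
    list(tss = tss, regions = regions, truth = truth)
  })
}

frag_length_mix <- function(n, nfr_fraction) {
  short <- runif(n) < nfr_fraction
  len <- ifelse(short, rlnorm(n, log(80), 0.25), rlnorm(n, log(180), 0.15))
  pmax(20L, as.integer(round(len)))
}

#' Generate one sample's raw fragment set
#'
#' Fragment counts per region are negative-binomial with mean proportional
#' to the region's planted trajectory value at the requested stage;
#' `condition` selects the modifier: wild-type ("wt"), a core-TF mutant
#' (regions bound by that factor depleted by 2^-mutant_effect) or
#' transcription inhibition ("amanitin": wild-type model except the planted
#' hypertranscribed region). Fragment lengths follow a bimodal
#' sub-nucleosomal/mono-nucleosomal mixture straddling 130 bp, and emitted
#' intervals are RAW (pre-Tn5-shift): running [adjust_cut_sites()] restores
#' the planted adjusted coordinates. Background fragments are scattered
#' genome-wide.
#'
#' @param config A `sim_config`.
#' @param truth Truth object from [simulate_annotation()].
#' @param regions Region table from [simulate_annotation()].
#' @param condition "wt", one of the core TFs (lower case, e.g. "pou5f3"),
#'   or "amanitin".
#' @param stage Stage label.
#' @param replicate Replicate index (selects the RNG stream).
#' @return BED-style data.frame (chrom, start, end, mapq, strand);
#'   attributes `region_counts` and `n_background` record the draws.
#' @export
simulate_fragments <- function(config, truth, regions, condition = "wt",
                               stage = config$stages[1], replicate = 1L) {
  cond_ok <- c("wt", "amanitin", tolower(CORE_TFS))
  if (!condition %in% cond_ok) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(cond_ok, collapse = ", "))
  }
  stopifnot(stage %in% config$stages)
  label <- paste("fragments", condition, stage, replicate, sep = ":")
  with_stream(config$seed, label, {
    traj <- truth$trajectories
    w <- traj[, stage]
    const <- if (sum(rowMeans(traj)) > 0) {
      config$fragment_depth * (1 - config$background_fraction) /
        sum(rowMeans(traj))
    } else 0
    mu <- const * w
    if (condition %in% tolower(CORE_TFS)) {
      tf <- CORE_TFS[match(condition, tolower(CORE_TFS))]
      bound <- vapply(strsplit(truth$region_bound_by, ","), function(x)
        tf %in% x, logical(1))
      mu[bound] <- mu[bound] *
        2^(-config$mutant_effect * truth$region_strength[bound])
    } else if (condition == "amanitin") {
      mu[truth$amanitin_sensitive] <- mu[truth$amanitin_sensitive] * 2^(-3)
    }
    counts <- if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else rpois(length(mu), mu)
    counts[mu == 0] <- 0L
    chrom_sizes <- sim_chrom_sizes(config)
    n_bg <- rpois(1, config$fragment_depth * config$background_fraction)

    frags <- list()
    for (i in seq_len(nrow(regions))) {
      if (counts[i] == 0) next
      len <- frag_length_mix(counts[i], config$nfr_fraction)
      ctr <- round(runif(counts[i], regions$start[i], regions$end[i]))
      s_adj <- pmax(10L, as.integer(ctr - len %/% 2))
      frags[[length(frags) + 1L]] <- data.frame(
        chrom = regions$chrom[i], start = s_adj, end = s_adj + len,
        stringsAsFactors = FALSE)
    }
    if (n_bg > 0) {
      chrom <- sample(names(chrom_sizes), n_bg, replace = TRUE,
                      prob = chrom_sizes / sum(chrom_sizes))
      len <- frag_length_mix(n_bg, 0.35)
      s_adj <- as.integer(round(runif(n_bg, 10, chrom_sizes[chrom] - 300)))
      frags[[length(frags) + 1L]] <- data.frame(
        chrom = chrom, start = s_adj, end = s_adj + len,
        stringsAsFactors = FALSE)
    }
    out <- if (length(frags)) do.call(rbind, frags) else
      data.frame(chrom = character(), start = integer(), end = integer())
    if (nrow(out)) {
      ## emit raw intervals: the +4/-5 shift recovers the drawn fragment
      ## (per-fragment names are added at write time to keep memory lean)
      out$start <- out$start - 4L
      out$end <- out$end + 5L
      out$mapq <- ifelse(runif(nrow(out)) < 0.02, 10L, 60L)
      out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
      out <- out[c("chrom", "start", "end", "mapq", "strand")]
    }
    attr(out, "region_counts") <- setNames(as.integer(counts), regions$name)
    attr(out, "n_background") <- n_bg
    out
  })
}

#' Generate the per-gene per-stage expression table
#'
#' Genes flagged never-expressed stay below the silent cutoff at all
#' stages; remaining genes are quiet before their activation stage and
#' express `baseline + priming_beta * delta + tf_activation * tf_load +
#' noise` from the late stage on, where delta is the planted accessibility
#' increase (256-cell to oblong axis positions 1 and 3, or the
#' first/middle stages for shorter designs) averaged over the gene's
#' linked elements, and tf_load is the number of core factors bound at its
#' elements scaled by the gene's planted dependence strength (so
#' TF-dependent genes express more, as mutant transcriptomes show).
#'
#' @param config A `sim_config`.
#' @param truth Truth from [simulate_annotation()] (needs links and
#'   trajectories).
#' @param late_stage_index Stage index from which genes express; defaults
#'   to the 4th stage (sphere) or the last stage for short designs.
#' @return data.frame gene_id x stages (RPKM); attributes `delta_access`
#'   (per gene) and `never_expressed`.
#' @export
simulate_expression <- function(config, truth, late_stage_index = NULL) {
  ns <- length(config$stages)
  if (is.null(late_stage_index)) late_stage_index <- min(4L, ns)
  i_early <- 1L
  i_late_acc <- min(3L, ns)
  with_stream(config$seed, "expression", {
    genes <- sort(unique(truth$region_gene))
    n <- length(genes)
    delta_by_region <- truth$trajectories[, i_late_acc] -
      truth$trajectories[, i_early]
    delta <- vapply(genes, function(g) {
      r <- names(truth$region_gene)[truth$region_gene == g]
      mean(delta_by_region[r])
    }, numeric(1))
    never <- runif(n) < config$silent_fraction
    ## TF-activation bonus: mean number of bound core factors over the
    ## gene's linked elements, coupling expression to mutant dependence
    n_core_region <- lengths(strsplit(truth$region_bound_by, ",")) *
      (truth$region_bound_by != "")
    ## TF load: bound core factors x dependence strength, zero for genes
    ## without any bound element
    tf_load <- vapply(genes, function(g) {
      r <- names(truth$region_gene)[truth$region_gene == g]
      nc <- max(n_core_region[match(r, names(truth$region_bound_by))])
      nc * truth$gene_tf_strength[g]
    }, numeric(1))
    expr <- matrix(0, n, ns, dimnames = list(genes, config$stages))
    for (j in seq_len(ns)) {
      if (j < late_stage_index) {
        expr[, j] <- runif(n, 0, 0.3)
      } else {
        base <- runif(n, 2, 3)
        expr[, j] <- pmax(0, base + config$priming_beta * delta +
                            config$tf_activation * tf_load +
                            rnorm(n, 0, config$noise_sd))
      }
    }
    expr[never, ] <- matrix(runif(sum(never) * ns, 0, 0.01),
                            nrow = sum(never))
    out <- data.frame(gene_id = genes, expr, stringsAsFactors = FALSE,
                      check.names = FALSE, row.names = NULL)
    attr(out, "delta_access") <- setNames(delta, genes)
    attr(out, "never_expressed") <- setNames(never, genes)
    out
  })
}

#' Generate ChIP peaks, per-region signal and region sequences
#'
#' Every planted enhancer receives a ChIP peak from each of its bound
#' factors (core and developmental); per-region ChIP and Input signal
#' tables have elevated ChIP/Input ratio at bound regions and a ratio
#' centered at 1 elsewhere; region DNA sequences carry the consensus of
#' each bound core factor's PWM at recorded positions.
#'
#' @param config A `sim_config`.
#' @param truth,regions From [simulate_annotation()].
#' @param pwms Named list of `pwm` objects keyed by TF name; defaults to
#'   the shipped synthetic core motifs.
#' @return list: `peaks` (named list of per-TF BED tables), `chip_signal` /
#'   `input_signal` (region x TF matrices), `sequences` (named character),
#'   `motif_positions` (data.frame region, tf, offset).
#' @export
simulate_chip_and_sequence <- function(config, truth, regions, pwms = NULL) {
  if (is.null(pwms)) pwms <- default_motifs()
  for (p in pwms) {
    if (p$width > config$region_width) {
      stop("PWM width exceeds region width")
    }
  }
  with_stream(config$seed, "chip", {
    tfs <- c(CORE_TFS, DEV_TFS)
    bound_mat <- vapply(tfs, function(tf) {
      core <- vapply(strsplit(truth$region_bound_by, ","), function(x)
        tf %in% x, logical(1))
      dev <- vapply(strsplit(truth$region_dev_by, ","), function(x)
        tf %in% x, logical(1))
      core | dev
    }, logical(nrow(regions)))
    peaks <- list()
    for (tf in tfs) {
      b <- which(bound_mat[, tf])
      if (!length(b)) {
        peaks[[tf]] <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), name = character())
        next
      }
      jit <- sample(-80:80, length(b), replace = TRUE)
      peaks[[tf]] <- data.frame(
        chrom = regions$chrom[b], start = regions$start[b] - 60L + jit,
        end = regions$end[b] + 60L + jit,
        name = sprintf("%s_peak%03d", tolower(tf), seq_along(b)),
        stringsAsFactors = FALSE)
    }
    nr <- nrow(regions)
    chip <- vapply(tfs, function(tf)
      rlnorm(nr, ifelse(bound_mat[, tf], log(4), 0), 0.15), numeric(nr))
    input <- matrix(rlnorm(nr * length(tfs), 0, 0.1), nr,
                    dimnames = list(regions$name, tfs))
    rownames(chip) <- regions$name

    seqs <- vapply(seq_len(nr), function(i)
      paste(sample(DNA_BASES, config$region_width, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- regions$name
    motif_pos <- list()
    for (i in seq_len(nr)) {
      planted <- intersect(names(pwms),
                           strsplit(truth$region_bound_by[i], ",")[[1]])
      off <- 40L
      for (tf in planted) {
        cons <- pwms[[tf]]$consensus
        substr(seqs[i], off + 1L, off + nchar(cons)) <- cons
        motif_pos[[length(motif_pos) + 1L]] <- data.frame(
          region = regions$name[i], tf = tf, offset = off,
          stringsAsFactors = FALSE)
        off <- off + nchar(cons) + 30L
      }
    }
    motif_positions <- if (length(motif_pos)) do.call(rbind, motif_pos) else
      data.frame(region = character(), tf = character(), offset = integer())
    list(peaks = peaks, chip_signal = chip, input_signal = input,
         sequences = seqs, motif_positions = motif_positions)
  })
}

#' Run the full generator
#'
#' Produces every input the pipeline consumes: annotation and truth,
#' wild-type fragment sets for all stages and replicates, mutant fragment
#' sets for the three core-TF mutants at the oblong stage, a genomic-DNA
#' control fragment set (uniform background), the expression table, and
#' ChIP peaks/signals/sequences.
#'
#' @param config A `sim_config`.
#' @param mutants Core-TF mutant conditions to simulate (lower-case names).
#' @param mutant_stage Stage at which mutants are sampled (default the 3rd
#'   stage, oblong).
#' @return list with elements `config`, `tss`, `regions`, `truth`,
#'   `samples` (named list of fragment tables, names like "wt_oblong_r1"),
#'   `control` (genomic DNA fragments), `expression`, `chip`,
#'   `chrom_sizes`.
#' @export
simulate_experiment <- function(config, mutants = tolower(CORE_TFS),
                                mutant_stage = NULL) {
  ann <- simulate_annotation(config)
  if (is.null(mutant_stage)) {
    mutant_stage <- config$stages[min(3L, length(config$stages))]
  }
  samples <- list()
  for (stage in config$stages) {
    for (r in seq_len(config$n_replicates)) {
      samples[[sprintf("wt_%s_r%d", stage, r)]] <-
        simulate_fragments(config, ann$truth, ann$regions, "wt", stage, r)
    }
  }
  for (m in mutants) {
    for (r in seq_len(config$n_replicates)) {
      samples[[sprintf("%s_%s_r%d", m, mutant_stage, r)]] <-
        simulate_fragments(config, ann$truth, ann$regions, m, mutant_stage, r)
    }
  }
  control <- with_stream(config$seed, "control", {
    chrom_sizes <- sim_chrom_sizes(config)
    n <- as.integer(config$fragment_depth)
    chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    len <- frag_length_mix(n, 0.5)
    s <- as.integer(round(runif(n, 10, chrom_sizes[chrom] - 300)))
    data.frame(chrom = chrom, start = s - 4L, end = s + len + 5L,
               mapq = 60L, strand = "+", stringsAsFactors = FALSE)
  })
  expression <- simulate_expression(config, ann$truth)
  chip <- simulate_chip_and_sequence(config, ann$truth, ann$regions)
  list(config = config, tss = ann$tss, regions = ann$regions,
       truth = ann$truth, samples = samples, control = control,
       expression = expression, chip = chip,
       chrom_sizes = sim_chrom_sizes(config),
       mutant_stage = mutant_stage)
}

#' Write a simulated experiment to disk
#'
#' Emits per-sample 6-column fragment BEDs, per-TF ChIP peak BEDs, signal
#' and expression TSVs, region sequences as FASTA, ground-truth TSVs and a
#' JSON manifest recording config and seed.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_bed6 <- function(fr) {
    if (nrow(fr)) {
      fr$name <- sprintf("frag%07d", seq_len(nrow(fr)))
      fr$score <- fr$mapq
      fr <- fr[c("chrom", "start", "end", "name", "score", "strand")]
    }
    fr
  }
  for (nm in names(sim$samples)) {
    write_bed(as_bed6(sim$samples[[nm]]), file.path(dir, paste0(nm, ".bed")))
  }
  write_bed(as_bed6(sim$control), file.path(dir, "control_gdna.bed"))
  for (tf in names(sim$chip$peaks)) {
    write_bed(sim$chip$peaks[[tf]],
              file.path(dir, sprintf("chip_%s.bed", tolower(tf))))
  }
  write_tsv_table(as.data.frame(sim$chip$chip_signal),
                  file.path(dir, "chip_signal.tsv"), rownames_as = "region")
  write_tsv_table(as.data.frame(sim$chip$input_signal),
                  file.path(dir, "input_signal.tsv"), rownames_as = "region")
  write_tsv_table(sim$expression, file.path(dir, "expression.tsv"))
  write_tsv_table(sim$tss, file.path(dir, "tss.tsv"))
  write_tsv_table(sim$regions, file.path(dir, "regions_truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$chip$sequences),
    file.path(dir, "region_sequences.fa"))
  cfg <- sim$config
  cfg$cluster_profiles <- apply(cfg$cluster_profiles, 1, paste,
                                collapse = ",")
  write_manifest(list(config = unclass(cfg), seed = sim$config$seed,
                      n_samples = length(sim$samples)),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
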