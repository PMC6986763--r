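## Regulatory-element definition: promoters around TSSs, rule-based putative
## enhancers (distal + core-TF + developmental-TF ChIP support), nearest-TSS
## gene linking and expression-based gene classes.

## Core pluripotency factors and the developmental TFs used for enhancer
## support, as factor-class constants.
CORE_TFS <- c("Pou5f3", "Sox19b", "Nanog")
DEV_TFS <- c("Smad2", "FoxH1", "Mxtx2", "Eomesa", "Ta", "Tbx16", "Mixl1")

## Distance between a point (0-based TSS position) and a half-open interval:
## 0 if the point lies inside, otherwise the gap to the nearest included base.
point_interval_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos < end, 0L,
         ifelse(pos < start, start - pos, pos - (end - 1L)))
}

#' Define promoter elements around TSSs
#'
#' Promoters are fixed windows centered on the TSS (2 kb by default, i.e.
#' +/- 1 kb). Windows running off a chromosome end are clipped and flagged.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `pos` (0-based), `strand`.
#' @param window Window width in bp, default 2000.
#' @param chrom_sizes Optional named vector for right-end clipping.
#' @return BED-style data.frame of promoters with `gene_id`, `element_class`
#'   and a `clipped` flag.
#' @export
define_promoters <- function(tss, window = 2000L, chrom_sizes = NULL) {
  half <- window %/% 2
  start <- tss$pos - half
  end <- tss$pos + half
  clipped <- start < 0
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[tss$chrom])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  data.frame(chrom = tss$chrom, start = start, end = end,
             name = paste0("prom_", tss$gene_id),
             gene_id = tss$gene_id, strand = tss$strand,
             element_class = "promoter", clipped = clipped,
             stringsAsFactors = FALSE)
}

min_tss_distance <- function(regions, tss) {
  vapply(seq_len(nrow(regions)), function(i) {
    p <- tss$pos[tss$chrom == regions$chrom[i]]
    if (!length(p)) return(Inf)
    min(point_interval_distance(p, regions$start[i], regions$end[i]))
  }, numeric(1))
}

#' Define putative enhancers from consensus peaks and ChIP support
#'
#' A consensus peak is a putative enhancer iff it is distal (>= `distal_min`
#' bp from every TSS, where distance is 0 for a TSS inside the peak and the
#' gap to the nearest peak base otherwise), overlaps (>= 1 bp) at least one
#' core-factor ChIP peak (Pou5f3/Sox19b(SoxB1)/Nanog) and at least one
#' developmental-TF ChIP peak. Supporting TFs are recorded per element.
#'
#' @param peaks Consensus peak table.
#' @param tss TSS table (see [define_promoters()]).
#' @param core_chip Named list of BED-style ChIP peak tables for core TFs.
#' @param dev_chip Named list for developmental TFs.
#' @param distal_min Minimum TSS distance in bp, default 1000.
#' @return Enhancer subset of `peaks` with `element_class`, `core_support`
#'   and `dev_support` columns (comma-separated TF names).
#' @export
define_enhancers <- function(peaks, tss, core_chip, dev_chip,
                             distal_min = 1000L) {
  if (!length(core_chip) || !length(dev_chip)) {
    warning("empty ChIP set list; no enhancers can be defined")
    return(peaks[integer(0), , drop = FALSE])
  }
  distal <- min_tss_distance(peaks, tss) >= distal_min
  support <- function(sets) {
    hits <- vapply(sets, function(s) overlaps_any_bed(peaks, s),
                   logical(nrow(peaks)))
    matrix(hits, nrow = nrow(peaks), dimnames = list(NULL, names(sets)))
  }
  core_hit <- support(core_chip)
  dev_hit <- support(dev_chip)
  keep <- distal & rowSums(core_hit) >= 1 & rowSums(dev_hit) >= 1
  out <- peaks[keep, , drop = FALSE]
  collapse <- function(m) vapply(seq_len(nrow(m)), function(i)
    paste(colnames(m)[m[i, ]], collapse = ","), character(1))
  out$element_class <- rep("enhancer", nrow(out))
  out$core_support <- collapse(core_hit[keep, , drop = FALSE])
  out$dev_support <- collapse(dev_hit[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Link regulatory elements to their nearest gene
#'
#' Each element is linked to the TSS with minimal point-to-interval distance
#' provided that distance is at most `link_max` (20 kb default); otherwise it
#' stays unlinked. Ties are broken deterministically: lower TSS coordinate,
#' then lexicographic gene id. The signed distance is negative when the TSS
#' lies left of the element start.
#'
#' @param elements BED-style element table with a `name` column.
#' @param tss TSS table.
#' @param link_max Maximum linking distance in bp, default 20000.
#' @return data.frame element, gene_id, distance (>= 0), signed_distance;
#'   one row per linked element.
#' @export
link_to_genes <- function(elements, tss, link_max = 20000L) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    cand <- tss[tss$chrom == elements$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    d <- point_interval_distance(cand$pos, elements$start[i], elements$end[i])
    ord <- order(d, cand$pos, cand$gene_id)
    j <- ord[1]
    if (d[j] > link_max) return(NULL)
    signed <- if (cand$pos[j] < elements$start[i]) -d[j] else d[j]
    data.frame(element = elements$name[i], gene_id = cand$gene_id[j],
               distance = d[j], signed_distance = signed,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(element = character(), gene_id = character(),
                      distance = numeric(), signed_distance = numeric()))
  }
  do.call(rbind, rows)
}

#' Classify genes by stage-wise expression
#'
#' Flags each gene as expressed per stage (RPKM >= `expressed_min`), marks
#' "late-activated" genes (expressed at `later_stage` but not at
#' `reference_stage`), and "never-expressed" control genes whose summed
#' expression over all stages stays below `silent_max`.
#'
#' @param expression data.frame: `gene_id` plus one numeric RPKM column per
#'   stage.
#' @param reference_stage,later_stage Stage column names; default to the
#'   last two stage columns.
#' @param expressed_min RPKM threshold for "expressed", default 1.0.
#' @param silent_max Summed-RPKM threshold for "never expressed", default 0.1.
#' @return data.frame gene_id, expressed.<stage> flags, late_activated,
#'   never_expressed.
#' @export
classify_gene_sets <- function(expression, reference_stage = NULL,
                               later_stage = NULL, expressed_min = 1.0,
                               silent_max = 0.1) {
  stage_cols <- setdiff(names(expression), "gene_id")
  if (length(stage_cols) < 2) stop("need at least two stage columns")
  if (is.null(reference_stage)) reference_stage <- stage_cols[length(stage_cols) - 1]
  if (is.null(later_stage)) later_stage <- stage_cols[length(stage_cols)]
  if (!all(c(reference_stage, later_stage) %in% stage_cols)) {
    stop("missing stage column: ",
         setdiff(c(reference_stage, later_stage), stage_cols))
  }
  expr <- as.matrix(expression[stage_cols])
  flags <- expr >= expressed_min
  colnames(flags) <- paste0("expressed.", stage_cols)
  out <- data.frame(gene_id = expression$gene_id, flags,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$late_activated <- expr[, later_stage] >= expressed_min &
    expr[, reference_stage] < expressed_min
  out$never_expressed <- rowSums(expr) < silent_max
  out
}
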