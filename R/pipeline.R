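# End-to-end analysis of a (simulated) TaDa experiment, and evaluation of
# recovery against the planted ground truth. These wrappers chain the
# module functions exactly as a real analysis would: counting, RPM, peak
# calling per fusion/Dam-only pair with replicate-consistency filtering,
# quantile-normalized averaged ratio profiles, consensus clustering,
# accessibility profiles, nearest-TSS annotation and DE enrichment.

tada_constructs <- function() {
  data.frame(factor = rep(c("Notch", "RBPJ"), each = 2),
             cell_type = rep(c("RGC", "IPC"), 2),
             construct = c("RGC_Notch", "IPC_Notch", "RGC_RBPJ", "IPC_RBPJ"),
             stringsAsFactors = FALSE)
}

#' Run the full TaDa analysis on a simulated experiment
#'
#' For every Dam-fusion construct, peaks are called for each fusion x
#' Dam-only replicate pair and filtered for presence in all pairwise
#' comparisons; log2 ratio profiles of all pairs are quantile-normalized,
#' averaged and backtransformed; construct peak sets are merged into
#' consensus peaks, the z-scored length-normalized intensity matrix is
#' clustered by silhouette-optimized k-means; Dam-only replicates give
#' per-cell-type accessibility profiles.
#'
#' @param sim A `tada_sim` from [simulate_experiment()].
#' @param params Peak caller parameters ([peak_params()]).
#' @param k_range Candidate cluster numbers (default 2:12).
#' @param n_init k-means restarts per k.
#' @param cluster_seed Seed for the k-means seed stream.
#' @return List of class `tada_analysis`: `peaks` (per construct),
#'   `profiles` (averaged linear per construct), `consensus`, `matrix`,
#'   `k_selection`, `clusters`, `accessibility` (per cell type),
#'   `bins`, `frags`.
#' @export
run_tada_analysis <- function(sim, params = peak_params(),
                              k_range = 2:12, n_init = 25L,
                              cluster_seed = 1L) {
  stopifnot(inherits(sim, "tada_sim"))
  truth <- sim$truth
  seqlen <- genome_seqlengths(truth$genome)
  bins <- fixed_bins(seqlen, 300L)
  frags <- truth$frags
  cfg <- truth$config
  reps <- seq_len(cfg$replicates)
  counts_bins <- lapply(sim$reads, count_reads, bins = bins)
  constructs <- tada_constructs()
  peaks <- list()
  profiles <- list()
  for (i in seq_len(nrow(constructs))) {
    fct <- constructs$factor[i]
    ct <- constructs$cell_type[i]
    nm <- constructs$construct[i]
    pair_peaks <- list()
    pair_ratios <- list()
    for (fr in reps) {
      fus <- counts_bins[[sprintf("%s_%s_rep%d", fct, ct, fr)]]
      for (cr in reps) {
        ctl <- counts_bins[[sprintf("Dam_%s_rep%d", ct, cr)]]
        lab <- sprintf("%s_f%d_c%d", nm, fr, cr)
        pair_peaks[[lab]] <- call_broad_peaks(fus, ctl, params, label = lab)
        pair_ratios[[lab]] <- compute_ratio(
          rpm_normalize(fus), rpm_normalize(ctl), frags,
          pseudocount = params$pseudocount, construct = nm, replicate = lab)
      }
    }
    peaks[[nm]] <- replicate_consistent_peaks(
      pair_peaks, min_peak_len = params$min_peak_len, label = nm)
    profiles[[nm]] <- average_backtransform(
      quantile_normalize_profiles(pair_ratios))
  }
  consensus <- merge_consensus(peaks)
  mat <- intensity_matrix(consensus, profiles)
  ksel <- select_k(mat, k_range = k_range, n_init = n_init,
                   seed = cluster_seed)
  accessibility <- lapply(stats::setNames(c("RGC", "IPC"), c("RGC", "IPC")),
                          function(ct) {
    ctl <- lapply(reps, function(r) {
      count_reads(sim$reads[[sprintf("Dam_%s_rep%d", ct, r)]], frags)
    })
    accessibility_profile(ctl, cell_type = ct)
  })
  structure(list(peaks = peaks, profiles = profiles, consensus = consensus,
                 matrix = mat, k_selection = ksel,
                 clusters = ksel$clustering,
                 accessibility = accessibility, bins = bins, frags = frags),
            class = "tada_analysis")
}

# planted bases occupied by `factor` in `cell_type`
occupied_sites <- function(truth, factor, cell_type) {
  arch <- tada_archetypes()
  ch <- paste0(tolower(factor), "_", tolower(cell_type))
  truth$sites[arch[[ch]][S4Vectors::mcols(truth$sites)$archetype] > 0]
}

#' Base-level peak recovery against planted sites
#'
#' Pools, over the four constructs, the planted bases occupied by the
#' profiled factor in the profiled cell type and the called peak bases,
#' and reports base-level sensitivity (planted bases recovered) and
#' precision (called bases that are planted).
#'
#' @param analysis A `tada_analysis`.
#' @param truth The matching `tada_truth`.
#' @return List with `sensitivity`, `precision` and the per-construct
#'   breakdown.
#' @export
evaluate_peak_recovery <- function(analysis, truth) {
  constructs <- tada_constructs()
  tp <- fp <- fn <- 0
  per <- list()
  for (i in seq_len(nrow(constructs))) {
    called <- GenomicRanges::reduce(analysis$peaks[[constructs$construct[i]]])
    planted <- GenomicRanges::reduce(occupied_sites(
      truth, constructs$factor[i], constructs$cell_type[i]))
    inter <- sum(IRanges::width(GenomicRanges::intersect(called, planted)))
    cb <- sum(IRanges::width(called))
    pb <- sum(IRanges::width(planted))
    tp <- tp + inter; fp <- fp + (cb - inter); fn <- fn + (pb - inter)
    per[[constructs$construct[i]]] <- c(
      sensitivity = if (pb > 0) inter / pb else NA_real_,
      precision = if (cb > 0) inter / cb else NA_real_)
  }
  list(sensitivity = tp / (tp + fn), precision = tp / (tp + fp),
       per_construct = per)
}

#' Archetype labels of consensus peaks
#'
#' Assigns each consensus peak the archetype of the planted site it
#' overlaps most (NA for peaks overlapping no site).
#'
#' @param consensus Consensus peak `GRanges`.
#' @param truth A `tada_truth`.
#' @return Integer vector of archetypes (NA where unmatched).
#' @export
consensus_archetypes <- function(consensus, truth) {
  hits <- GenomicRanges::findOverlaps(consensus, truth$sites)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(consensus)[S4Vectors::queryHits(hits)],
    IRanges::ranges(truth$sites)[S4Vectors::subjectHits(hits)]))
  lab <- rep(NA_integer_, length(consensus))
  for (i in unique(S4Vectors::queryHits(hits))) {
    sel <- S4Vectors::queryHits(hits) == i
    lab[i] <- S4Vectors::mcols(truth$sites)$archetype[
      S4Vectors::subjectHits(hits)[sel][which.max(ov[sel])]]
  }
  lab
}

#' Map recovered clusters to planted archetypes
#'
#' For each k-means cluster, the planted archetype most frequent among
#' its peaks (majority vote).
#'
#' @param analysis A `tada_analysis`.
#' @param truth A `tada_truth`.
#' @return Integer vector, one archetype per cluster 1..k.
#' @export
cluster_archetype_map <- function(analysis, truth) {
  arch <- consensus_archetypes(analysis$consensus, truth)
  vapply(seq_len(analysis$clusters$k), function(cl) {
    tab <- table(arch[analysis$clusters$cluster == cl])
    if (!length(tab)) return(NA_integer_)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

#' TSS table of simulated genes
#'
#' @param truth A `tada_truth`.
#' @return Data frame suitable for [nearest_tss()].
#' @export
truth_tss_table <- function(truth) {
  truth$genes[, c("gene_id", "gene_name", "chrom", "tss", "strand",
                  "biotype")]
}
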