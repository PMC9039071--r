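#' Region x position signal matrix
#'
#' Samples a profile around region midpoints: rows are regions, columns
#' position bins of width `binwidth` spanning `[-flank, +flank)` around
#' the anchor. Each cell is the length-weighted mean of fragment scores
#' overlapping that window; windows extending past chromosome ends yield
#' `NA` (ignored in averages). Regions overlapping any exclusion interval
#' are dropped entirely (signal from excluded loci, e.g. mitochondrial or
#' promoter-plasmid regions, should not enter average accessibility
#' plots).
#'
#' @param profile A `tada_profile` (ratio or accessibility).
#' @param regions `GRanges` of regions (e.g. peaks); anchored at their
#'   midpoints.
#' @param flank Flank size in bp (default 2500); must be a multiple of
#'   `binwidth`.
#' @param binwidth Position bin width in bp (default 150).
#' @param exclusions Optional `GRanges` exclusion list.
#' @return Numeric matrix (regions x positions) with column names the bp
#'   offsets of each window start; row order preserves input region order.
#' @export
signal_matrix <- function(profile, regions, flank = 2500L, binwidth = 150L,
                          exclusions = NULL) {
  stopifnot(flank %% binwidth == 0, flank > 0, binwidth > 0)
  if (!is.null(exclusions) && length(exclusions)) {
    drop <- GenomicRanges::countOverlaps(regions, exclusions,
                                         ignore.strand = TRUE) > 0
    regions <- regions[!drop]
  }
  if (!length(regions)) stop("no regions left after exclusion")
  frags <- profile$frags
  seqlen <- GenomeInfoDb::seqlengths(frags)
  ncol <- 2L * flank %/% binwidth
  offsets <- seq(-flank, flank - binwidth, by = binwidth)
  mid <- (BiocGenerics::start(regions) + BiocGenerics::end(regions)) %/% 2L
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  win_start <- rep(mid, each = ncol) + rep(offsets, length(regions))
  win_chrom <- rep(chrom, each = ncol)
  wins <- GenomicRanges::GRanges(
    win_chrom, IRanges::IRanges(win_start, width = binwidth))
  vals <- project_weighted_mean(frags, profile$score, wins)
  # windows not fully inside the chromosome are missing (chromosomes of
  # unknown length are bounded only by the fragment tiling itself)
  sl <- seqlen[win_chrom]
  out_of_bounds <- win_start < 1L |
    (!is.na(sl) & (win_start + binwidth - 1L) > sl)
  vals[out_of_bounds] <- NA_real_
  m <- matrix(vals, nrow = length(regions), ncol = ncol, byrow = TRUE,
              dimnames = list(NULL, offsets))
  rn <- S4Vectors::mcols(regions)$consensus_id
  if (!is.null(rn)) rownames(m) <- rn
  m
}

#' Column-wise average profile with standard error
#'
#' @param m Signal matrix from [signal_matrix()] with >= 2 rows.
#' @return Data frame per position: `position` (bp offset), `mean`,
#'   `sem` (sd / sqrt(n)), `n` (non-missing rows).
#' @export
average_profile <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0L) stop("empty signal matrix")
  if (nrow(m) < 2L) stop("s.e.m. needs at least two regions")
  n <- colSums(!is.na(m))
  data.frame(position = as.integer(colnames(m)),
             mean = colMeans(m, na.rm = TRUE),
             sem = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(n),
             n = n, row.names = NULL)
}

#' Nonparametric accessibility comparison between groups
#'
#' Omnibus Kruskal-Wallis test across cell-type groups of per-region
#' summary values, followed by post-hoc pairwise two-sided Wilcoxon
#' rank-sum tests with Holm adjustment.
#'
#' @param values Numeric vector of per-region summaries (e.g. mean
#'   accessibility over a peak).
#' @param groups Factor/character of group (cell type) labels, same
#'   length; each group needs >= 3 observations.
#' @return List of class `group_comparison`: `kruskal_p`, `pairwise_p`
#'   (matrix of Holm-adjusted p-values), `group_medians`.
#' @export
compare_accessibility <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(stats::pairwise.wilcox.test(
    values, groups, p.adjust.method = "holm", exact = FALSE))
  structure(list(kruskal_p = kw$p.value,
                 pairwise_p = pw$p.value,
                 group_medians = tapply(values, groups, stats::median)),
            class = "group_comparison")
}
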