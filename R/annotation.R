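#' Associate peaks with the nearest protein-coding TSS
#'
#' Each peak is assigned the protein-coding TSS minimizing the distance
#' along the linear genome (0 if the TSS lies inside the peak). Equidistant
#' TSSs are resolved toward the lexicographically smallest `gene_id`. The
#' signed distance is positive when the TSS lies downstream (right) of the
#' peak and negative when upstream (left).
#'
#' @param peaks Peak `GRanges`.
#' @param tss Data frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position) and optionally `gene_name`, `strand`, `biotype`.
#' @param biotype_filter Keep only TSSs of this biotype when a `biotype`
#'   column is present (default `"protein_coding"`).
#' @return Data frame with `peak_id`, `gene_id`, `distance`; peaks on
#'   chromosomes without any TSS get `NA` with a warning.
#' @export
nearest_tss <- function(peaks, tss, biotype_filter = "protein_coding") {
  stopifnot(is.data.frame(tss), nrow(tss) > 0)
  if (!is.null(tss$biotype) && !is.null(biotype_filter)) {
    tss <- tss[tss$biotype == biotype_filter, , drop = FALSE]
  }
  if (nrow(tss) == 0) stop("no TSS left after biotype filtering")
  peak_id <- S4Vectors::mcols(peaks)$consensus_id
  if (is.null(peak_id)) peak_id <- sprintf("peak_%05d", seq_along(peaks))
  gene <- rep(NA_character_, length(peaks))
  dist_out <- rep(NA_real_, length(peaks))
  pk_chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  start0 <- BiocGenerics::start(peaks) - 1L   # 0-based half-open edges
  end0 <- BiocGenerics::end(peaks)
  for (chrom in unique(pk_chrom)) {
    sel_t <- which(tss$chrom == chrom)
    sel_p <- which(pk_chrom == chrom)
    if (!length(sel_t)) next
    t0 <- tss$tss[sel_t]
    for (i in sel_p) {
      # signed edge distance: 0 inside, start0 - tss upstream (negative),
      # tss - end0 downstream (positive)
      d <- ifelse(t0 >= start0[i] & t0 < end0[i], 0,
                  ifelse(t0 < start0[i], start0[i] - t0, t0 - end0[i]))
      cand <- which(d == min(d))
      win <- cand[order(tss$gene_id[sel_t][cand])][1L]
      gene[i] <- tss$gene_id[sel_t][win]
      dist_out[i] <- if (d[win] == 0) 0 else
        if (t0[win] < start0[i]) -d[win] else d[win]
    }
  }
  if (anyNA(gene)) {
    warning("peak(s) on chromosomes without TSS annotation: ",
            sum(is.na(gene)), " association(s) missing")
  }
  data.frame(peak_id = peak_id, gene_id = gene, distance = dist_out,
             stringsAsFactors = FALSE)
}

#' Build collapsed genomic feature sets
#'
#' From tabular transcript models, derives the feature categories used
#' for peak-overlap enrichment: `upstream5kb` (strand-aware 5 kb upstream
#' of each transcript's TSS), `five_prime_utr`, `three_prime_utr`,
#' `exon`, `intron` (transcript extent minus exons) and `intergenic`
#' (genome minus gene bodies and upstream regions). Overlapping regions
#' are collapsed feature-wise; distinct categories may still overlap each
#' other.
#'
#' @param gene_models Data frame with one row per transcript feature:
#'   columns `gene_id`, `transcript_id`, `chrom`, `strand` (`+`/`-`),
#'   `feature` (`exon`, `five_prime_utr`, `three_prime_utr`), `start`
#'   (0-based), `end` (exclusive).
#' @param seqlengths Named chromosome lengths.
#' @param upstream Upstream window size in bp (default 5000).
#' @return Named list of collapsed `GRanges`, one per category.
#' @export
build_features <- function(gene_models, seqlengths, upstream = 5000L) {
  gm <- gene_models
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "feature", "start", "end") %in% names(gm)))
  if (any(gm$end > seqlengths[gm$chrom] | gm$start < 0)) {
    stop("transcript feature outside chromosome bounds")
  }
  as_gr <- function(df) {
    if (!nrow(df)) return(GenomicRanges::GRanges(seqlengths = seqlengths))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end),
                                 strand = df$strand)
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
    gr
  }
  exons <- as_gr(gm[gm$feature == "exon", ])
  utr5 <- as_gr(gm[gm$feature == "five_prime_utr", ])
  utr3 <- as_gr(gm[gm$feature == "three_prime_utr", ])
  collapse <- function(gr) {
    out <- GenomicRanges::reduce(GenomicRanges::granges(gr),
                                 ignore.strand = TRUE)
    BiocGenerics::strand(out) <- "*"
    out
  }
  # transcript extents and introns
  tx_rows <- gm[gm$feature == "exon", ]
  tx_split <- split(seq_len(nrow(tx_rows)), tx_rows$transcript_id)
  tx_list <- lapply(tx_split, function(idx) {
    chrom <- tx_rows$chrom[idx[1]]
    strand <- tx_rows$strand[idx[1]]
    c(chrom = chrom, strand = strand,
      start = min(tx_rows$start[idx]), end = max(tx_rows$end[idx]))
  })
  tx_df <- data.frame(
    transcript_id = names(tx_list),
    chrom = vapply(tx_list, `[[`, "", "chrom"),
    strand = vapply(tx_list, `[[`, "", "strand"),
    start = as.integer(vapply(tx_list, `[[`, "", "start")),
    end = as.integer(vapply(tx_list, `[[`, "", "end")),
    stringsAsFactors = FALSE)
  bodies <- as_gr(tx_df)
  introns <- GenomicRanges::setdiff(collapse(bodies), collapse(exons))
  # strand-aware upstream windows
  plus <- tx_df$strand != "-"
  up_start0 <- ifelse(plus, pmax(0L, tx_df$start - upstream), tx_df$end)
  up_end0 <- ifelse(plus, tx_df$start,
                    pmin(seqlengths[tx_df$chrom], tx_df$end + upstream))
  up_df <- data.frame(chrom = tx_df$chrom, strand = tx_df$strand,
                      start = up_start0, end = up_end0,
                      stringsAsFactors = FALSE)
  up_df <- up_df[up_df$end > up_df$start, , drop = FALSE]
  upstream5kb <- as_gr(up_df)
  genome_gr <- GenomicRanges::GRanges(
    names(seqlengths), IRanges::IRanges(1L, unname(seqlengths)))
  GenomeInfoDb::seqlengths(genome_gr) <- seqlengths
  genic <- GenomicRanges::union(collapse(bodies), collapse(upstream5kb))
  intergenic <- GenomicRanges::setdiff(genome_gr, genic)
  list(upstream5kb = collapse(upstream5kb),
       five_prime_utr = collapse(utr5),
       three_prime_utr = collapse(utr3),
       exon = collapse(exons),
       intron = introns,
       intergenic = intergenic)
}

# covered-bp prefix helper: bp of `category` covered within [1, x] per query
covered_upto <- function(x, starts, ends, cumcov) {
  idx <- findInterval(x, starts)
  out <- numeric(length(x))
  has <- idx >= 1L
  out[has] <- cumcov[idx[has]] +
    pmax(0, pmin(x[has], ends[idx[has]]) - starts[idx[has]] + 1)
  out
}

#' Randomized feature-overlap enrichment
#'
#' Observed overlap of peaks with each feature category (bp, as a percent
#' of total peak bp) is compared with a randomization null in which every
#' peak is re-placed uniformly at random within its own chromosome
#' (length-preserving; placed peaks may overlap each other), with whole
#' chromosomes as the workspace. The empirical enrichment p-value uses the
#' add-one rule and is therefore never 0.
#'
#' @param peaks Peak `GRanges`.
#' @param features Named list of collapsed `GRanges`
#'   ([build_features()]).
#' @param seqlengths Named chromosome lengths (the workspace).
#' @param n_samples Number of random placements (>= 100; default 10000).
#' @param seed Integer seed.
#' @return Data frame per category: `observed_percent`,
#'   `expected_percent`, `fold`, `p_enrich`, `p_deplete`, `n_samples`.
#' @export
feature_overlap_enrichment <- function(peaks, features, seqlengths,
                                       n_samples = 10000L, seed = 1L) {
  stopifnot(n_samples >= 100L, length(peaks) > 0)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  w <- IRanges::width(peaks)
  if (any(w > seqlengths[chrom])) stop("peak longer than its chromosome")
  total_bp <- sum(w)
  set.seed(seed)
  # presample random starts: matrix peaks x n_samples
  starts <- matrix(0L, length(peaks), n_samples)
  for (i in seq_along(peaks)) {
    starts[i, ] <- 1L + floor(stats::runif(n_samples) *
                                (seqlengths[chrom[i]] - w[i] + 1))
  }
  res <- lapply(names(features), function(cat) {
    fgr <- GenomicRanges::reduce(features[[cat]])
    # per-peak overlap sum (each placed peak counts individually in the
    # null, so the observed statistic must match)
    hits <- GenomicRanges::findOverlaps(peaks, fgr)
    obs <- sum(IRanges::width(IRanges::pintersect(
      IRanges::ranges(peaks)[S4Vectors::queryHits(hits)],
      IRanges::ranges(fgr)[S4Vectors::subjectHits(hits)])))
    samp <- numeric(n_samples)
    for (chr in unique(chrom)) {
      sel <- which(chrom == chr)
      sub <- fgr[GenomeInfoDb::seqnames(fgr) == chr]
      if (!length(sub)) next
      st <- BiocGenerics::start(sub); en <- BiocGenerics::end(sub)
      cumcov <- c(0, cumsum(en - st + 1))[seq_along(st)]
      a <- starts[sel, , drop = FALSE]
      b <- a + w[sel] - 1L
      ov <- covered_upto(as.vector(b), st, en, cumcov) -
        covered_upto(as.vector(a) - 1, st, en, cumcov)
      samp <- samp + colSums(matrix(ov, nrow = length(sel)))
    }
    obs_pct <- 100 * obs / total_bp
    samp_pct <- 100 * samp / total_bp
    data.frame(category = cat,
               observed_percent = obs_pct,
               expected_percent = mean(samp_pct),
               fold = if (mean(samp_pct) > 0) obs_pct / mean(samp_pct) else NA_real_,
               p_enrich = (1 + sum(samp_pct >= obs_pct)) / (n_samples + 1),
               p_deplete = (1 + sum(samp_pct <= obs_pct)) / (n_samples + 1),
               n_samples = n_samples,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
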