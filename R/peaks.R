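#' Broad peak caller parameters
#'
#' @param fdr_threshold Benjamini-Hochberg q-value cutoff for significant
#'   bins (stringent default `1e-5`).
#' @param max_gap Maximum gap (bp) between significant bins merged into one
#'   broad peak (default 900, i.e. three 300 bp bins).
#' @param min_peak_len Minimum peak length in bp (default 300).
#' @param pseudocount RPM pseudocount used for the reported peak score.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(fdr_threshold = 1e-5, max_gap = 900L,
                        min_peak_len = 300L, pseudocount = 0.5) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, max_gap >= 0)
  structure(list(fdr_threshold = fdr_threshold,
                 max_gap = as.integer(max_gap),
                 min_peak_len = as.integer(min_peak_len),
                 pseudocount = pseudocount),
            class = "peak_params")
}

#' Call broad peaks from a Dam-fusion/Dam-only pair
#'
#' A self-contained Poisson broad caller: for each fixed-width bin the
#' local rate is the Dam-only control count scaled to the fusion depth,
#' floored at the genome-wide mean fusion rate; the per-bin p-value is the
#' upper-tail Poisson probability of the observed fusion count;
#' Benjamini-Hochberg q-values are computed across all bins; significant
#' bins closer than `max_gap` are merged; peaks shorter than
#' `min_peak_len` are dropped. The Dam-only control is a matched local
#' background, so no multi-scale lambda windows are used. An adapter for
#' externally called peak files is available via [read_broadpeak()].
#'
#' @param fusion,control `binned_counts` in raw units on the same fixed
#'   bin system, with positive library sizes.
#' @param params A [peak_params()] list.
#' @param label Label recorded on the peak set (construct/replicate pair).
#' @return `GRanges` of peaks with metadata columns `score` (mean linear
#'   RPM ratio over member bins) and `qvalue` (min member q), sorted and
#'   non-overlapping; `metadata()$label` carries the label.
#' @export
call_broad_peaks <- function(fusion, control, params = peak_params(),
                             label = NA_character_) {
  stopifnot(inherits(fusion, "binned_counts"),
            inherits(control, "binned_counts"))
  if (fusion$units != "raw" || control$units != "raw") {
    stop("peak calling uses raw counts")
  }
  if (length(fusion$counts) == 0L) stop("empty counts")
  if (control$library_size <= 0) stop("zero-depth control")
  if (!identical(IRanges::ranges(fusion$bins),
                 IRanges::ranges(control$bins))) {
    stop("fusion and control are on different bin systems")
  }
  sf <- fusion$library_size / control$library_size
  lambda <- pmax(control$counts * sf, mean(fusion$counts))
  pvals <- stats::ppois(fusion$counts - 1, lambda, lower.tail = FALSE)
  qvals <- stats::p.adjust(pvals, method = "BH")
  sig <- which(qvals < params$fdr_threshold)
  empty <- GenomicRanges::GRanges()
  S4Vectors::metadata(empty)$label <- label
  if (!length(sig)) return(empty)
  merged <- GenomicRanges::reduce(fusion$bins[sig],
                                  min.gapwidth = params$max_gap + 1L)
  merged <- merged[IRanges::width(merged) >= params$min_peak_len]
  if (!length(merged)) return(empty)
  frpm <- fusion$counts * 1e6 / fusion$library_size
  crpm <- control$counts * 1e6 / control$library_size
  ratio <- (frpm + params$pseudocount) / (crpm + params$pseudocount)
  hits <- GenomicRanges::findOverlaps(merged, fusion$bins[sig])
  S4Vectors::mcols(merged)$score <- as.numeric(
    rowsum(ratio[sig][S4Vectors::subjectHits(hits)],
           S4Vectors::queryHits(hits)) /
      tabulate(S4Vectors::queryHits(hits), length(merged)))
  qv <- tapply(qvals[sig][S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), min)
  qvalue <- rep(NA_real_, length(merged))
  qvalue[as.integer(names(qv))] <- as.numeric(qv)
  S4Vectors::mcols(merged)$qvalue <- qvalue
  S4Vectors::metadata(merged)$label <- label
  sort(merged)
}

#' Read an externally produced broadPeak/narrowPeak/BED peak file
#'
#' Adapter for users preferring an external peak caller; q-values are
#' taken from the 9th column (-log10) when present.
#'
#' @param path Peak file path (BED6+, 0-based half-open on disk).
#' @param label Label to record.
#' @return Peak `GRanges` compatible with [replicate_consistent_peaks()].
#' @export
read_broadpeak <- function(path, label = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  S4Vectors::mcols(gr)$score <- if (ncol(df) >= 7) df[[7]] else
    if (ncol(df) >= 5) df[[5]] else NA_real_
  S4Vectors::mcols(gr)$qvalue <- if (ncol(df) >= 9) 10^(-df[[9]]) else NA_real_
  S4Vectors::metadata(gr)$label <- label
  sort(gr)
}

#' Replicate-consistent peaks
#'
#' Retains only signal present in all pairwise fusion/control comparisons
#' of one experimental condition. In the default `"intersect"` mode a
#' genomic base survives iff it is covered by a peak in every input set
#' (strictest reading); surviving bases are assembled into maximal
#' intervals. In `"overlap"` mode the union of all peaks is kept wherever
#' every input set contributes at least one overlapping peak.
#'
#' @param peaksets List of peak `GRanges` (>= 1; a single set is returned
#'   unchanged apart from the length filter).
#' @param min_peak_len Minimum surviving interval length (default 300 bp).
#' @param mode `"intersect"` (base-level intersection) or `"overlap"`.
#' @param label Label for the output set.
#' @return Peak `GRanges` with `score` = mean over member sets of the mean
#'   score of their overlapping peaks.
#' @export
replicate_consistent_peaks <- function(peaksets, min_peak_len = 300L,
                                       mode = c("intersect", "overlap"),
                                       label = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(peaksets) >= 1L)
  if (length(peaksets) == 1L) {
    out <- peaksets[[1]]
    out <- out[IRanges::width(out) >= min_peak_len]
    S4Vectors::metadata(out)$label <- label
    return(out)
  }
  if (mode == "intersect") {
    out <- GenomicRanges::reduce(peaksets[[1]], ignore.strand = TRUE)
    for (ps in peaksets[-1]) {
      out <- GenomicRanges::intersect(out, GenomicRanges::reduce(ps),
                                      ignore.strand = TRUE)
    }
  } else {
    out <- GenomicRanges::reduce(
      do.call(c, unname(lapply(peaksets, GenomicRanges::granges))))
    keep <- rep(TRUE, length(out))
    for (ps in peaksets) {
      keep <- keep & GenomicRanges::countOverlaps(out, ps) > 0
    }
    out <- out[keep]
  }
  out <- out[IRanges::width(out) >= min_peak_len]
  if (length(out)) {
    score <- matrix(NA_real_, length(out), length(peaksets))
    for (j in seq_along(peaksets)) {
      ps <- peaksets[[j]]
      if (is.null(S4Vectors::mcols(ps)$score)) next
      hits <- GenomicRanges::findOverlaps(out, ps)
      if (length(hits)) {
        mean_sc <- tapply(S4Vectors::mcols(ps)$score[S4Vectors::subjectHits(hits)],
                          S4Vectors::queryHits(hits), mean)
        score[as.integer(names(mean_sc)), j] <- as.numeric(mean_sc)
      }
    }
    S4Vectors::mcols(out)$score <- rowMeans(score, na.rm = TRUE)
  }
  S4Vectors::metadata(out)$label <- label
  sort(out)
}

#' Write peaks as BED6
#'
#' Name column is the set label, score is `1000 * min(1, ratio / 10)` per
#' BED convention, strand is `"."`.
#'
#' @param peaks Peak `GRanges`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  label <- S4Vectors::metadata(peaks)$label
  if (is.null(label) || is.na(label)) label <- "peak"
  score <- S4Vectors::mcols(peaks)$score
  if (is.null(score)) score <- rep(0, length(peaks))
  write_bed(peaks, path,
            names = rep(label, length(peaks)),
            scores = 1000 * pmin(1, score / 10))
}
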