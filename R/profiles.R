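#' TaDa signal profile on GATC fragments
#'
#' A profile holds one score per GATC fragment plus scale and label tags.
#' Ratio profiles are tagged `"log2"` until averaged and backtransformed to
#' `"linear"`; accessibility profiles are linear RPM.
#'
#' @param frags GATC fragment `GRanges` (see [gatc_fragments()]).
#' @param score Numeric, one value per fragment, no missing values.
#' @param scale `"log2"` or `"linear"`.
#' @param construct Construct label (e.g. `"RGC_RBPJ"`).
#' @param replicate Replicate label, or `"averaged"`.
#' @return An object of class `tada_profile`.
#' @export
new_profile <- function(frags, score, scale = c("log2", "linear"),
                        construct = NA_character_,
                        replicate = NA_character_) {
  scale <- match.arg(scale)
  stopifnot(length(score) == length(frags), !anyNA(score))
  if (scale == "linear" && any(score < 0)) {
    stop("linear profile scores must be non-negative")
  }
  structure(list(frags = frags, score = as.numeric(score), scale = scale,
                 construct = construct, replicate = replicate),
            class = "tada_profile")
}

#' @export
print.tada_profile <- function(x, ...) {
  cat(sprintf("tada_profile: %s/%s | %d fragments | scale=%s\n",
              x$construct, x$replicate, length(x$score), x$scale))
  invisible(x)
}

check_same_frags <- function(profiles) {
  ref <- profiles[[1]]$frags
  for (p in profiles[-1]) {
    if (length(p$frags) != length(ref) ||
        !identical(IRanges::ranges(p$frags), IRanges::ranges(ref))) {
      stop("profiles are not on identical fragment sets")
    }
  }
  invisible(ref)
}

# Length-weighted projection of per-bin values onto target intervals:
# value(target) = sum over overlapping bins of (overlap bp * value) /
# (total overlap bp). With bins tiling the genome the denominator equals
# the target width.
project_weighted_mean <- function(bins, values, targets) {
  hits <- GenomicRanges::findOverlaps(targets, bins, ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(targets)[S4Vectors::queryHits(hits)],
    IRanges::ranges(bins)[S4Vectors::subjectHits(hits)]))
  num <- rowsum(ov * values[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
  den <- rowsum(ov, S4Vectors::queryHits(hits))
  out <- rep(NA_real_, length(targets))
  out[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
  out
}

#' Compute a log2 Dam-fusion/Dam-only ratio profile
#'
#' Per 300 bp bin, `r = log2((fusion + pc) / (control + pc))` on RPM
#' counts; each GATC fragment then receives the length-weighted mean of
#' `r` over the bins it overlaps. The pseudocount `pc` bounds ratios on
#' zero-count bins while preserving sign symmetry.
#'
#' @param fusion,control `binned_counts` in RPM units on the same fixed
#'   bin system.
#' @param frags GATC fragment `GRanges` on the same genome.
#' @param pseudocount Pseudocount in RPM added to both numerator and
#'   denominator (default 0.5).
#' @param construct,replicate Labels for the resulting profile.
#' @return A `tada_profile` tagged `"log2"`.
#' @export
compute_ratio <- function(fusion, control, frags, pseudocount = 0.5,
                          construct = NA_character_,
                          replicate = NA_character_) {
  stopifnot(inherits(fusion, "binned_counts"),
            inherits(control, "binned_counts"), pseudocount > 0)
  if (fusion$units != "rpm" || control$units != "rpm") {
    stop("ratio computation requires RPM-normalized counts")
  }
  if (length(fusion$counts) != length(control$counts) ||
      !identical(IRanges::ranges(fusion$bins),
                 IRanges::ranges(control$bins))) {
    stop("fusion and control are on different bin systems")
  }
  r <- log2((fusion$counts + pseudocount) / (control$counts + pseudocount))
  score <- project_weighted_mean(fusion$bins, r, frags)
  if (anyNA(score)) stop("fragments extend outside the binned genome")
  new_profile(frags, score, scale = "log2",
              construct = construct, replicate = replicate)
}

#' Quantile-normalize replicate profiles
#'
#' Classic quantile normalization across the profiles of one construct:
#' each profile's rank `i` value is replaced by the mean across profiles of
#' their i-th order statistics; ties receive the mean of the reference
#' values at the tied ranks. After normalization all profiles share the
#' same sorted values.
#'
#' @param profiles List of >= 2 `tada_profile`s on identical fragments and
#'   the same scale.
#' @return List of normalized profiles (same order, labels preserved).
#' @export
quantile_normalize_profiles <- function(profiles) {
  if (length(profiles) < 2L) {
    stop("quantile normalization needs at least two profiles")
  }
  check_same_frags(profiles)
  scales <- unique(vapply(profiles, `[[`, "", "scale"))
  if (length(scales) != 1L) stop("profiles mix scales")
  m <- vapply(profiles, `[[`, numeric(length(profiles[[1]]$score)), "score")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    p$score <- qn[, i]
    p
  })
}

#' Average replicate profiles and backtransform
#'
#' Fragment-wise mean of the log2 scores followed by `2^mean` ("unlog"),
#' i.e. a geometric mean on the linear scale. The resulting linear track
#' has midline 1.
#'
#' @param profiles List of >= 1 log2 `tada_profile`s on identical
#'   fragments.
#' @return A linear `tada_profile` labelled `"averaged"`.
#' @export
average_backtransform <- function(profiles) {
  if (length(profiles) < 1L) stop("no profiles to average")
  check_same_frags(profiles)
  if (any(vapply(profiles, `[[`, "", "scale") != "log2")) {
    stop("average_backtransform expects log2 profiles")
  }
  m <- vapply(profiles, `[[`, numeric(length(profiles[[1]]$score)), "score")
  if (is.null(dim(m))) m <- matrix(m, ncol = length(profiles))
  new_profile(profiles[[1]]$frags, 2^rowMeans(m), scale = "linear",
              construct = profiles[[1]]$construct, replicate = "averaged")
}

#' Dam-only chromatin accessibility profile
#'
#' Per-GATC-fragment RPM scores of Dam-only samples, used as a chromatin
#' accessibility readout (untethered Dam preferentially methylates
#' accessible chromatin). "Non-normalized" here means not ratio-normalized
#' against a fusion sample; RPM depth scaling is still applied. Replicates
#' of one cell type are quantile-normalized to each other (optional) and
#' averaged on the linear scale.
#'
#' @param controls List of Dam-only `binned_counts` (raw units) on the
#'   GATC fragment system, one per replicate.
#' @param quantile_norm Quantile-normalize replicates before averaging
#'   (default `TRUE`; only applies with >= 2 replicates).
#' @param cell_type Cell-type label.
#' @return A linear `tada_profile`.
#' @export
accessibility_profile <- function(controls, quantile_norm = TRUE,
                                  cell_type = NA_character_) {
  stopifnot(length(controls) >= 1L,
            all(vapply(controls, inherits, TRUE, "binned_counts")))
  frags <- controls[[1]]$bins
  profs <- lapply(controls, function(bc) {
    if (bc$units == "raw") bc <- rpm_normalize(bc)
    new_profile(frags, bc$counts, scale = "linear",
                construct = cell_type, replicate = bc$sample_id)
  })
  if (quantile_norm && length(profs) >= 2L) {
    profs <- quantile_normalize_profiles(profs)
  }
  m <- vapply(profs, `[[`, numeric(length(frags)), "score")
  if (is.null(dim(m))) m <- matrix(m, ncol = length(profs))
  new_profile(frags, rowMeans(m), scale = "linear",
              construct = cell_type, replicate = "averaged")
}

#' Genome-wide Pearson correlation between tracks
#'
#' Pairwise Pearson correlation of signal tracks over 500 bp bins or over
#' a supplied set of peak regions. Read tracks intended for this
#' comparison should be counted with 150 bp extension (see
#' [count_reads()]).
#'
#' @param tracks Named list of `binned_counts` or `tada_profile`s, all on
#'   the same bin system.
#' @param mode `"bins"` (use the tracks' own bins) or `"peak_regions"`
#'   (aggregate signal over `regions` first).
#' @param regions `GRanges` of regions when `mode = "peak_regions"`.
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a constant track are `NA`.
#' @export
genome_correlation <- function(tracks, mode = c("bins", "peak_regions"),
                               regions = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) >= 2L)
  values <- lapply(tracks, function(t) {
    if (inherits(t, "binned_counts")) t$counts else t$score
  })
  bins <- tracks[[1]]
  bins <- if (inherits(bins, "binned_counts")) bins$bins else bins$frags
  m <- do.call(cbind, values)
  if (mode == "peak_regions") {
    if (is.null(regions)) stop("peak_regions mode requires regions")
    m <- vapply(seq_len(ncol(m)), function(j) {
      project_weighted_mean(bins, m[, j], regions)
    }, numeric(length(regions)))
  }
  colnames(m) <- names(tracks)
  const <- apply(m, 2, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  if (any(const)) {
    warning("constant track(s): ", paste(names(tracks)[const], collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(cc) <- 1
  cc
}
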