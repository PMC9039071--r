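#' Merge peaks from multiple constructs into consensus peaks
#'
#' Overlapping or book-ended (gap 0) peaks from different Dam-fusion
#' constructs are merged into one consensus interval; the contributing
#' source sets are recorded per interval.
#'
#' @param peaksets Named list of peak `GRanges`.
#' @param gap Maximum gap merged across (default 0 = overlapping or
#'   book-ended only).
#' @return Sorted non-overlapping `GRanges` with metadata columns
#'   `consensus_id` and `contributors` (comma-separated source names).
#' @export
merge_consensus <- function(peaksets, gap = 0L) {
  stopifnot(length(peaksets) >= 1L)
  if (is.null(names(peaksets))) {
    names(peaksets) <- paste0("set", seq_along(peaksets))
  }
  all_peaks <- do.call(c, unname(lapply(peaksets, GenomicRanges::granges)))
  cons <- GenomicRanges::reduce(sort(all_peaks), min.gapwidth = gap + 1L)
  contrib <- matrix(FALSE, length(cons), length(peaksets))
  for (j in seq_along(peaksets)) {
    contrib[, j] <- GenomicRanges::countOverlaps(cons, peaksets[[j]]) > 0
  }
  S4Vectors::mcols(cons)$consensus_id <- sprintf("consensus_%05d",
                                                 seq_along(cons))
  S4Vectors::mcols(cons)$contributors <- apply(contrib, 1, function(x) {
    paste(names(peaksets)[x], collapse = ",")
  })
  cons
}

#' Consensus-peak binding intensity matrix
#'
#' Rows are consensus peaks, columns constructs. The raw entry is the
#' length-normalized signal: sum over fragments overlapping the peak of
#' (overlap bp x linear score) divided by the peak length, i.e. the mean
#' signal per bp. Columns are then z-scored (mean 0, sd 1).
#'
#' @param consensus Consensus peak `GRanges` ([merge_consensus()]).
#' @param profiles Named list of averaged linear `tada_profile`s, one per
#'   construct, sharing one fragment set.
#' @param zscore Convert columns to z-scores (default `TRUE`).
#' @return Numeric matrix (peaks x constructs) with rownames
#'   `consensus_id`; attribute `stage` is `"zscored"` or
#'   `"raw_lengthnorm"`.
#' @export
intensity_matrix <- function(consensus, profiles, zscore = TRUE) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  if (any(IRanges::width(consensus) < 1L)) stop("zero-length peak")
  check_same_frags(profiles)
  frags <- profiles[[1]]$frags
  m <- vapply(profiles, function(p) {
    project_weighted_mean(frags, p$score, consensus)
  }, numeric(length(consensus)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(profiles),
                                   dimnames = list(NULL, names(profiles)))
  rownames(m) <- S4Vectors::mcols(consensus)$consensus_id
  if (zscore) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance construct column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    attr(m, "stage") <- "zscored"
  } else {
    attr(m, "stage") <- "raw_lengthnorm"
  }
  m
}

# deterministic per-init seed stream below 2^31
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 10007 + 7 * seq_len(n)) %% 2147483647
}

#' k-means clustering of binding patterns
#'
#' Best-of-`n_init` k-means (Euclidean distance on z-scores, Lloyd
#' iterations capped at 300) under a deterministic seed stream; the
#' restart with the lowest within-cluster sum of squares wins. Clusters
#' are relabeled by descending size (ties by first occurrence).
#'
#' @param m Z-scored intensity matrix.
#' @param k Number of clusters (>= 2, <= number of rows).
#' @param n_init Number of random restarts (default 25).
#' @param seed Integer seed.
#' @return List of class `tada_clusters` with elements `k`, `cluster`
#'   (integer assignment per row), `centers`, `tot_withinss`, `seed`.
#' @export
kmeans_cluster <- function(m, k, n_init = 25L, seed = 1L) {
  stopifnot(k >= 2L)
  if (k > nrow(m)) stop("k exceeds the number of rows")
  seeds <- derive_seeds(seed, n_init)
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(seeds[i])
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = k, iter.max = 300L,
                                     nstart = 1L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart")
  sizes <- tabulate(best$cluster, k)
  relabel <- order(-sizes, seq_len(k))
  map <- integer(k)
  map[relabel] <- seq_len(k)
  structure(list(k = k,
                 cluster = map[best$cluster],
                 centers = best$centers[relabel, , drop = FALSE],
                 tot_withinss = best$tot.withinss,
                 seed = seed),
            class = "tada_clusters")
}

#' Select the number of clusters by mean silhouette width
#'
#' Runs [kmeans_cluster()] for each candidate k and computes the mean
#' silhouette width; returns the argmax (ties broken toward smaller k).
#'
#' @param m Z-scored intensity matrix with at least `2 * max(k_range)`
#'   rows.
#' @param k_range Candidate cluster numbers (default 2:12).
#' @param n_init Restarts per k.
#' @param seed Integer seed.
#' @return List with `k` (selected), `silhouette` (data frame of k and
#'   mean silhouette width) and `clustering` (the winning
#'   `tada_clusters`).
#' @export
select_k <- function(m, k_range = 2:12, n_init = 25L, seed = 1L) {
  stopifnot(nrow(m) >= 2L * max(k_range))
  d <- stats::dist(m)
  if (all(d == 0)) stop("degenerate matrix: all rows identical")
  fits <- list()
  sil <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    fit <- kmeans_cluster(m, k, n_init = n_init, seed = seed + k)
    fits[[i]] <<- fit
    mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)   # which.max takes the first maximum: smaller k
  list(k = k_range[best],
       silhouette = data.frame(k = k_range, mean_silhouette = sil),
       clustering = fits[[best]])
}

#' Adjusted Rand index
#'
#' Agreement between two partitions corrected for chance; 1 for identical
#' partitions, ~0 for random agreement.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Write consensus peaks with cluster labels as BED
#'
#' @param consensus Consensus `GRanges`.
#' @param clusters A `tada_clusters` result on the same rows.
#' @param path Output path.
#' @export
write_clustered_peaks_bed <- function(consensus, clusters, path) {
  write_bed(consensus, path,
            names = sprintf("cluster_%d", clusters$cluster))
}
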