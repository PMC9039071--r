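de_significant <- function(de, threshold, direction) {
  sig <- de$q < threshold
  switch(direction,
         up = sig & de$effect > 0,
         down = sig & de$effect < 0,
         both = sig,
         stop("direction must be 'up', 'down' or 'both'"))
}

#' Binomial enrichment of peak-gene associations among DE genes
#'
#' Since multiple peaks can be linked to the same gene, the number of
#' associations hitting significantly differentially expressed genes is
#' modelled as binomial: under the null each of the `n` associations
#' lands on a significant gene with probability `p0 = S / N`, where `S`
#' is the number of genes passing the significance threshold (in the
#' requested direction) and `N` the total number of genes in the DE
#' table. The reported enrichment p-value is the exact upper tail
#' `P(X >= k | n, p0)`. The mirror phrasing (a lower-tail test applied
#' to the count of non-significant associations,
#' `P(X <= n - k | n, 1 - p0)`) is available via `alternative =
#' "mirror"`; by tail complementarity the two are the same exact tail.
#'
#' @param assocs Data frame of peak-gene associations (`peak_id`,
#'   `gene_id`), e.g. from [nearest_tss()]. Associations whose gene is
#'   absent from the DE table are dropped with a warning.
#' @param de DE table: data frame with `gene_id`, `effect` (log
#'   fold-change, cell type A vs B) and `q` (adjusted significance in
#'   [0, 1]), one row per gene.
#' @param threshold Significance threshold `t` (0 < t < 1).
#' @param direction `"up"` (effect > 0), `"down"` or `"both"`.
#' @param alternative `"enrich"` (upper tail on k) or `"mirror"`.
#' @return List of class `assoc_counts`: `threshold`, `N`, `S`, `n`, `k`
#'   and `p` (raw p-value).
#' @export
binomial_association_test <- function(assocs, de, threshold,
                                      direction = c("up", "down", "both"),
                                      alternative = c("enrich", "mirror")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  stopifnot(threshold > 0, threshold < 1, nrow(de) > 0)
  if (anyDuplicated(de$gene_id)) stop("DE table must have one row per gene")
  known <- assocs$gene_id %in% de$gene_id
  if (!all(known)) {
    warning(sum(!known), " association(s) with genes absent from the DE ",
            "table dropped")
    assocs <- assocs[known, , drop = FALSE]
  }
  sig <- de_significant(de, threshold, direction)
  N <- nrow(de)
  S <- sum(sig)
  n <- nrow(assocs)
  k <- sum(assocs$gene_id %in% de$gene_id[sig])
  p0 <- S / N
  if (S == 0 && k > 0) stop("impossible counts: k > 0 with S = 0")
  p <- if (alternative == "enrich") {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(n - k, n, 1 - p0)
  }
  structure(list(threshold = threshold, N = N, S = S, n = n, k = k,
                 p = p, direction = direction),
            class = "assoc_counts")
}

#' Enrichment curve across DE significance thresholds and peak sets
#'
#' Repeats the binomial association test for every combination of peak
#' set and threshold, applies a Bonferroni correction whose family is all
#' tests performed in this call, and returns the per-point association
#' counts (`k` is the paper-style "peaksAtGenes" count of associations
#' with genes passing the threshold).
#'
#' @param assoc_sets Named list of association data frames, one per peak
#'   set (see [nearest_tss()]).
#' @param de DE table (see [binomial_association_test()]).
#' @param thresholds Decreasing significance grid; default decade steps
#'   `10^-(1:10)`.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Data frame with one row per (peak set, threshold):
#'   `peak_set`, `threshold`, `N`, `S`, `n`, `k`, `p_raw`, `p_adj`.
#' @export
enrichment_curve <- function(assoc_sets, de, thresholds = 10^-(1:10),
                             direction = "up") {
  stopifnot(length(thresholds) >= 1L, length(assoc_sets) >= 1L)
  if (is.null(names(assoc_sets))) {
    names(assoc_sets) <- paste0("peakset", seq_along(assoc_sets))
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- list()
  for (set in names(assoc_sets)) {
    for (t in thresholds) {
      ct <- suppressWarnings(binomial_association_test(
        assoc_sets[[set]], de, t, direction = direction))
      rows[[length(rows) + 1L]] <- data.frame(
        peak_set = set, threshold = t, N = ct$N, S = ct$S, n = ct$n,
        k = ct$k, p_raw = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Hypergeometric overlap of two gene sets
#'
#' Models the overlap of `set_a` (e.g. genes associated with a peak set)
#' and `set_b` (e.g. differentially expressed genes) within a gene
#' universe as hypergeometric and returns the upper-tail p-value
#' `P(X >= q_obs)` (the `phyper(..., lower.tail = FALSE)` convention
#' applied to `q_obs - 1`).
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of all genes.
#' @return List of class `hyper_overlap`: `N_u`, `K`, `n`, `q_obs`, `p`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  N_u <- length(universe)
  K <- length(set_a)
  n <- length(set_b)
  q_obs <- length(intersect(set_a, set_b))
  p <- stats::phyper(q_obs - 1, K, N_u - K, n, lower.tail = FALSE)
  structure(list(N_u = N_u, K = K, n = n, q_obs = q_obs, p = p),
            class = "hyper_overlap")
}

#' Sampled random-gene overlap null
#'
#' Draws `n_iter` random gene samples of the same size as the observed
#' peak-associated gene set (without replacement from the universe) and
#' records each sample's overlap with a reference set, to assess the
#' background overlap level empirically.
#'
#' @param peak_gene_count Number of genes to draw per iteration.
#' @param universe Character vector of all genes.
#' @param reference_set Character vector, the reference gene set.
#' @param n_iter Number of samplings (default 1000).
#' @param seed Integer seed.
#' @return List: `overlaps` (integer vector of length `n_iter`), `mean`,
#'   `sd`, `quantiles` (1%, 5%, 50%, 95%, 99%).
#' @export
sampled_overlap_null <- function(peak_gene_count, universe, reference_set,
                                 n_iter = 1000L, seed = 1L) {
  stopifnot(n_iter >= 1L, peak_gene_count <= length(universe))
  universe <- unique(universe)
  in_ref <- universe %in% reference_set
  set.seed(seed)
  overlaps <- vapply(seq_len(n_iter), function(i) {
    sum(in_ref[sample.int(length(universe), peak_gene_count)])
  }, integer(1))
  list(overlaps = overlaps, mean = mean(overlaps),
       sd = stats::sd(overlaps),
       quantiles = stats::quantile(overlaps, c(.01, .05, .5, .95, .99)))
}
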