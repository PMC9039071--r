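# Independent brute-force oracles used to validate the implementation.
# These are deliberately naive (loops, enumeration) and share no code
# with the package internals.

# naive all-positions substring scan (1-based starts)
oracle_scan <- function(seq, motif = "GATC") {
  n <- nchar(seq) - nchar(motif) + 1L
  if (n < 1L) return(integer(0))
  which(vapply(seq_len(n), function(i) {
    substr(seq, i, i + nchar(motif) - 1L) == motif
  }, logical(1)))
}

# classic quantile normalization: replace rank i by the mean of the i-th
# order statistics; ties get the mean of the reference values at their
# tied ranks
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[c(lo, hi)])
    }, numeric(1))
  }
  out
}

# length-weighted mean of bin values over a target interval, by looping
# over every base of the target (exact, O(width))
oracle_weighted_mean <- function(bin_starts, bin_ends, values, from, to) {
  per_base <- numeric(to - from + 1L)
  for (pos in from:to) {
    j <- which(bin_starts <= pos & bin_ends >= pos)
    per_base[pos - from + 1L] <- values[j[1L]]
  }
  mean(per_base)
}

# exact binomial upper tail by summation
oracle_binom_upper <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) stats::dbinom(x, n, p0), numeric(1)))
}

# hypergeometric upper tail by enumeration
oracle_hyper_upper <- function(q, N, K, n) {
  xs <- max(0, q):min(K, n)
  sum(vapply(xs, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# brute-force nearest TSS: all-pairs scan in 0-based half-open
# coordinates with lexicographic tie-break; distance 0 if the TSS falls
# inside [start0, end0), else distance to the nearer peak edge
oracle_nearest <- function(start0, end0, tss0, gene_ids) {
  d <- vapply(tss0, function(t) {
    if (t >= start0 && t < end0) 0
    else if (t < start0) start0 - t
    else t - end0
  }, numeric(1))
  cand <- which(d == min(d))
  cand[order(gene_ids[cand])][1L]
}

# interval set intersection / union on integer base sets
oracle_intersect_bases <- function(a_start, a_end, b_start, b_end) {
  a <- unlist(mapply(seq, a_start, a_end, SIMPLIFY = FALSE))
  b <- unlist(mapply(seq, b_start, b_end, SIMPLIFY = FALSE))
  sort(intersect(a, b))
}
oracle_union_bases <- function(a_start, a_end, b_start, b_end) {
  a <- unlist(mapply(seq, a_start, a_end, SIMPLIFY = FALSE))
  b <- unlist(mapply(seq, b_start, b_end, SIMPLIFY = FALSE))
  sort(union(a, b))
}

# GRanges to sorted covered-base vector
covered_bases <- function(gr) {
  gr <- GenomicRanges::reduce(gr)
  if (!length(gr)) return(integer(0))
  sort(unlist(mapply(seq, BiocGenerics::start(gr), BiocGenerics::end(gr),
                     SIMPLIFY = FALSE)))
}
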