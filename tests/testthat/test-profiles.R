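test_that("compute_ratio matches the closed form within one bin", {
  # fusion 4 RPM, control 1 RPM, pseudocount 1: log2(5/2)
  bins <- fixed_bins(c(chr1 = 300L), 300L)
  fus <- new_binned_counts(bins, 4, "rpm", library_size = 1e6, "f")
  ctl <- new_binned_counts(bins, 1, "rpm", library_size = 1e6, "c")
  frags <- gatc_fragments(list(chr1 = integer(0)), c(chr1 = 300L))
  pr <- compute_ratio(fus, ctl, frags, pseudocount = 1)
  expect_equal(pr$score, log2(5 / 2), tolerance = 1e-12)
  expect_equal(pr$scale, "log2")
})

test_that("equal fusion and control give an all-zero log2 profile", {
  bins <- fixed_bins(c(chr1 = 1200L), 300L)
  x <- c(3, 8, 0, 5)
  fus <- new_binned_counts(bins, x, "rpm", 1e6, "f")
  ctl <- new_binned_counts(bins, x, "rpm", 1e6, "c")
  frags <- gatc_fragments(list(chr1 = c(101L, 501L, 901L)), c(chr1 = 1200L))
  expect_equal(compute_ratio(fus, ctl, frags)$score, rep(0, 4))
})

test_that("fragments spanning bins get length-weighted mean ratios", {
  # fragment overlapping bin 1 by 100 bp (r = 1) and bin 2 by 300 bp
  # (r = 3): (100*1 + 300*3) / 400 = 2.5
  bins <- fixed_bins(c(chr1 = 600L), 300L)
  fus <- new_binned_counts(bins, c(3, 15), "rpm", 1e6, "f")
  ctl <- new_binned_counts(bins, c(1, 1), "rpm", 1e6, "c")
  frags <- gatc_fragments(list(chr1 = 201L), c(chr1 = 600L))
  pr <- compute_ratio(fus, ctl, frags, pseudocount = 1)
  expect_equal(pr$score[2], 2.5, tolerance = 1e-12)
  expect_error(compute_ratio(fus, new_binned_counts(
    fixed_bins(c(chr1 = 900L), 300L), c(1, 1, 1), "rpm", 1e6, "c"),
    frags), "bin systems")
})

test_that("quantile normalization matches the hand-computed reference", {
  p1 <- profile_on_frags(c(1, 2, 3))
  p2 <- profile_on_frags(c(2, 4, 6))
  qn <- quantile_normalize_profiles(list(p1, p2))
  expect_equal(qn[[1]]$score, c(1.5, 3.0, 4.5))
  expect_equal(qn[[2]]$score, c(1.5, 3.0, 4.5))
  # identical profiles are a fixed point
  qn2 <- quantile_normalize_profiles(list(p1, p1))
  expect_equal(qn2[[1]]$score, p1$score)
  expect_equal(qn2[[2]]$score, p1$score)
  # all-tied profiles collapse to the common mean
  qn3 <- quantile_normalize_profiles(list(profile_on_frags(c(2, 2, 2)),
                                          profile_on_frags(c(4, 4, 4))))
  expect_equal(qn3[[1]]$score, rep(3, 3))
  expect_equal(qn3[[2]]$score, rep(3, 3))
  expect_error(quantile_normalize_profiles(list(p1)), "at least two")
})

test_that("quantile normalization agrees with the brute-force oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    k <- sample(2:5, 1)
    m <- matrix(sample(1:8, n * k, replace = TRUE) / 2, n, k)  # many ties
    profs <- lapply(seq_len(k), function(j) profile_on_frags(m[, j]))
    qn <- quantile_normalize_profiles(profs)
    got <- vapply(qn, `[[`, numeric(n), "score")
    expect_equal(got, oracle_quantile_normalize(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # on tie-free profiles the outputs are permutations of a common
  # multiset (ties instead receive averaged reference values)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    qn <- quantile_normalize_profiles(
      lapply(seq_len(k), function(j) profile_on_frags(m[, j])))
    got <- vapply(qn, `[[`, numeric(n), "score")
    for (j in seq_len(k)) {
      expect_equal(sort(got[, j]), sort(got[, 1]), tolerance = 1e-12)
    }
  }
})

test_that("averaging is on log2 scale before backtransform", {
  p1 <- profile_on_frags(c(1, 2))
  p2 <- profile_on_frags(c(-1, 2))
  av <- average_backtransform(list(p1, p2))
  expect_equal(av$score, c(1, 4))
  expect_equal(av$scale, "linear")
  expect_equal(av$replicate, "averaged")
  expect_equal(average_backtransform(list(profile_on_frags(2)))$score, 4)
  expect_equal(average_backtransform(list(profile_on_frags(1),
                                          profile_on_frags(1),
                                          profile_on_frags(4)))$score, 4)
})

test_that("duplicate replicates pass through qn + backtransform as 2^x", {
  set.seed(9)
  x <- rnorm(50)
  p <- profile_on_frags(x)
  av <- average_backtransform(quantile_normalize_profiles(list(p, p)))
  expect_equal(av$score, 2^x, tolerance = 1e-12)
})

test_that("ratio profiles are invariant to joint library rescaling", {
  set.seed(13)
  raw_f <- rpois(10, 40); raw_c <- rpois(10, 40)
  frags <- gatc_fragments(list(chr1 = c(501L, 1501L, 2201L)),
                          c(chr1 = 3000L))
  mk <- function(x, f) counts_on_bins(x * f, chrom_len = 3000L,
                                      library_size = sum(x) * f)
  r1 <- compute_ratio(rpm_normalize(mk(raw_f, 1)),
                      rpm_normalize(mk(raw_c, 1)), frags)
  r5 <- compute_ratio(rpm_normalize(mk(raw_f, 5)),
                      rpm_normalize(mk(raw_c, 5)), frags)
  expect_equal(r1$score, r5$score, tolerance = 1e-12)
})

test_that("accessibility profiles are flat for uniform reads and track depth", {
  set.seed(21)
  len <- 60000L
  g <- Biostrings::DNAStringSet(stats::setNames(random_dna(len), "chr1"))
  frags <- gatc_fragments(scan_gatc_sites(g), genome_seqlengths(g))
  # ~30+ reads per fragment on average
  n_reads <- 40L * length(frags)
  rd <- reads_at(sample(len, n_reads, replace = TRUE))
  ap <- accessibility_profile(list(count_reads(rd, frags)), cell_type = "RGC")
  per_bp <- ap$score / IRanges::width(frags)
  # near-constant at adequate depth: restrict to fragments expecting
  # >= 30 reads (shorter fragments are legitimately noisier)
  deep <- IRanges::width(frags) >= 30 * len / n_reads
  expect_lt(stats::sd(per_bp[deep]) / mean(per_bp[deep]), 0.2)
  # zero reads: all-zero profile
  empty <- count_reads(reads_at(integer(0)), frags)
  empty$library_size <- 1
  expect_equal(accessibility_profile(list(empty))$score,
               rep(0, length(frags)))
})

test_that("planted accessible regions stand out in Dam-only profiles", {
  sim <- small_sim()
  truth <- sim$truth
  ctl <- lapply(1:3, function(r) {
    count_reads(sim$reads[[sprintf("Dam_IPC_rep%d", r)]], truth$frags)
  })
  ap <- accessibility_profile(ctl, cell_type = "IPC")
  arch <- S4Vectors::mcols(truth$sites)$archetype
  open_sites <- truth$sites[arch == 6]
  reduced_sites <- truth$sites[arch == 8]
  m_open <- mean(tadakit:::project_weighted_mean(ap$frags, ap$score, open_sites))
  m_red <- mean(tadakit:::project_weighted_mean(ap$frags, ap$score, reduced_sites))
  expect_gt(m_open / m_red, 2)
})

test_that("genome correlation has unit diagonal and flags constant tracks", {
  set.seed(4)
  x <- rnorm(1000)
  p1 <- profile_on_frags(x)
  p2 <- profile_on_frags(-x)
  cc <- genome_correlation(list(a = p1, b = p2))
  expect_equal(diag(cc), c(a = 1, b = 1))
  expect_equal(cc["a", "b"], -1)
  # independent Poisson tracks decorrelate
  t1 <- counts_on_bins(rpois(10000, 20))
  t2 <- counts_on_bins(rpois(10000, 20))
  cc2 <- genome_correlation(list(x = t1, y = t2))
  expect_lt(abs(cc2["x", "y"]), 0.05)
  expect_warning(
    cc3 <- genome_correlation(list(x = p1, k = profile_on_frags(rep(0, 1000)))),
    "constant")
  expect_true(is.na(cc3["x", "k"]))
})
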