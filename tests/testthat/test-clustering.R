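test_that("consensus merging unions overlapping and book-ended peaks", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
  cons <- merge_consensus(list(x = a, y = b))
  expect_length(cons, 1L)
  expect_equal(BiocGenerics::start(cons), 1)
  expect_equal(BiocGenerics::end(cons), 150)
  expect_equal(S4Vectors::mcols(cons)$contributors, "x,y")
  # book-ended intervals merge at gap 0
  d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  cons2 <- merge_consensus(list(x = a, y = d))
  expect_length(cons2, 1L)
  expect_equal(IRanges::width(cons2), 200)
  # disjoint inputs concatenate, sorted
  e <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600))
  cons3 <- merge_consensus(list(x = e, y = a))
  expect_equal(BiocGenerics::start(cons3), c(1, 500))
  # every input peak overlaps exactly one consensus interval
  cons4 <- merge_consensus(list(x = c(a, e), y = b))
  for (pk in list(a, b, e)) {
    expect_equal(GenomicRanges::countOverlaps(pk, cons4), 1L)
  }
})

test_that("consensus union agrees with a base-level oracle", {
  set.seed(41)
  for (i in 1:10) {
    st1 <- sort(sample(1:500, 5)) * 10
    st2 <- sort(sample(1:500, 5)) * 10
    a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st1, st1 + 250))
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st2, st2 + 250))
    cons <- merge_consensus(list(a = a, b = b))
    expect_identical(covered_bases(cons),
                     oracle_union_bases(st1, st1 + 250, st2, st2 + 250))
  }
})

test_that("intensity matrix is the per-bp mean over the peak", {
  # constant profile: raw entry equals the constant
  prof <- profile_on_frags(rep(2, 10), frag_width = 100L, scale = "linear")
  cons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500))
  S4Vectors::mcols(cons)$consensus_id <- "consensus_00001"
  m <- intensity_matrix(cons, list(A = prof), zscore = FALSE)
  expect_equal(unname(m[1, "A"]), 2)
  # 400 bp peak covering 100 bp at score 1 and 300 bp at score 3: 2.5
  prof2 <- new_profile(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), c(100, 600))),
    c(1, 3), scale = "linear")
  cons2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400))
  S4Vectors::mcols(cons2)$consensus_id <- "consensus_00001"
  m2 <- intensity_matrix(cons2, list(A = prof2), zscore = FALSE)
  expect_equal(unname(m2[1, "A"]), 2.5)
})

test_that("weighted peak intensities match the per-base oracle", {
  set.seed(42)
  for (i in 1:10) {
    k <- 30L
    bounds <- sort(sample(2:999, k - 1))
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, 1000L)
    vals <- runif(k, 0, 5)
    prof <- new_profile(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, ends)), vals, scale = "linear")
    from <- sample(1:500, 1); to <- from + sample(50:400, 1)
    cons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(from, to))
    S4Vectors::mcols(cons)$consensus_id <- "c1"
    m <- intensity_matrix(cons, list(A = prof), zscore = FALSE)
    expect_equal(unname(m[1, 1]),
                 oracle_weighted_mean(starts, ends, vals, from, to),
                 tolerance = 1e-10)
  }
})

test_that("z-scored columns have zero mean, unit sd, and are idempotent", {
  set.seed(43)
  prof_list <- lapply(1:3, function(j) {
    profile_on_frags(runif(50, 0, 4), frag_width = 200L, scale = "linear")
  })
  names(prof_list) <- c("A", "B", "C")
  st <- seq(1, 9801, by = 400)
  cons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 199))
  S4Vectors::mcols(cons)$consensus_id <- sprintf("c%02d", seq_along(st))
  m <- intensity_matrix(cons, prof_list)
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-9))
  expect_equal(unname(scale(m)[, ]), unname(m[, ]), tolerance = 1e-12)
  # zero-variance column errors
  flat <- list(A = profile_on_frags(rep(1, 50), frag_width = 200L,
                                    scale = "linear"))
  expect_error(intensity_matrix(cons, flat), "zero-variance")
})

test_that("two well-separated blobs select k = 2 with high silhouette", {
  set.seed(44)
  m <- rbind(matrix(rnorm(100 * 2, 0, 1), ncol = 2),
             matrix(rnorm(100 * 2, 10, 1), ncol = 2))
  sel <- select_k(m, k_range = 2:8, n_init = 10, seed = 1)
  expect_equal(sel$k, 2L)
  expect_gt(sel$silhouette$mean_silhouette[sel$silhouette$k == 2], 0.8)
})

test_that("eight noisy archetype rows recover k = 8 and the partition", {
  set.seed(45)
  proto <- matrix(rnorm(8 * 4, 0, 2), nrow = 8)
  labels <- rep(1:8, each = 25)
  m <- proto[labels, ] + matrix(rnorm(200 * 4, 0, 0.1), ncol = 4)
  sel <- select_k(m, k_range = 2:12, n_init = 10, seed = 5)
  expect_equal(sel$k, 8L)
  # silhouette peaks at the true k
  expect_equal(sel$silhouette$k[which.max(sel$silhouette$mean_silhouette)], 8L)
  expect_gte(adjusted_rand_index(sel$clustering$cluster, labels), 0.9)
  # degenerate matrix errors
  expect_error(select_k(matrix(1, 30, 3), k_range = 2:3), "identical")
})

test_that("k-means is deterministic, exact on noiseless data, relabeled by size", {
  set.seed(46)
  proto <- matrix(c(0, 0, 5, 5, 10, 0), nrow = 3, byrow = TRUE)
  m <- proto[c(rep(1, 6), rep(2, 3), rep(3, 2)), ]
  cl <- kmeans_cluster(m, 3, n_init = 5, seed = 9)
  expect_equal(cl$tot_withinss, 0)
  expect_equal(cl$cluster, c(rep(1, 6), rep(2, 3), rep(3, 2)))
  cl2 <- kmeans_cluster(m, 3, n_init = 5, seed = 9)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(kmeans_cluster(m, 50, seed = 1), "exceeds")
})

test_that("best-of-n_init WCSS is monotone in restarts on one seed stream", {
  # derive_seeds(seed, n) is a prefix-stable stream, so more restarts can
  # only improve the best within-cluster sum of squares
  set.seed(47)
  m <- matrix(rnorm(120 * 3), ncol = 3)
  wcss <- vapply(c(1, 5, 20), function(ni) {
    kmeans_cluster(m, 4, n_init = ni, seed = 3)$tot_withinss
  }, numeric(1))
  expect_true(all(diff(wcss) <= 1e-9))
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(48)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
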