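mk_tss <- function(gene_id, chrom, tss, biotype = "protein_coding") {
  data.frame(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
             tss = tss, strand = "+", biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("nearest_tss picks the closest protein-coding TSS", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  # TSS inside the peak: distance 0
  a <- nearest_tss(pk, mk_tss("g1", "chr1", 150))
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance, 0)
  # TSSs at 0-based 250 and 400: the closer wins at distance 50
  a2 <- nearest_tss(pk, mk_tss(c("g1", "g2"), "chr1", c(250, 400)))
  expect_equal(a2$gene_id, "g1")
  expect_equal(a2$distance, 50)
  # non-coding genes are ignored
  a3 <- nearest_tss(pk, mk_tss(c("nc", "far"), "chr1", c(210, 400),
                               biotype = c("lincRNA", "protein_coding")))
  expect_equal(a3$gene_id, "far")
  # upstream TSS gets a negative sign
  a4 <- nearest_tss(pk, mk_tss("g1", "chr1", 10))
  expect_lt(a4$distance, 0)
})

test_that("equidistant TSSs resolve to the lexicographically smaller gene", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  # 0-based TSS 50 and 250 are both 50 bp from the peak edges
  a <- nearest_tss(pk, mk_tss(c("gB", "gA"), "chr1", c(50, 250)))
  expect_equal(a$gene_id, "gA")
})

test_that("peaks on unannotated chromosomes are flagged missing", {
  pk <- GenomicRanges::GRanges(c("chr1", "chrM"),
                               IRanges::IRanges(c(101, 11), c(200, 60)))
  expect_warning(a <- nearest_tss(pk, mk_tss("g1", "chr1", 150)), "without")
  expect_equal(a$gene_id, c("g1", NA))
})

test_that("nearest_tss agrees with a brute-force all-pairs scan", {
  set.seed(51)
  for (i in 1:200) {
    n_tss <- sample(2:8, 1)
    tss0 <- sample(0:2999, n_tss)
    ids <- sample(sprintf("g%02d", 1:20), n_tss)
    from <- sample(1:2500, 1)
    to <- from + sample(10:400, 1)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(from, to))
    got <- nearest_tss(pk, mk_tss(ids, "chr1", tss0))
    want <- oracle_nearest(from - 1L, to, tss0, ids)
    expect_equal(got$gene_id, ids[want])
  }
})

mk_models <- function() {
  data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-", "-"),
    feature = c("five_prime_utr", "exon", "exon", "exon", "three_prime_utr"),
    start = c(10000L, 10000L, 12000L, 30000L, 30000L),
    end = c(10200L, 10500L, 13000L, 31000L, 30100L),
    stringsAsFactors = FALSE)
}

test_that("build_features derives strand-aware upstream windows", {
  feats <- build_features(mk_models(), c(chr1 = 50000L))
  # + strand gene TSS at 10000: upstream [5000, 10000)
  up <- feats$upstream5kb
  expect_true(any(BiocGenerics::start(up) == 5001 &
                  BiocGenerics::end(up) == 10000))
  # - strand gene TSS at 31000: upstream [31000, 36000)
  expect_true(any(BiocGenerics::start(up) == 31001 &
                  BiocGenerics::end(up) == 36000))
  # introns are the gene body minus exons
  expect_equal(BiocGenerics::start(feats$intron), 10501)
  expect_equal(BiocGenerics::end(feats$intron), 12000)
  # intergenic excludes bodies and upstream regions
  expect_equal(sum(IRanges::width(GenomicRanges::intersect(
    feats$intergenic, feats$upstream5kb))), 0)
  expect_error(build_features(transform(mk_models(), end = 60000L),
                              c(chr1 = 50000L)), "bounds")
})

test_that("overlapping exons collapse into one interval", {
  gm <- data.frame(gene_id = "g", transcript_id = c("t1", "t2"),
                   chrom = "chr1", strand = "+", feature = "exon",
                   start = c(1000L, 1400L), end = c(1500L, 2000L),
                   stringsAsFactors = FALSE)
  feats <- build_features(gm, c(chr1 = 10000L))
  expect_length(feats$exon, 1L)
  expect_equal(IRanges::width(feats$exon), 1000L)
})

test_that("feature overlap enrichment handles the trivial geometries", {
  seqlen <- c(chr1 = 100000L)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1001, 5001),
                                                        c(2000, 6000)))
  # category exactly covering the peaks: observed 100%
  feats <- list(hit = pk)
  res <- feature_overlap_enrichment(pk, feats, seqlen, n_samples = 200,
                                    seed = 2)
  expect_equal(res$observed_percent, 100)
  # category = whole genome: every placement overlaps fully
  whole <- list(all = GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(1, 100000)))
  res2 <- feature_overlap_enrichment(pk, whole, seqlen, n_samples = 200,
                                     seed = 2)
  expect_equal(res2$observed_percent, 100)
  expect_equal(res2$expected_percent, 100)
  expect_equal(res2$fold, 1)
  expect_equal(res2$p_enrich, 1)
  expect_error(feature_overlap_enrichment(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e5)),
    feats, seqlen, n_samples = 100, seed = 1), "longer")
})

test_that("peaks concentrated in a category are detected as enriched", {
  set.seed(52)
  seqlen <- c(chr1 = 200000L)
  # category: 10 exon islands of 2 kb
  ex_start <- seq(10000, 190000, by = 20000)
  exon <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(ex_start, ex_start + 1999))
  # peaks planted inside exons
  pk <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(ex_start + 500,
                                                ex_start + 999))
  res <- feature_overlap_enrichment(pk, list(exon = exon), seqlen,
                                    n_samples = 1000, seed = 3)
  expect_lte(res$p_enrich, 0.002)
  expect_gt(res$fold, 2)
  expect_gt(res$p_enrich, 0)   # add-one rule: never exactly 0
})

test_that("sampled overlap percentages are calibrated against geometry", {
  # a category covering 30% of the chromosome should attract ~30% overlap
  set.seed(53)
  seqlen <- c(chr1 = 100000L)
  cat30 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 30000))
  pk <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(50000, 59000, by = 1000),
                                                width = 500))
  res <- feature_overlap_enrichment(pk, list(c30 = cat30), seqlen,
                                    n_samples = 2000, seed = 4)
  expect_equal(res$expected_percent, 30, tolerance = 0.05)
})
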