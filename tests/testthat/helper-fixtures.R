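# Shared fixture builders (everything generated in code; no binary data)

write_tmp_fasta <- function(seqs, wrap = 60L) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  close(con)
  path
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small read GRanges at given 1-based positions
reads_at <- function(pos, chrom = "chr1", strand = "+", sample_id = "s") {
  gr <- GenomicRanges::GRanges(rep(chrom, length(pos)),
                               IRanges::IRanges(pos, width = 1L),
                               strand = rep(strand, length(pos)))
  S4Vectors::metadata(gr)$sample_id <- sample_id
  gr
}

# binned counts straight from a numeric vector on 300 bp bins
counts_on_bins <- function(counts, width = 300L, chrom_len = NULL,
                           library_size = sum(counts), units = "raw",
                           sample_id = "s") {
  if (is.null(chrom_len)) chrom_len <- length(counts) * width
  bins <- fixed_bins(c(chr1 = chrom_len), width)
  new_binned_counts(bins, counts, units = units,
                    library_size = library_size, sample_id = sample_id)
}

# profile on synthetic fragments tiling one chromosome
profile_on_frags <- function(score, frag_width = 100L, scale = "log2",
                             construct = "c", replicate = "r") {
  len <- length(score) * frag_width
  starts <- seq(1L, len, by = frag_width)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(starts,
                                                starts + frag_width - 1L))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = len)
  new_profile(gr, score, scale = scale, construct = construct,
              replicate = replicate)
}

# small simulation shared by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chroms = 1L, chrom_length = 3e5, n_sites = 40L,
                        n_genes = 80L, depth = 1e5, seed = 11L)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})
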