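#' Load a genome from FASTA
#'
#' Reads a (multi-record, possibly line-wrapped) FASTA file and returns the
#' sequences uppercased. Record names are taken up to the first whitespace.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record, in file
#'   order. Sequences are uppercased; `N` is allowed.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  genome <- Biostrings::readDNAStringSet(fasta_path)
  if (length(genome) == 0L) {
    stop("empty FASTA: ", fasta_path)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate record names in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  }
  genome <- Biostrings::DNAStringSet(toupper(genome))
  bad <- !grepl("^[ACGTN]*$", as.character(genome))
  if (any(bad)) {
    stop("sequence alphabet outside {A,C,G,T,N} in record(s): ",
         paste(names(genome)[bad], collapse = ", "))
  }
  genome
}

#' Chromosome lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] as returned by [load_genome()].
#' @return Named integer vector of chromosome lengths.
#' @export
genome_seqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Locate GATC motifs
#'
#' Scans each chromosome for occurrences of the (non-self-overlapping) GATC
#' motif. Motif instances containing `N` are not reported; runs of `N` are
#' treated as ordinary non-motif sequence.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param motif Restriction motif; only `"GATC"` is routinely used.
#' @return Named list (one element per chromosome) of sorted 1-based motif
#'   start positions (integer, possibly empty).
#' @export
scan_gatc_sites <- function(genome, motif = "GATC") {
  stopifnot(nchar(motif) >= 1L)
  lapply(stats::setNames(seq_along(genome), names(genome)), function(i) {
    m <- Biostrings::matchPattern(motif, genome[[i]], fixed = TRUE)
    sort(BiocGenerics::start(m))
  })
}

#' Build GATC fragments
#'
#' Tiles each chromosome into fragments delimited by GATC motif starts: a
#' fragment runs from one motif start to the next (the motif belongs to the
#' fragment it begins, reflecting that DamID amplicons start at the cut
#' GATC). The first fragment starts at the chromosome start, the last ends
#' at the chromosome end, so fragments tile the chromosome without gaps.
#'
#' @param sites Named list of sorted 1-based motif start positions per
#'   chromosome, as from [scan_gatc_sites()].
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return A [GenomicRanges::GRanges] of fragments with metadata column
#'   `fragment_id` (`<chrom>_<index>`).
#' @export
gatc_fragments <- function(sites, seqlengths) {
  stopifnot(all(names(sites) %in% names(seqlengths)))
  pieces <- lapply(names(sites), function(chrom) {
    len <- seqlengths[[chrom]]
    pos <- sites[[chrom]]
    if (length(pos) && (max(pos) > len || min(pos) < 1L)) {
      stop("GATC site outside chromosome bounds on ", chrom)
    }
    bounds <- sort(unique(c(1L, pos, len + 1L)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  })
  frags <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlengths(frags) <-
    seqlengths[GenomeInfoDb::seqlevels(frags)]
  S4Vectors::mcols(frags)$fragment_id <- paste0(
    GenomeInfoDb::seqnames(frags), "_",
    unlist(lapply(pieces, function(p) seq_along(p)), use.names = FALSE))
  S4Vectors::metadata(frags)$binning <- "gatc"
  frags
}

#' Tile chromosomes into fixed-width bins
#'
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param width Bin width in bp (300 for ratio computation, 500 for
#'   genome-wide correlation). The last bin per chromosome is truncated.
#' @return A [GenomicRanges::GRanges] of bins.
#' @export
fixed_bins <- function(seqlengths, width = 300L) {
  if (length(width) != 1L || is.na(width) || width < 1L) {
    stop("bin width must be a positive integer")
  }
  width <- as.integer(width)
  pieces <- lapply(names(seqlengths), function(chrom) {
    len <- seqlengths[[chrom]]
    starts <- seq.int(1L, len, by = width)
    ends <- pmin(starts + width - 1L, len)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  })
  bins <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlengths(bins) <- seqlengths[GenomeInfoDb::seqlevels(bins)]
  S4Vectors::metadata(bins)$binning <- "fixed"
  S4Vectors::metadata(bins)$width <- width
  bins
}
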