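#' Binned read counts
#'
#' Container pairing a bin system with per-bin counts.
#'
#' @param bins `GRanges` bin system ([fixed_bins()] or [gatc_fragments()]).
#' @param counts Numeric vector, one value per bin.
#' @param units `"raw"` (integer reads) or `"rpm"`.
#' @param library_size Total mapped reads of the sample.
#' @param sample_id Sample label.
#' @return An object of class `binned_counts`.
#' @export
new_binned_counts <- function(bins, counts, units = c("raw", "rpm"),
                              library_size, sample_id = NA_character_) {
  units <- match.arg(units)
  stopifnot(length(counts) == length(bins), all(counts >= 0))
  structure(list(bins = bins, counts = as.numeric(counts), units = units,
                 library_size = library_size, sample_id = sample_id),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts: %s | %d bins | units=%s | library=%g\n",
              x$sample_id, length(x$counts), x$units, x$library_size))
  invisible(x)
}

#' Read aligned read 5' positions from BED
#'
#' Expects 6-column BED of single-base 5' positions (or intervals whose
#' start is the 5' position on the plus strand).
#'
#' @param path BED path.
#' @param sample_id Sample label (defaults to file name).
#' @return Width-1 `GRanges` with strand; one range per read.
#' @export
read_reads_bed <- function(path, sample_id = NULL) {
  gr <- read_bed(path)
  gr <- GenomicRanges::resize(gr, width = 1L, fix = "start",
                              ignore.strand = TRUE)
  S4Vectors::metadata(gr)$sample_id <-
    if (is.null(sample_id)) basename(path) else sample_id
  gr
}

#' Count reads into bins
#'
#' With `extension = 0`, each read contributes 1 to the bin containing its
#' 5' start. With `extension > 0`, each read is extended to
#' `[start, start + extension)` and contributes its per-bin overlap
#' fraction (overlap bp / extension) to every bin it overlaps.
#'
#' @param reads Width-1 `GRanges` of read 5' positions.
#' @param bins Bin `GRanges` ([fixed_bins()] or [gatc_fragments()]).
#' @param extension Extension length in bp (0 disables).
#' @param sample_id Sample label (defaults to the reads' metadata).
#' @return A `binned_counts` in raw units. With `extension = 0` the counts
#'   sum to the library size (conservation).
#' @export
count_reads <- function(reads, bins, extension = 0L, sample_id = NULL) {
  stopifnot(extension >= 0)
  miss <- setdiff(unique(as.character(GenomeInfoDb::seqnames(reads))),
                  unique(as.character(GenomeInfoDb::seqnames(bins))))
  if (length(miss)) {
    stop("read chromosome(s) absent from bin system: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(sample_id)) {
    sample_id <- S4Vectors::metadata(reads)$sample_id
    if (is.null(sample_id)) sample_id <- NA_character_
  }
  if (extension == 0) {
    counts <- GenomicRanges::countOverlaps(bins, reads,
                                           ignore.strand = TRUE)
  } else {
    ext <- GenomicRanges::resize(reads, width = as.integer(extension),
                                 fix = "start", ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(ext, bins, ignore.strand = TRUE)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(ext)[S4Vectors::queryHits(hits)],
      IRanges::ranges(bins)[S4Vectors::subjectHits(hits)]))
    counts <- numeric(length(bins))
    acc <- rowsum(ov / extension, S4Vectors::subjectHits(hits))
    counts[as.integer(rownames(acc))] <- acc[, 1L]
  }
  new_binned_counts(bins, counts, units = "raw",
                    library_size = length(reads), sample_id = sample_id)
}

#' RPM-normalize binned counts
#'
#' Reads-per-million scaling: each count is multiplied by `1e6 / library
#' size`. Refuses to renormalize counts that are already RPM.
#'
#' @param counts A `binned_counts` in raw units.
#' @return A `binned_counts` in RPM units.
#' @export
rpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  if (counts$units != "raw") {
    stop("counts are already RPM-normalized")
  }
  if (is.na(counts$library_size) || counts$library_size <= 0) {
    stop("library size must be positive for RPM normalization")
  }
  out <- counts
  out$counts <- counts$counts * 1e6 / counts$library_size
  out$units <- "rpm"
  out
}
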