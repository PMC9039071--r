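# Plain-text genomic I/O. On disk all interval formats are 0-based
# half-open (standard BED/bedGraph); in memory everything is 1-based
# closed GRanges. Numeric scores are serialized with %.17g so that
# write -> read -> write round-trips byte-identically.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # sprintf keeps a stable shortest-ish form; integers print without '.'
  ifelse(is.finite(x) & x == round(x) & abs(x) < 1e15,
         sprintf("%d", as.integer64_safe(x)), out)
}

as.integer64_safe <- function(x) {
  # values here are far below 2^31 in practice (coordinates, counts)
  as.integer(round(x))
}

#' Write intervals as BED
#'
#' Writes BED3/BED6 (0-based half-open). With `scores`, scores go to column
#' 5 capped to `[0, 1000]` per BED convention unless `raw_scores = TRUE`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param names Optional name column (default `.` or `mcols(gr)$name`).
#' @param scores Optional numeric score column.
#' @param raw_scores Keep scores as-is instead of BED's 0-1000 integers.
#' @export
write_bed <- function(gr, path, names = NULL, scores = NULL,
                      raw_scores = FALSE) {
  n <- length(gr)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (is.null(names)) {
    names <- if (!is.null(S4Vectors::mcols(gr)$name)) {
      as.character(S4Vectors::mcols(gr)$name)
    } else {
      rep(".", n)
    }
  }
  lines <- if (is.null(scores)) {
    paste(chrom, start0, end0, names, sep = "\t")
  } else {
    sc <- if (raw_scores) fmt_num(scores) else {
      sprintf("%d", pmin(1000L, pmax(0L, as.integer(round(scores)))))
    }
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "."
    paste(chrom, start0, end0, names, sc, strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file
#'
#' Accepts BED3+ (tab-separated, no header). Columns beyond the third are
#' kept as `name`, `score`, `strand` when present.
#'
#' @param path BED file path.
#' @param seqlengths Optional named chromosome lengths to attach.
#' @return A `GRanges` (1-based closed internally).
#' @export
read_bed <- function(path, seqlengths = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  if (ncol(df) >= 6) {
    strand <- as.character(df[[6]])
    strand[!strand %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- strand
  }
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write a profile as bedGraph
#'
#' One row per GATC fragment, 4 columns (chrom, 0-based start, end, score).
#' For linear TaDa ratio tracks the midline is 1 (a fragment with equal
#' Dam-fusion and Dam-only signal scores 1).
#'
#' @param profile A `tada_profile` (see [new_profile()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, path) {
  gr <- profile$frags
  lines <- paste(as.character(GenomeInfoDb::seqnames(gr)),
                 BiocGenerics::start(gr) - 1L,
                 BiocGenerics::end(gr),
                 fmt_num(profile$score), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph profile
#'
#' @param path bedGraph path (4 columns, no track line).
#' @param scale Scale tag to attach (`"log2"` or `"linear"`).
#' @param construct,replicate Labels to attach.
#' @return A `tada_profile`.
#' @export
read_bedgraph <- function(path, scale = "linear", construct = NA_character_,
                          replicate = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  new_profile(gr, as.numeric(df[[4]]), scale = scale,
              construct = construct, replicate = replicate)
}

#' Write a data frame as TSV
#'
#' Tab-separated, header, no quoting, no row names; numeric columns are
#' serialized with full precision so round-trips are exact.
#'
#' @param df A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
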