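#' @importFrom methods as is
#' @importFrom stats dnorm ppois pgamma runif rnorm uniroot setNames
#' @importFrom utils head tail write.table
NULL

# All internal coordinates are 0-based half-open [start, end); conversion to
# the 1-based inclusive convention of SAM/GRanges happens only at the
# boundaries below.

#' Construct a 0-based half-open genomic interval table
#'
#' The package's universal coordinate currency: a plain `data.frame` with
#' columns `contig`, `start`, `end` where `start` is 0-based inclusive and
#' `end` is 0-based exclusive (the BED convention).
#'
#' @param contig character vector of contig names.
#' @param start,end integer-like vectors; `end > start` required.
#' @param ... further equal-length columns stored alongside.
#' @return a `data.frame` with at least columns `contig`, `start`, `end`.
#' @export
genomic_intervals <- function(contig, start, end, ...) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(!nzchar(contig))) stop("contig names must be non-empty")
  if (any(end <= start)) stop("interval end must exceed start (0-based half-open)")
  data.frame(contig = as.character(contig), start = as.numeric(start),
             end = as.numeric(end), ..., stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based inclusive)
as_granges0 <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand
             else rep("*", length(df$contig))
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
    if (GenomeInfoDb_ok) {
      gr <- GenomicRanges::GRanges(
        seqnames = factor(as.character(GenomicRanges::seqnames(gr)),
                          levels = names(seqlengths)),
        ranges = IRanges::ranges(gr), strand = GenomicRanges::strand(gr),
        seqlengths = seqlengths)
    }
  }
  gr
}

# GRanges -> 0-based half-open data.frame
granges_to_df0 <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

# Read a 3+ column BED file into the internal 0-based data.frame.
read_bed0 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  genomic_intervals(df[[1]], df[[2]], df[[3]])
}

write_bed0 <- function(df, path, extra_cols = character(), header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  cols <- c("contig", "start", "end", extra_cols)
  utils::write.table(df[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# overlap width between one interval and a vector of intervals (same contig
# assumed filtered by caller); 0-based half-open arithmetic.
overlap_width0 <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}
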