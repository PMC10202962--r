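#' Open an alignment file, converting SAM text to sorted+indexed BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] (which coordinate-sorts
#' and indexes) into `work_dir`; BAM input must already be accompanied by a
#' `.bai` index.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @param work_dir directory for the converted BAM when `path` is SAM.
#' @return path to a coordinate-sorted, indexed BAM file.
#' @export
ensure_bam <- function(path, work_dir = tempdir()) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- file.path(work_dir, sub("\\.sam$", "", basename(path), ignore.case = TRUE))
    return(Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE))
  }
  idx <- paste0(path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", path, ignore.case = TRUE)
  if (!file.exists(idx) && !file.exists(idx2))
    stop("BAM index (.bai) not found for: ", path,
         " (coordinate-sorted, indexed input required)")
  path
}

cigar_clips <- function(cigar) {
  left <- rep(0L, length(cigar))
  right <- left
  has_l <- grepl("^[0-9]+[SH]", cigar)
  left[has_l] <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cigar[has_l]))
  has_r <- grepl("[0-9]+[SH]$", cigar)
  right[has_r] <- as.integer(sub("^.*?([0-9]+)[SH]$", "\\1", cigar[has_r]))
  list(left = left, right = right)
}

#' Load filtered ATAC-Seq alignments
#'
#' Streams primary alignments from a coordinate-sorted BAM/SAM file and
#' applies the preprocessing filters: mapping quality strictly greater than
#' `mapq_min`, not flagged as duplicate, not overlapping any blacklist
#' interval (any-overlap, >= 1 bp, by default). Unmapped, secondary and
#' supplementary records are dropped.
#'
#' @param path BAM (indexed) or SAM file.
#' @param blacklist optional blacklist as a 0-based interval `data.frame`
#'   (see [genomic_intervals()]) or a path to a BED file.
#' @param mapq_min reads with `mapq > mapq_min` are kept (strict; the
#'   default 10 drops reads at exactly MAPQ 10).
#' @param work_dir scratch directory for SAM conversion.
#' @return a `data.frame` of reads with 0-based half-open `start`/`end`
#'   alignment spans, clip lengths, mate position and template length,
#'   sorted by contig then start.
#' @export
load_filtered_reads <- function(path, blacklist = NULL, mapq_min = 10,
                                work_dir = tempdir()) {
  bam <- ensure_bam(path, work_dir)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "mrnm", "mpos", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(aln)
  reads <- data.frame(
    read_id = as.character(md$qname),
    contig = as.character(GenomicAlignments::seqnames(aln)),
    start = GenomicAlignments::start(aln) - 1,
    end = as.numeric(GenomicAlignments::end(aln)),
    strand = as.character(GenomicAlignments::strand(aln)),
    mapq = as.integer(md$mapq),
    is_duplicate = bitwAnd(md$flag, 1024L) > 0L,
    mate_contig = as.character(md$mrnm),
    mate_start = ifelse(is.na(md$mpos), NA_real_, md$mpos - 1),
    tlen = as.numeric(md$isize),
    is_proper_pair = bitwAnd(md$flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  clips <- cigar_clips(GenomicAlignments::cigar(aln))
  reads$clip_left <- clips$left
  reads$clip_right <- clips$right

  # coordinate order check per contig (error on first out-of-order record)
  grp <- rle(reads$contig)
  idx_end <- cumsum(grp$lengths)
  idx_start <- idx_end - grp$lengths + 1L
  for (g in seq_along(grp$values)) {
    s <- reads$start[idx_start[g]:idx_end[g]]
    bad <- which(diff(s) < 0)
    if (length(bad))
      stop("input not coordinate-sorted at record ",
           reads$read_id[idx_start[g] + bad[1L]], " on ", grp$values[g])
  }

  keep <- reads$mapq > mapq_min & !reads$is_duplicate
  reads <- reads[keep, , drop = FALSE]
  if (!is.null(blacklist)) {
    if (is.character(blacklist)) blacklist <- read_bed0(blacklist)
    if (nrow(blacklist)) {
      hits <- GenomicRanges::findOverlaps(as_granges0(reads),
                                          as_granges0(blacklist))
      drop <- unique(S4Vectors::queryHits(hits))
      if (length(drop)) reads <- reads[-drop, , drop = FALSE]
    }
  }
  rownames(reads) <- NULL
  reads
}

#' Classify reads into junction-evidence classes
#'
#' A read is *discordant* when its absolute template length exceeds
#' `insert_threshold` or (optionally) when its mate maps to a different
#' contig; it is *clipped* when its alignment is soft/hard-clipped at either
#' end. The labels compose: a read can be `discordant+clipped`.
#'
#' @param reads a `data.frame` from [load_filtered_reads()].
#' @param insert_threshold template length (bp) above which a pair is called
#'   discordant; default 1500.
#' @param intercontig_discordant treat mates on different contigs as
#'   discordant (default TRUE; ecDNA may join different chromosomes).
#' @return `reads` with logical columns `is_discordant`, `is_clipped` and a
#'   character column `class`.
#' @export
classify_reads <- function(reads, insert_threshold = 1500,
                           intercontig_discordant = TRUE) {
  inter <- !is.na(reads$mate_contig) & reads$mate_contig != reads$contig
  long_insert <- !is.na(reads$tlen) & abs(reads$tlen) > insert_threshold
  reads$is_discordant <- long_insert | (intercontig_discordant & inter)
  reads$is_clipped <- (reads$clip_left + reads$clip_right) > 0
  reads$class <- ifelse(reads$is_discordant & reads$is_clipped, "discordant+clipped",
                 ifelse(reads$is_discordant, "discordant",
                 ifelse(reads$is_clipped, "clipped", "concordant")))
  reads
}
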