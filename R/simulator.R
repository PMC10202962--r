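#' Build a seeded synthetic reference genome
#'
#' A random-sequence reference with seeded N runs, used as a desk-scale
#' stand-in for a real genome (it is labelled synthetic everywhere). The
#' sequence itself is optional: mock generation and perfect alignment only
#' need contig lengths and the N-run map, so large benchmark references can
#' skip the ~tens-of-MB of actual bases.
#'
#' @param contig_lengths named vector of contig lengths (bp); default two
#'   contigs totalling ~20 Mb.
#' @param n_nruns number of N runs to scatter across the genome.
#' @param nrun_size length range (bp) of each N run.
#' @param with_sequence materialize random A/C/G/T sequence (default TRUE).
#' @return a `synthetic_reference` object: `list(lengths, nruns, seqs)`.
#' @export
synthetic_reference <- function(contig_lengths = c(chr1 = 12e6, chr2 = 8e6),
                                n_nruns = 8, nrun_size = c(2000, 10000),
                                with_sequence = TRUE) {
  stopifnot(!is.null(names(contig_lengths)))
  nruns <- NULL
  if (n_nruns > 0) {
    ctg <- sample(names(contig_lengths), n_nruns, replace = TRUE,
                  prob = contig_lengths / sum(contig_lengths))
    len <- round(runif(n_nruns, nrun_size[1], nrun_size[2]))
    start <- floor(runif(n_nruns) * (contig_lengths[ctg] - len))
    nruns <- granges_to_df0(GenomicRanges::reduce(
      as_granges0(genomic_intervals(ctg, start, start + len))))
  }
  if (is.null(nruns)) nruns <- genomic_intervals(character(), numeric(), numeric())
  seqs <- NULL
  if (with_sequence) {
    seqs <- Biostrings::DNAStringSet(vapply(names(contig_lengths), function(ctg) {
      paste(sample(c("A", "C", "G", "T"), contig_lengths[[ctg]], replace = TRUE),
            collapse = "")
    }, ""))
    names(seqs) <- names(contig_lengths)
    for (i in seq_len(nrow(nruns))) {
      r <- nruns[i, ]
      seqs[[r$contig]] <- Biostrings::replaceAt(
        seqs[[r$contig]], IRanges::IRanges(r$start + 1, r$end),
        paste(rep("N", r$end - r$start), collapse = ""))
    }
  }
  structure(list(lengths = contig_lengths, nruns = nruns, seqs = seqs),
            class = "synthetic_reference")
}

#' Load a reference from FASTA
#'
#' @param path FASTA file.
#' @return a `synthetic_reference`-shaped object with the N-run map scanned
#'   from the sequence.
#' @export
reference_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lengths <- setNames(Biostrings::width(seqs), names(seqs))
  runs <- lapply(names(seqs), function(ctg) {
    m <- IRanges::reduce(as(Biostrings::matchPattern("N", seqs[[ctg]],
                                                     fixed = FALSE), "IRanges"))
    m <- m[Biostrings::width(m) > 0]
    if (!length(m)) return(NULL)
    genomic_intervals(rep(ctg, length(m)), IRanges::start(m) - 1,
                      IRanges::end(m))
  })
  runs <- do.call(rbind, runs[!vapply(runs, is.null, TRUE)])
  if (is.null(runs)) runs <- genomic_intervals(character(), numeric(), numeric())
  structure(list(lengths = lengths, nruns = runs, seqs = seqs),
            class = "synthetic_reference")
}

#' Write the reference as FASTA
#' @param ref a `synthetic_reference` with sequence.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  if (is.null(ref$seqs)) stop("reference has no materialized sequence")
  Biostrings::writeXStringSet(ref$seqs, path)
  invisible(path)
}

# non-N intervals of the reference (0-based half-open)
non_n_intervals <- function(ref) {
  all <- genomic_intervals(names(ref$lengths), rep(0, length(ref$lengths)),
                           ref$lengths)
  if (!nrow(ref$nruns)) return(all)
  granges_to_df0(GenomicRanges::setdiff(as_granges0(all), as_granges0(ref$nruns)))
}

# sample one placement of length l from blocks (rows weighted by slack)
.sample_placement <- function(blocks, l) {
  slack <- blocks$end - blocks$start - l + 1
  ok <- which(slack > 0)
  if (!length(ok)) return(NULL)
  i <- if (length(ok) == 1) ok else sample(ok, 1, prob = slack[ok])
  s <- blocks$start[i] + floor(runif(1) * slack[i])
  genomic_intervals(blocks$contig[i], s, s + l)
}

#' Generate one ground-truth mock ecDNA
#'
#' Segments are drawn from the non-N portion of the reference, mutually
#' non-overlapping, each assigned an independent uniform-random orientation,
#' and ligated in draw order into a circle whose total length falls in
#' `total_size`. An `exclude` set (plus `min_gap` padding around every
#' placed segment) lets callers keep several mocks in one sample well
#' separated, emulating the sparsity that circles drawn from a full-size
#' genome would have on a desk-scale reference.
#'
#' @param ref a `synthetic_reference`.
#' @param n_segments integer range for the segment count (default `c(1, 50)`).
#' @param total_size circle length range in bp (default `c(5e3, 1e7)`).
#' @param min_segment minimum single-segment length (bp).
#' @param exclude optional intervals the mock must avoid.
#' @param min_gap padding (bp) kept between segments (and `exclude`).
#' @param id circle identifier string.
#' @return a `mock_ecdna` object: `list(id, segments, circle_length, cum)`.
#' @export
generate_mock_ecdna <- function(ref, n_segments = c(1, 50),
                                total_size = c(5e3, 1e7), min_segment = 2500,
                                exclude = NULL, min_gap = 50000,
                                id = "mock1") {
  avail <- non_n_intervals(ref)
  total <- round(runif(1, total_size[1], total_size[2]))
  kmax <- min(n_segments[2], floor(total / min_segment))
  krange <- seq.int(n_segments[1], max(n_segments[1], kmax))
  k <- if (length(krange) == 1) krange else sample(krange, 1)
  # symmetric Dirichlet split with a floor on each part
  w <- stats::rexp(k)
  lens <- round(min_segment + w / sum(w) * (total - k * min_segment))
  lens[k] <- total - sum(lens[-k])

  used <- exclude
  segs <- vector("list", k)
  for (i in seq_len(k)) {
    blocks <- avail
    if (!is.null(used) && nrow(used)) {
      pad <- genomic_intervals(used$contig, pmax(0, used$start - min_gap),
                               used$end + min_gap)
      blocks <- granges_to_df0(GenomicRanges::setdiff(
        as_granges0(blocks), as_granges0(pad)))
    }
    placed <- .sample_placement(blocks, lens[i])
    if (is.null(placed))
      stop("reference too small for requested mock ecDNA size/count")
    placed$strand <- sample(c("+", "-"), 1)
    segs[[i]] <- placed
    used <- rbind(if (is.null(used)) NULL else used,
                  placed[, c("contig", "start", "end")])
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  structure(list(id = id, segments = segments,
                 circle_length = sum(segments$end - segments$start),
                 cum = cumsum(segments$end - segments$start)),
            class = "mock_ecdna")
}

#' Extract the ligated circular sequence of a mock ecDNA
#'
#' @param mock a `mock_ecdna`.
#' @param ref a `synthetic_reference` with sequence.
#' @return a [Biostrings::DNAString] of length `circle_length`; offset 0
#'   is the first base of segment 1, and the last base is circularly
#'   adjacent to offset 0.
#' @export
circular_sequence <- function(mock, ref) {
  if (is.null(ref$seqs)) stop("reference has no materialized sequence")
  parts <- lapply(seq_len(nrow(mock$segments)), function(i) {
    s <- mock$segments[i, ]
    if (s$end > ref$lengths[[s$contig]]) stop("segment outside contig ", s$contig)
    x <- Biostrings::subseq(ref$seqs[[s$contig]], s$start + 1, s$end)
    if (s$strand == "-") x <- Biostrings::reverseComplement(x)
    as.character(x)
  })
  Biostrings::DNAString(paste(unlist(parts), collapse = ""))
}

# truncated normal fragment lengths in [lo, hi]
.rfrag <- function(n, mean, sd, lo, hi) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate paired-end reads from a circular template
#'
#' Fragment starts are uniform on the circle (fragments crossing offset 0
#' wrap) and the pair count follows the coverage identity
#' `round(local_depth * circle_length / (2 * read_len))`.
#'
#' @param mock a `mock_ecdna`.
#' @param local_depth target mean per-base depth over the circle.
#' @param read_len read length (bp, 35-150 typical).
#' @param frag_mean,frag_sd,frag_max fragment length model (truncated normal
#'   in `[read_len, frag_max]`; defaults 250/50/1000 keep linear pairs below
#'   the 1500 bp discordance threshold).
#' @param error_rate i.i.d. substitution rate applied when sequences are
#'   emitted.
#' @param prefix read-name prefix.
#' @return `data.frame` of truth placements: `qname`, `start` (circular
#'   offset of the fragment), `frag_len`, `read_len`, plus attributes.
#' @export
simulate_reads <- function(mock, local_depth = 30, read_len = 100,
                           frag_mean = 250, frag_sd = 50, frag_max = 1000,
                           error_rate = 0, prefix = mock$id) {
  if (read_len > frag_mean) stop("read_len must not exceed the fragment mean")
  L <- mock$circle_length
  n <- round(local_depth * L / (2 * read_len))
  pairs <- data.frame(
    qname = sprintf("%s_%06d", prefix, seq_len(n)),
    start = floor(runif(n) * L),
    frag_len = .rfrag(n, frag_mean, frag_sd, read_len, frag_max),
    read_len = read_len, stringsAsFactors = FALSE)
  attr(pairs, "error_rate") <- error_rate
  pairs
}

#' Simulate uniform linear background pairs over the reference
#'
#' Concordant pairs drawn uniformly from the non-N reference at the
#' requested mean depth; fragment lengths are truncated well below the
#' discordance threshold, so a clean background contributes no junction
#' evidence.
#'
#' @param ref a `synthetic_reference`.
#' @param genome_depth target mean depth (the 1-3x regime of real ATAC-Seq
#'   libraries; default 2).
#' @inheritParams simulate_reads
#' @return `data.frame` of placements: `qname`, `contig`, `start`,
#'   `frag_len`, `read_len`.
#' @export
simulate_background <- function(ref, genome_depth = 2, read_len = 100,
                                frag_mean = 250, frag_sd = 50, frag_max = 1000,
                                error_rate = 0, prefix = "bg") {
  blocks <- non_n_intervals(ref)
  bw <- blocks$end - blocks$start
  total <- sum(bw)
  n <- round(genome_depth * total / (2 * read_len))
  frag <- .rfrag(n, frag_mean, frag_sd, read_len, frag_max)
  slack <- pmax(bw - max(frag) + 1, 0)
  bi <- sample.int(nrow(blocks), n, replace = TRUE, prob = slack)
  start <- blocks$start[bi] + floor(runif(n) * (bw[bi] - frag + 1))
  pairs <- data.frame(
    qname = sprintf("%s_%07d", prefix, seq_len(n)),
    contig = blocks$contig[bi], start = start, frag_len = frag,
    read_len = read_len, stringsAsFactors = FALSE)
  attr(pairs, "error_rate") <- error_rate
  pairs
}
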