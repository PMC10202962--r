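# map reads placed on the circle back to reference coordinates; a is the
# 0-based circular offset vector, rl the read length, circle_strand the
# orientation of sequencing along the circle ("+" for R1, "-" for R2).
# Returns one primary placement per read: contig, pos0, mlen, ref_strand,
# cl/cr soft clips (reference orientation) and the segment index used.
.map_circle_reads <- function(mock, a, rl, circle_strand) {
  segs <- mock$segments
  k <- nrow(segs)
  cum <- mock$cum
  starts_c <- c(0, cum[-k])
  L <- mock$circle_length
  j <- findInterval(a, starts_c)
  n <- length(a)
  out <- data.frame(contig = character(n), pos0 = numeric(n), mlen = integer(n),
                    ref_strand = character(n), cl = integer(n), cr = integer(n),
                    seg = integer(n), stringsAsFactors = FALSE)
  place <- function(i, jj, off, plen, before) {
    if (segs$strand[jj] == "+") {
      out$pos0[i] <<- segs$start[jj] + off
      out$ref_strand[i] <<- circle_strand
      out$cl[i] <<- before; out$cr[i] <<- rl - before - plen
    } else {
      out$pos0[i] <<- segs$end[jj] - off - plen
      out$ref_strand[i] <<- if (circle_strand == "+") "-" else "+"
      out$cl[i] <<- rl - before - plen; out$cr[i] <<- before
    }
    out$contig[i] <<- segs$contig[jj]
    out$mlen[i] <<- plen
    out$seg[i] <<- jj
  }
  cross <- which(a + rl > cum[j])
  simple <- setdiff(seq_len(n), cross)
  if (length(simple)) {
    jj <- j[simple]
    off <- a[simple] - starts_c[jj]
    plus <- segs$strand[jj] == "+"
    out$contig[simple] <- segs$contig[jj]
    out$pos0[simple] <- ifelse(plus, segs$start[jj] + off,
                               segs$end[jj] - off - rl)
    out$ref_strand[simple] <- ifelse(plus == (circle_strand == "+"), "+", "-")
    out$mlen[simple] <- rl
    out$seg[simple] <- jj
  }
  two_plus <- 0L
  for (i in cross) {
    pos <- a[i]; remaining <- rl; before <- 0L
    pieces <- list()
    while (remaining > 0) {
      pm <- pos %% L
      jj <- findInterval(pm, starts_c)
      plen <- min(cum[jj] - pm, remaining)
      pieces[[length(pieces) + 1L]] <- c(jj = jj, off = pm - starts_c[jj],
                                         plen = plen, before = before)
      pos <- pos + plen; remaining <- remaining - plen; before <- before + plen
    }
    if (length(pieces) > 2L) two_plus <- two_plus + 1L
    best <- pieces[[which.max(vapply(pieces, function(p) p[["plen"]], 0))]]
    place(i, best[["jj"]], best[["off"]], best[["plen"]], best[["before"]])
  }
  if (two_plus > 0)
    warning(two_plus, " read(s) crossed more than one junction; ",
            "clipped to their longest reference-consistent part")
  out
}

.cigar_str <- function(cl, mlen, cr) {
  paste0(ifelse(cl > 0, paste0(cl, "S"), ""), mlen, "M",
         ifelse(cr > 0, paste0(cr, "S"), ""))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

# assemble the two mates of each pair into SAM records given their primary
# placements (data.frames with contig/pos0/mlen/ref_strand/cl/cr) and
# optional reference-oriented sequences.
.pair_sam <- function(qname, p1, p2, rl, seq1, seq2, frag_max) {
  same <- p1$contig == p2$contig
  end1 <- p1$pos0 + p1$mlen; end2 <- p2$pos0 + p2$mlen
  span <- pmax(end1, end2) - pmin(p1$pos0, p2$pos0)
  lead1 <- p1$pos0 <= p2$pos0
  tlen1 <- same * ifelse(lead1, span, -span)
  tlen2 <- same * ifelse(lead1, -span, span)
  rev1 <- p1$ref_strand == "-"; rev2 <- p2$ref_strand == "-"
  proper <- same & span <= frag_max & (rev1 != rev2)
  flag1 <- 1L + 64L + 16L * rev1 + 32L * rev2 + 2L * proper
  flag2 <- 1L + 128L + 16L * rev2 + 32L * rev1 + 2L * proper
  full_m <- paste0(rl, "M")
  cig <- function(p) {
    out <- rep.int(full_m, length(p$cl))
    idx <- which(p$cl > 0 | p$cr > 0)
    if (length(idx)) out[idx] <- .cigar_str(p$cl[idx], p$mlen[idx], p$cr[idx])
    out
  }
  qual1 <- if (identical(seq1, "*")) "*" else strrep("?", rl)
  qual2 <- if (identical(seq2, "*")) "*" else strrep("?", rl)
  rec <- function(p, mate, flag, tlen, seqs, qual) data.frame(
    qname = qname, flag = as.integer(flag),
    rname = p$contig, pos = as.integer(p$pos0 + 1L), mapq = 60L,
    cigar = cig(p),
    rnext = ifelse(same, "=", mate$contig), pnext = as.integer(mate$pos0 + 1L),
    tlen = as.integer(tlen), seq = seqs, qual = qual,
    stringsAsFactors = FALSE)
  rbind(rec(p1, p2, flag1, tlen1, seq1, qual1),
        rec(p2, p1, flag2, tlen2, seq2, qual2))
}

#' Emit perfect alignments for simulated pairs as SAM records
#'
#' Replaces the external aligner for self-contained benchmarking: every
#' read is mapped back through the mock's segment map to reference
#' coordinates. A read crossing a junction is emitted as a single primary
#' alignment of its longest reference-consistent part with the remainder
#' soft-clipped; mates in different segments acquire a long or inter-contig
#' template, exactly the discordant evidence the detector consumes.
#'
#' @param pairs placements from [simulate_reads()] (with `mock`) or
#'   [simulate_background()] (with `mock = NULL`).
#' @param mock the `mock_ecdna` the pairs were simulated from, or `NULL`
#'   for background pairs.
#' @param ref reference (needed when `with_seq = TRUE`).
#' @param with_seq emit real sequences (requires reference sequence);
#'   `FALSE` writes `*`, which downstream depth/graph analysis never reads.
#' @param frag_max proper-pair template bound for FLAG bookkeeping.
#' @return `data.frame` of SAM fields (two rows per pair).
#' @export
perfect_align <- function(pairs, mock = NULL, ref = NULL, with_seq = TRUE,
                          frag_max = 1000) {
  if (!nrow(pairs)) stop("no pairs to align")
  rl <- pairs$read_len[1]
  error_rate <- attr(pairs, "error_rate") %||% 0
  if (is.null(mock)) {
    a1 <- pairs$start
    a2 <- pairs$start + pairs$frag_len - rl
    p1 <- data.frame(contig = pairs$contig, pos0 = a1, mlen = rl,
                     ref_strand = "+", cl = 0L, cr = 0L,
                     stringsAsFactors = FALSE)
    p2 <- data.frame(contig = pairs$contig, pos0 = a2, mlen = rl,
                     ref_strand = "-", cl = 0L, cr = 0L,
                     stringsAsFactors = FALSE)
    if (with_seq) {
      if (is.null(ref$seqs)) stop("with_seq=TRUE requires reference sequence")
      seq1 <- seq2 <- character(nrow(pairs))
      for (ctg in unique(pairs$contig)) {
        cs <- as.character(ref$seqs[[ctg]])
        i <- pairs$contig == ctg
        seq1[i] <- substring(cs, a1[i] + 1, a1[i] + rl)
        seq2[i] <- substring(cs, a2[i] + 1, a2[i] + rl)
      }
      seq1 <- .inject_errors(seq1, error_rate)
      seq2 <- .inject_errors(seq2, error_rate)
    } else seq1 <- seq2 <- "*"
    return(.pair_sam(pairs$qname, p1, p2, rl, seq1, seq2, frag_max))
  }
  L <- mock$circle_length
  a1 <- pairs$start %% L
  a2 <- (pairs$start + pairs$frag_len - rl) %% L
  p1 <- .map_circle_reads(mock, a1, rl, "+")
  p2 <- .map_circle_reads(mock, a2, rl, "-")
  if (with_seq) {
    cs2 <- strrep(as.character(circular_sequence(mock, ref)), 2)
    sub1 <- substring(cs2, a1 + 1, a1 + rl)
    sub2 <- substring(cs2, a2 + 1, a2 + rl)
    # SEQ is reference-forward over the aligned piece: the circle-forward
    # substring matches the reference iff the primary segment is '+'
    minus1 <- mock$segments$strand[p1$seg] == "-"
    minus2 <- mock$segments$strand[p2$seg] == "-"
    seq1 <- sub1; seq1[minus1] <- .revcomp_chr(sub1[minus1])
    seq2 <- sub2; seq2[minus2] <- .revcomp_chr(sub2[minus2])
    seq1 <- .inject_errors(seq1, error_rate)
    seq2 <- .inject_errors(seq2, error_rate)
  } else seq1 <- seq2 <- "*"
  .pair_sam(pairs$qname, p1, p2, rl, seq1, seq2, frag_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write SAM records to a text SAM file
#'
#' @param records `data.frame` from [perfect_align()] (rows from several
#'   calls may be `rbind`-ed together first).
#' @param contig_lengths named contig lengths for the `@SQ` header.
#' @param path output `.sam` path.
#' @return the path, invisibly.
#' @export
write_sam <- function(records, contig_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  writeLines(header, path)
  data.table::fwrite(records, path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated pairs as FASTQ (R1/R2)
#'
#' Sequences are emitted in sequencing orientation (R2 is the reverse
#' complement of the template); qualities are constant Q30.
#'
#' @param pairs placements from [simulate_reads()] or
#'   [simulate_background()].
#' @param mock `mock_ecdna` or `NULL` for background pairs.
#' @param ref reference with sequence.
#' @param r1_path,r2_path output FASTQ paths.
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_fastq <- function(pairs, mock = NULL, ref, r1_path, r2_path) {
  rl <- pairs$read_len[1]
  error_rate <- attr(pairs, "error_rate") %||% 0
  if (is.null(mock)) {
    seq1 <- seq2 <- character(nrow(pairs))
    a2 <- pairs$start + pairs$frag_len - rl
    for (ctg in unique(pairs$contig)) {
      cs <- as.character(ref$seqs[[ctg]])
      i <- pairs$contig == ctg
      seq1[i] <- substring(cs, pairs$start[i] + 1, pairs$start[i] + rl)
      seq2[i] <- substring(cs, a2[i] + 1, a2[i] + rl)
    }
  } else {
    cs2 <- strrep(as.character(circular_sequence(mock, ref)), 2)
    L <- mock$circle_length
    a1 <- pairs$start %% L
    a2 <- (pairs$start + pairs$frag_len - rl) %% L
    seq1 <- substring(cs2, a1 + 1, a1 + rl)
    seq2 <- substring(cs2, a2 + 1, a2 + rl)
  }
  seq2 <- .revcomp_chr(seq2)
  seq1 <- .inject_errors(seq1, error_rate)
  seq2 <- .inject_errors(seq2, error_rate)
  qual <- strrep("?", rl)
  writeLines(paste0("@", pairs$qname, "/1\n", seq1, "\n+\n", qual), r1_path)
  writeLines(paste0("@", pairs$qname, "/2\n", seq2, "\n+\n", qual), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write mock-ecDNA truth as JSON + BED
#'
#' Uses the same BED dialect the detector emits so truth and predictions
#' can be compared directly.
#'
#' @param mocks list of `mock_ecdna` objects.
#' @param json_path,bed_path output paths (either may be `NULL`).
#' @return invisibly, the list of paths written.
#' @export
write_truth <- function(mocks, json_path = NULL, bed_path = NULL) {
  if (!is.null(json_path)) {
    recs <- lapply(mocks, function(mk) list(
      circle_id = mk$id, total_length = mk$circle_length,
      segments = mk$segments))
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(bed_path)) {
    rows <- unlist(lapply(mocks, function(mk) {
      n <- nrow(mk$segments)
      sprintf("%s\t%d\t%d\t%s_%d_of_%d\t0\t%s", mk$segments$contig,
              as.integer(mk$segments$start), as.integer(mk$segments$end),
              mk$id, seq_len(n), n, mk$segments$strand)
    }))
    writeLines(c("#chrom\tstart\tend\tname\tscore\tstrand", rows), bed_path)
  }
  invisible(c(json_path, bed_path))
}

#' Read mock truth back from JSON
#' @param json_path path written by [write_truth()].
#' @return list of `mock_ecdna` objects.
#' @export
read_truth_json <- function(json_path) {
  recs <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(recs)), function(i) {
    seg <- recs$segments[[i]]
    structure(list(id = recs$circle_id[i], segments = seg,
                   circle_length = recs$total_length[i],
                   cum = cumsum(seg$end - seg$start)),
              class = "mock_ecdna")
  })
}
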