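#' Poisson survival function P(X >= count)
#'
#' Upper-tail probability of a Poisson variable, extended continuously to
#' real-valued counts through the gamma-Poisson duality
#' `P(X >= c) = P_lower_reg_gamma(c, lambda) = pgamma(lambda, shape = c)`.
#' For integer counts this equals the classical finite series
#' `1 - sum_{k < c} exp(-lambda) lambda^k / k!`. Counts of the discordant
#' ratio track are fractional, which is why the continuous extension is the
#' default significance machinery of the whole package.
#'
#' @param count non-negative count (may be fractional); vectorized.
#' @param lam Poisson mean, must be > 0.
#' @return `P(X >= count)`; exactly 1 for `count <= 0`.
#' @export
poisson_sf <- function(count, lam) {
  if (any(lam <= 0)) stop("lambda must be positive")
  ifelse(count <= 0, 1, pgamma(lam, shape = pmax(count, .Machine$double.xmin)))
}

# smallest integer k with poisson_sf(k, lam) < p  (depth tracks are integer)
poisson_min_signif_count <- function(lam, p) {
  k <- stats::qpois(p, lam, lower.tail = FALSE)  # P(X > k) < p
  while (k > 0 && poisson_sf(k, lam) < p) k <- k - 1L
  while (poisson_sf(k, lam) >= p) k <- k + 1L
  as.integer(k)
}

# smallest real c with poisson_sf(c, lam) <= thr (continuous threshold for
# the fractional ratio track)
poisson_signif_ratio_cut <- function(lam, thr) {
  f <- function(c) pgamma(lam, shape = c) - thr
  lo <- 1e-9
  hi <- max(lam * 2, 2)
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Pile up read alignment spans into per-base depth tracks
#'
#' @param reads `data.frame` of reads (0-based half-open spans).
#' @param contig_lengths named vector of contig lengths (bp).
#' @return an [IRanges::RleList] of per-base depth, one element per contig
#'   in `contig_lengths` (run-length encoded).
#' @export
pileup_track <- function(reads, contig_lengths) {
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be a named vector")
  if (nrow(reads)) {
    bad <- which(!(reads$contig %in% names(contig_lengths)))
    if (length(bad))
      stop("read ", reads$read_id[bad[1]], " maps to unknown contig ",
           reads$contig[bad[1]])
    over <- which(reads$end > contig_lengths[reads$contig])
    if (length(over))
      stop("read ", reads$read_id[over[1]], " extends beyond the end of ",
           reads$contig[over[1]])
  }
  gr <- as_granges0(reads[, c("contig", "start", "end")],
                    seqlengths = contig_lengths)
  cov <- GenomicRanges::coverage(gr, width = contig_lengths)
  cov[names(contig_lengths)]
}

#' Genome-wide mean depth (the global Poisson lambda)
#'
#' Total aligned bases divided by the effective genome length. The
#' effective length defaults to the full track length minus blacklist bases;
#' pass `effective_length` directly to also exclude N runs of the reference.
#'
#' @param track an `RleList` depth track.
#' @param blacklist optional interval `data.frame`; its bases are excluded.
#' @param effective_length optional explicit effective genome length.
#' @return mean depth (reads/bp) over the effective genome.
#' @export
track_lambda <- function(track, blacklist = NULL, effective_length = NULL) {
  total <- sum(vapply(track, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                             S4Vectors::runLength(x)), 0))
  if (is.null(effective_length)) {
    effective_length <- sum(vapply(track, length, 0L))
    if (!is.null(blacklist) && nrow(blacklist))
      effective_length <- effective_length - sum(blacklist$end - blacklist$start)
  }
  if (effective_length <= 0) stop("effective genome length must be positive")
  total / effective_length
}

#' Call consecutive enrichment regions
#'
#' Maximal runs of bases whose depth is Poisson-significant against the
#' genome-wide mean (`poisson_sf(depth, lam) < p_cut`), with runs closer
#' than `merge_dist` merged into one region (strict: a gap of exactly
#' `merge_dist` bp is not merged).
#'
#' @param track depth `RleList` from [pileup_track()].
#' @param lam genome-wide mean depth, e.g. from [track_lambda()].
#' @param p_cut per-base significance threshold (default 0.05).
#' @param merge_dist merge gap (bp, default 12500).
#' @return `data.frame` with `contig`, `start`, `end`, `mean_depth`,
#'   `fold_enrichment`, coordinate-sorted.
#' @export
call_consecutive_regions <- function(track, lam, p_cut = 0.05,
                                     merge_dist = 12500) {
  if (lam <= 0) stop("lambda must be positive")
  kmin <- poisson_min_signif_count(lam, p_cut)
  out <- lapply(names(track), function(ctg) {
    rl <- track[[ctg]]
    if (length(rl) == 0) return(NULL)
    ir <- IRanges::reduce(as(IRanges::slice(rl, lower = kmin), "IRanges"),
                          min.gapwidth = merge_dist)
    if (length(ir) == 0) return(NULL)
    md <- IRanges::viewMeans(IRanges::Views(rl, ir))
    data.frame(contig = ctg, start = IRanges::start(ir) - 1,
               end = as.numeric(IRanges::end(ir)),
               mean_depth = as.numeric(md),
               fold_enrichment = as.numeric(md) / lam,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      mean_depth = numeric(), fold_enrichment = numeric())
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Call discordant-pair enrichment regions
#'
#' Builds the per-base ratio `r(b) = discordant depth / total depth` (0
#' where total is 0), takes the genome-wide mean ratio over covered bases as
#' Poisson lambda, and keeps maximal runs of bases whose score
#' `-log10(poisson_sf(r, lambda_r))` reaches `score_cut`
#' (default 1.301 = -log10(0.05)). Each run becomes a junction-evidence
#' region; its side is the majority strand vote of the discordant reads that
#' overlap it (forward strand extends rightwards, so the junction is on the
#' region's right; reverse, left). An exact tie emits two regions, one per
#' side. `mode = "count"` replaces the ratio track by the raw discordant
#' depth with the mean discordant depth as lambda (a statistically more
#' conventional alternative).
#'
#' @param disc_track discordant-read depth `RleList`.
#' @param total_track all-read depth `RleList` on the same contigs.
#' @param disc_reads `data.frame` of classified discordant reads (provides
#'   supporting read IDs and strand votes).
#' @param score_cut `-log10` p-value threshold (default 1.301).
#' @param mode `"count"` (default: discordant depth against the mean
#'   discordant depth) or `"ratio"` (the literal ratio model; see the
#'   methods vignette for why it is not the default).
#' @return `data.frame` with `contig`, `start`, `end`, `side`
#'   (`"left"`/`"right"`), `n_fwd`, `n_rev` and a list column `read_ids`.
#' @export
call_discordant_regions <- function(disc_track, total_track, disc_reads,
                                    score_cut = 1.301,
                                    mode = c("count", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(identical(names(disc_track), names(total_track)))
  covered <- vapply(total_track, function(x)
    sum(as.numeric(S4Vectors::runLength(x)[S4Vectors::runValue(x) > 0])), 0)
  n_cov <- sum(covered)
  if (n_cov == 0) stop("total depth track has no coverage")
  if (mode == "ratio") {
    score_track <- lapply(names(disc_track), function(ctg) {
      r <- disc_track[[ctg]] / total_track[[ctg]]
      v <- S4Vectors::runValue(r)
      v[!is.finite(v)] <- 0
      S4Vectors::runValue(r) <- v
      r
    })
    names(score_track) <- names(disc_track)
    lam_r <- sum(vapply(score_track, function(x)
      sum(as.numeric(S4Vectors::runValue(x)) * S4Vectors::runLength(x)), 0)) / n_cov
  } else {
    score_track <- as.list(disc_track)
    lam_r <- sum(vapply(score_track, function(x)
      sum(as.numeric(S4Vectors::runValue(x)) * S4Vectors::runLength(x)), 0)) / n_cov
  }
  if (lam_r <= 0) {
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      side = character(), n_fwd = integer(), n_rev = integer(),
                      read_ids = I(list())))
  }
  cstar <- poisson_signif_ratio_cut(lam_r, 10^(-score_cut))
  rows <- lapply(names(score_track), function(ctg) {
    ir <- as(IRanges::slice(score_track[[ctg]], lower = cstar,
                            includeLower = TRUE), "IRanges")
    if (length(ir) == 0) return(NULL)
    data.frame(contig = ctg, start = IRanges::start(ir) - 1,
               end = as.numeric(IRanges::end(ir)), stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  if (is.null(regions))
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      side = character(), n_fwd = integer(), n_rev = integer(),
                      read_ids = I(list())))
  regions <- regions[order(regions$contig, regions$start), , drop = FALSE]

  hits <- GenomicRanges::findOverlaps(as_granges0(regions),
                                      as_granges0(disc_reads))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rd <- sh[qh == i]
    if (!length(rd)) next  # no supporting reads: not a usable junction region
    ids <- unique(disc_reads$read_id[rd])
    n_fwd <- sum(disc_reads$strand[rd] == "+")
    n_rev <- sum(disc_reads$strand[rd] == "-")
    side <- if (n_fwd > n_rev) "right" else if (n_rev > n_fwd) "left" else c("left", "right")
    out[[i]] <- data.frame(contig = regions$contig[i], start = regions$start[i],
                           end = regions$end[i], side = side,
                           n_fwd = n_fwd, n_rev = n_rev,
                           read_ids = I(rep(list(ids), length(side))),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      side = character(), n_fwd = integer(), n_rev = integer(),
                      read_ids = I(list()))
  rownames(res) <- NULL
  attr(res, "lambda_ratio") <- lam_r
  res
}

#' Keep discordant regions hosted by a consecutive region
#'
#' Discordant-pair regions only make sense inside a depth-enriched segment;
#' regions in a depth desert are dropped. The host is the consecutive
#' region with the largest overlap.
#'
#' @param disc `data.frame` from [call_discordant_regions()].
#' @param consec `data.frame` from [call_consecutive_regions()].
#' @return `disc` filtered, with an integer `host` column indexing `consec`.
#' @export
attach_to_consecutive <- function(disc, consec) {
  if (!nrow(disc) || !nrow(consec)) return(disc[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(as_granges0(disc), as_granges0(consec))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- overlap_width0(disc$start[qh], disc$end[qh],
                       consec$start[sh], consec$end[sh])
  host <- rep(NA_integer_, nrow(disc))
  for (i in unique(qh)) {
    cand <- which(qh == i)
    host[i] <- sh[cand[which.max(ow[cand])]]
  }
  disc$host <- host
  out <- disc[!is.na(host), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda_ratio") <- attr(disc, "lambda_ratio")
  out
}

#' Export a depth track as bedGraph text
#'
#' @param track `RleList` depth track.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track)) {
    rl <- track[[ctg]]
    v <- S4Vectors::runValue(rl); l <- S4Vectors::runLength(rl)
    e <- cumsum(as.numeric(l)); s <- e - l
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ctg, as.integer(s[keep]),
                         as.integer(e[keep]), v[keep]), con)
  }
  invisible(path)
}
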