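#' Does a prediction have the same ligation structure as a truth circle?
#'
#' True when (i) there is a bijection between predicted and truth segments
#' in which each pair shares the contig and overlaps reciprocally by at
#' least `seg_overlap_frac` of both lengths, and (ii) after substituting
#' each predicted segment by its matched truth segment the two cyclic
#' structures have identical [canonical_structure()] keys (rotation and
#' reversal-with-strand-flip allowed).
#'
#' @param pred a circle candidate (list with a `segments` `data.frame`).
#' @param truth a `mock_ecdna`.
#' @param seg_overlap_frac reciprocal overlap requirement (default 0.95).
#' @return logical.
#' @export
same_ligation_structure <- function(pred, truth, seg_overlap_frac = 0.95) {
  ps <- pred$segments
  ts <- truth$segments
  if (nrow(ps) != nrow(ts)) return(FALSE)
  n <- nrow(ts)
  matched <- integer(n)  # pred row matched to each truth row
  taken <- logical(n)
  for (i in seq_len(n)) {
    cand <- which(ps$contig == ts$contig[i] & !taken)
    if (!length(cand)) return(FALSE)
    ow <- overlap_width0(ps$start[cand], ps$end[cand], ts$start[i], ts$end[i])
    tl <- ts$end[i] - ts$start[i]
    pl <- ps$end[cand] - ps$start[cand]
    ok <- cand[ow >= seg_overlap_frac * tl & ow >= seg_overlap_frac * pl]
    if (!length(ok)) return(FALSE)
    ow_ok <- ow[match(ok, cand)]
    pick <- ok[which.max(ow_ok)]
    matched[i] <- pick
    taken[pick] <- TRUE
  }
  # normalize the prediction onto truth coordinates, keep predicted strands
  norm <- ps
  truth_row <- integer(n); truth_row[matched] <- seq_len(n)
  norm$contig <- ts$contig[truth_row]
  norm$start <- ts$start[truth_row]
  norm$end <- ts$end[truth_row]
  identical(canonical_structure(norm), canonical_structure(ts))
}

# fraction of truth circle bases covered by the union of pred segments
# (orientation-blind: coverage is about bases, not strands)
coverage_fraction <- function(pred, truth) {
  unstranded <- function(df) as_granges0(df[, c("contig", "start", "end")])
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(unstranded(pred$segments)),
    GenomicRanges::reduce(unstranded(truth$segments)))
  sum(GenomicRanges::width(ov)) / truth$circle_length
}

#' Structure-aware truth matching criterion
#'
#' @param mode `"coverage_structure"` (predicted segments cover at least
#'   `coverage_frac` of the truth circle and the ligation structure is the
#'   same) or `"breakpoint_ci_structure"` (same structure and every truth
#'   breakpoint lies inside the matched predicted 95% credible interval).
#' @param coverage_frac coverage requirement (default 0.95).
#' @return a `match_criterion` list.
#' @export
match_criterion <- function(mode = c("coverage_structure",
                                     "breakpoint_ci_structure"),
                            coverage_frac = 0.95) {
  mode <- match.arg(mode)
  stopifnot(coverage_frac > 0, coverage_frac <= 1)
  structure(list(mode = mode, coverage_frac = coverage_frac),
            class = "match_criterion")
}

#' Match one prediction against one truth circle
#'
#' @param pred circle candidate.
#' @param truth `mock_ecdna`.
#' @param criterion a [match_criterion()].
#' @return logical.
#' @export
match_circle <- function(pred, truth, criterion = match_criterion()) {
  if (!same_ligation_structure(pred, truth)) return(FALSE)
  if (criterion$mode == "coverage_structure")
    return(coverage_fraction(pred, truth) >= criterion$coverage_frac)
  # breakpoint_ci_structure: every truth junction coordinate inside the
  # matched predicted CI; segments are aligned by interval overlap
  ps <- pred$segments
  ts <- truth$segments
  for (i in seq_len(nrow(ts))) {
    ow <- overlap_width0(ps$start, ps$end, ts$start[i], ts$end[i])
    ow[ps$contig != ts$contig[i]] <- 0
    j <- which.max(ow)
    if (ow[j] <= 0) return(FALSE)
    if (ts$start[i] < ps$ci_start_low[j] || ts$start[i] > ps$ci_start_high[j])
      return(FALSE)
    if (ts$end[i] < ps$ci_end_low[j] || ts$end[i] > ps$ci_end_high[j])
      return(FALSE)
  }
  TRUE
}

#' Score predictions against truth circles
#'
#' Greedy one-to-one matching, best coverage first: each truth is matched
#' by at most one prediction and vice versa. `tp` = matched truths, `fp` =
#' unmatched predictions, `fn` = unmatched truths.
#'
#' @param preds list of circle candidates.
#' @param truths list of `mock_ecdna`.
#' @param criterion a [match_criterion()].
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` and a
#'   per-truth logical `matched` vector.
#' @export
score_circles <- function(preds, truths, criterion = match_criterion()) {
  np <- length(preds); nt <- length(truths)
  hits <- list()
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    if (match_circle(preds[[i]], truths[[j]], criterion))
      hits[[length(hits) + 1L]] <- c(i = i, j = j,
                                     cov = coverage_fraction(preds[[i]], truths[[j]]))
  }
  used_p <- logical(np); used_t <- logical(nt)
  if (length(hits)) {
    hm <- do.call(rbind, hits)
    hm <- hm[order(-hm[, "cov"]), , drop = FALSE]
    for (r in seq_len(nrow(hm))) {
      i <- hm[r, "i"]; j <- hm[r, "j"]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
      }
    }
  }
  tally_scores(tp = sum(used_t), fp = sum(!used_p), fn = sum(!used_t),
               matched = used_t)
}

#' Precision/recall/F1 from match counts
#'
#' @param tp,fp,fn counts.
#' @param matched optional per-truth logical vector carried through.
#' @return list with counts and `precision`, `recall`, `f1` (0-denominator
#'   conventions: 0).
#' @export
tally_scores <- function(tp, fp, fn, matched = NULL) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, matched = matched)
}

#' Write an evaluation result as a metrics TSV
#'
#' @param result from [score_circles()] or [tally_scores()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(result, path) {
  df <- data.frame(tp = result$tp, fp = result$fp, fn = result$fn,
                   precision = result$precision, recall = result$recall,
                   f1 = result$f1)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
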