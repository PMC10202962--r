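#' Pipeline configuration
#'
#' Central home of every tunable parameter with its documented default.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @details Defaults: `mapq_min = 10`, `insert_threshold = 1500` bp,
#'   `p_cut = 0.05`, `merge_dist = 12500` bp, `disc_score_cut = 1.301`
#'   (`-log10(0.05)`), `min_support = "auto"` (Poisson inverse survival of
#'   the discordant enrichment background, floored at 3), `e = 5` bp,
#'   `max_outputs = 1000`, `fold_min = 10`, `support_min = 3`,
#'   `max_repeat_frac = 0.05`, `intercontig_discordant = TRUE`,
#'   `disc_test_mode = "ratio"`, `blacklist = NULL`, `repeats = NULL`,
#'   `effective_length = NULL`, `seed = NULL`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(mapq_min = 10, insert_threshold = 1500, p_cut = 0.05,
              merge_dist = 12500, disc_score_cut = 1.301,
              min_support = "auto", e = 5, max_outputs = 1000,
              fold_min = 10, support_min = 3, max_repeat_frac = 0.05,
              intercontig_discordant = TRUE, disc_test_mode = "count",
              blacklist = NULL, repeats = NULL, effective_length = NULL,
              seed = NULL)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(!nzchar(names(over))))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$mapq_min >= 0, cfg$insert_threshold > 0,
            cfg$p_cut > 0, cfg$p_cut < 1, cfg$merge_dist >= 0,
            cfg$disc_score_cut > 0, cfg$e > 0, cfg$max_outputs >= 1,
            cfg$support_min >= 0, cfg$max_repeat_frac > 0)
  structure(cfg, class = "pipeline_config")
}

.log <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage, "] ", ...)
}

.echo_config <- function(cfg, path) {
  scalar <- cfg[!vapply(cfg, is.null, TRUE)]
  writeLines(paste0(names(scalar), " = ",
                    vapply(scalar, function(x) paste(format(x), collapse = ","), "")),
             path)
}

#' Run ecDNA detection end to end
#'
#' Stages: read filtering, classification, pileup, consecutive and
#' discordant enrichment calling, breakpoint-graph construction, Bayesian
#' breakpoint estimation, alternating-edge circle search, candidate
#' filtering, output. Per-stage record counts are logged. An input with no
#' enrichment yields an empty (but valid) output.
#'
#' @param bam_path coordinate-sorted, indexed BAM (or SAM, converted on the
#'   fly).
#' @param config a [pipeline_config()].
#' @param out_prefix if non-NULL, writes `<prefix>.bed`, `<prefix>.json`
#'   and `<prefix>.config.txt`.
#' @return invisibly, a list with `candidates`, `graph`, `consec`, `lambda`.
#' @export
run_detect <- function(bam_path, config = pipeline_config(),
                       out_prefix = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bam_path <- ensure_bam(bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  reads <- load_filtered_reads(bam_path, blacklist = config$blacklist,
                               mapq_min = config$mapq_min)
  .log("preprocess", nrow(reads), " reads pass filters")
  reads <- classify_reads(reads, config$insert_threshold,
                          config$intercontig_discordant)
  disc_reads <- reads[reads$is_discordant, , drop = FALSE]
  .log("classify", nrow(disc_reads), " discordant / ",
       sum(reads$is_clipped), " clipped")

  total_track <- pileup_track(reads, hdr)
  disc_track <- pileup_track(disc_reads, hdr)
  bl <- config$blacklist
  if (is.character(bl)) bl <- read_bed0(bl)
  lam <- track_lambda(total_track, blacklist = bl,
                      effective_length = config$effective_length)
  .log("enrich", "genome-wide lambda = ", signif(lam, 4))
  consec <- call_consecutive_regions(total_track, lam, config$p_cut,
                                     config$merge_dist)
  .log("enrich", nrow(consec), " consecutive regions")
  disc_reg <- call_discordant_regions(disc_track, total_track, disc_reads,
                                      score_cut = config$disc_score_cut,
                                      mode = config$disc_test_mode)
  disc_reg <- attach_to_consecutive(disc_reg, consec)
  .log("enrich", nrow(disc_reg), " discordant junction regions kept")

  graph <- breakpoint_graph(disc_reg, consec)
  min_support <- config$min_support
  if (identical(min_support, "auto")) {
    lam_r <- attr(disc_reg, "lambda_ratio")
    if (is.null(lam_r) || !length(lam_r) || is.na(lam_r) || lam_r <= 0)
      lam_r <- {
        cov_b <- sum(vapply(total_track, function(x)
          sum(as.numeric(S4Vectors::runLength(x)[S4Vectors::runValue(x) > 0])), 0))
        db <- sum(vapply(disc_track, function(x)
          sum(as.numeric(S4Vectors::runValue(x)) * S4Vectors::runLength(x)), 0))
        if (cov_b > 0 && db > 0) db / cov_b / max(1, lam) else NA
      }
    min_support <- if (is.na(lam_r)) 3L else min_support_default(lam_r)
  }
  .log("graph", "min discordant-edge support = ", min_support)
  graph <- add_discordant_edges(graph, disc_reads, min_support)
  graph <- apply_estimates(graph, reads, e = config$e,
                           insert_threshold = config$insert_threshold)
  graph <- add_consecutive_edges(graph, total_track, lam)
  # segments that already fail the reporting fold filter cannot appear in
  # any reported circle; pruning their edges up front keeps the search from
  # drowning in background-depth spans when merged consecutive regions grow
  # large (it never changes the filtered output)
  if (config$fold_min > 0) {
    keep <- graph$edges$type != "consecutive" |
      is.na(graph$edges$seg_fold) | graph$edges$seg_fold > config$fold_min
    graph$edges <- graph$edges[keep, , drop = FALSE]
  }
  .log("graph", nrow(graph$nodes), " nodes, ", nrow(graph$edges), " edges")

  cands <- find_circles(graph, max_outputs = config$max_outputs)
  .log("search", length(cands), " raw circle candidates")
  cands <- apply_filters(cands, fold_min = config$fold_min,
                         support_min = config$support_min,
                         repeats = config$repeats,
                         max_repeat_frac = config$max_repeat_frac)
  .log("filter", length(cands), " candidates pass filters")

  if (!is.null(out_prefix)) {
    write_circles(cands, paste0(out_prefix, ".bed"),
                  paste0(out_prefix, ".json"))
    .echo_config(config, paste0(out_prefix, ".config.txt"))
  }
  invisible(list(candidates = cands, graph = graph, consec = consec,
                 lambda = lam))
}

#' Simulate one benchmark sample (mock circles + background) to SAM
#'
#' @param ref a `synthetic_reference`.
#' @param n_circles circles in this sample.
#' @param sam_path output SAM path.
#' @param n_segments,total_size,min_segment,min_gap mock geometry (see
#'   [generate_mock_ecdna()]).
#' @param local_depth,read_len,genome_depth sequencing model.
#' @param with_seq emit sequences (needs reference sequence).
#' @param truth_json,truth_bed optional truth outputs.
#' @param id_prefix mock id prefix.
#' @return invisibly, list of the sample's `mock_ecdna` truths.
#' @export
run_simulate <- function(ref, n_circles, sam_path,
                         n_segments = c(1, 8), total_size = c(2e4, 2e5),
                         min_segment = 2500, min_gap = 50000,
                         local_depth = 30, read_len = 100, genome_depth = 2,
                         with_seq = FALSE, truth_json = NULL,
                         truth_bed = NULL, id_prefix = "mock") {
  mocks <- vector("list", n_circles)
  used <- NULL
  recs <- vector("list", n_circles + 1L)
  for (i in seq_len(n_circles)) {
    mk <- generate_mock_ecdna(ref, n_segments = n_segments,
                              total_size = total_size,
                              min_segment = min_segment, exclude = used,
                              min_gap = min_gap,
                              id = sprintf("%s%02d", id_prefix, i))
    used <- rbind(used, mk$segments[, c("contig", "start", "end")])
    pairs <- simulate_reads(mk, local_depth = local_depth,
                            read_len = read_len, prefix = mk$id)
    recs[[i]] <- perfect_align(pairs, mock = mk, ref = ref,
                               with_seq = with_seq)
    mocks[[i]] <- mk
  }
  bg <- simulate_background(ref, genome_depth = genome_depth,
                            read_len = read_len)
  recs[[n_circles + 1L]] <- perfect_align(bg, mock = NULL, ref = ref,
                                          with_seq = with_seq)
  write_sam(data.table::rbindlist(recs), ref$lengths, sam_path)
  write_truth(mocks, truth_json, truth_bed)
  invisible(mocks)
}

#' Evaluate predictions against truth
#'
#' @param preds candidate list or path to a detector JSON.
#' @param truths `mock_ecdna` list or path to a truth JSON.
#' @param criterion a [match_criterion()].
#' @param tsv_path optional metrics TSV output.
#' @return the [score_circles()] result.
#' @export
run_evaluate <- function(preds, truths, criterion = match_criterion(),
                         tsv_path = NULL) {
  if (is.character(preds)) preds <- read_circles_json(preds)
  if (is.character(truths)) truths <- read_truth_json(truths)
  res <- score_circles(preds, truths, criterion)
  if (!is.null(tsv_path)) write_metrics(res, tsv_path)
  res
}

# deterministic 31-bit sub-seed stream
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Run the full mock-ecDNA benchmark (simulate + detect + evaluate)
#'
#' Simulates `n_circles` seeded mock ecDNAs spread over samples of
#' `per_sample` circles each (so the circle-occupied fraction of the
#' desk-scale reference stays as sparse as circles drawn from a full-size
#' genome), runs detection at the supplied config, and pools per-sample
#' true/false positives into one F1.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param n_circles total mock circles (default 25).
#' @param per_sample circles per simulated sample (default 2).
#' @param read_len,local_depth,genome_depth sequencing model.
#' @param ref optional prebuilt reference (built from the seed otherwise).
#' @param config detection [pipeline_config()].
#' @param criterion a [match_criterion()].
#' @param work_dir scratch directory.
#' @param n_segments,total_size mock geometry.
#' @return list with pooled `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   and per-sample results.
#' @export
run_bench <- function(seed, n_circles = 25, per_sample = 2, read_len = 100,
                      local_depth = 30, genome_depth = 2, ref = NULL,
                      config = pipeline_config(),
                      criterion = match_criterion("coverage_structure"),
                      work_dir = tempdir(), n_segments = c(1, 8),
                      total_size = c(2e4, 2e5)) {
  if (is.null(ref)) {
    set.seed(.sub_seed(seed, 0))
    ref <- synthetic_reference(with_sequence = FALSE)
  }
  nonN <- non_n_intervals(ref)
  eff_len <- sum(nonN$end - nonN$start)
  config$effective_length <- eff_len
  sizes <- rep(per_sample, n_circles %/% per_sample)
  if (n_circles %% per_sample) sizes <- c(sizes, n_circles %% per_sample)
  tp <- fp <- fn <- 0
  per_sample_res <- vector("list", length(sizes))
  done <- 0L
  for (s in seq_along(sizes)) {
    set.seed(.sub_seed(seed, s))
    sam <- file.path(work_dir, sprintf("bench_s%02d_rl%d.sam", s, read_len))
    mocks <- run_simulate(ref, sizes[s], sam, n_segments = n_segments,
                          total_size = total_size, local_depth = local_depth,
                          read_len = read_len, genome_depth = genome_depth,
                          id_prefix = sprintf("s%02d_mock", s))
    det <- run_detect(sam, config = config)
    res <- score_circles(det$candidates, mocks, criterion)
    tp <- tp + res$tp; fp <- fp + res$fp; fn <- fn + res$fn
    per_sample_res[[s]] <- res
    done <- done + sizes[s]
    .log("bench", "sample ", s, "/", length(sizes), ": tp=", res$tp,
         " fp=", res$fp, " fn=", res$fn)
    unlink(c(sam, sub("\\.sam$", ".bam", sam),
             sub("\\.sam$", ".bam.bai", sam)))
  }
  out <- tally_scores(tp, fp, fn)
  out$per_sample <- per_sample_res
  out$n_circles <- done
  out
}
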