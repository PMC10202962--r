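#' Canonical key of a circle structure
#'
#' Two candidate circles describe the same ecDNA when one is a rotation of
#' the other or its reversal with every strand flipped. The key is the
#' lexicographic minimum over all rotations of both orientations of the
#' per-segment tuples, so it is invariant under exactly those symmetries.
#'
#' @param segments `data.frame` with `contig`, `start`, `end`, `strand`.
#' @return a single character key.
#' @export
canonical_structure <- function(segments) {
  fwd <- sprintf("%s:%d-%d:%s", segments$contig, as.integer(segments$start),
                 as.integer(segments$end), segments$strand)
  rev_str <- ifelse(rev(segments$strand) == "+", "-", "+")
  bwd <- sprintf("%s:%d-%d:%s", rev(segments$contig),
                 as.integer(rev(segments$start)), as.integer(rev(segments$end)),
                 rev_str)
  n <- length(fwd)
  rots <- character(0)
  for (k in seq_len(n)) {
    idx <- c(seq.int(k, n), if (k > 1) seq_len(k - 1))
    rots <- c(rots, paste(fwd[idx], collapse = "|"),
              paste(bwd[idx], collapse = "|"))
  }
  min(rots)
}

.assemble_candidate <- function(edge_ids, start, edges, nodes) {
  cur <- start
  walk <- vector("list", length(edge_ids))
  for (i in seq_along(edge_ids)) {
    e <- edges[edges$edge_id == edge_ids[i], ]
    fwd <- e$from == cur
    walk[[i]] <- list(e = e, fwd = fwd)
    cur <- if (fwd) e$to else e$from
  }
  types <- vapply(walk, function(x) x$e$type, "")
  k <- which(types == "consecutive")[1L]
  if (is.na(k)) return(NULL)
  if (k > 1) walk <- c(walk[seq.int(k, length(walk))], walk[seq_len(k - 1L)])
  n_seg <- length(walk) / 2L
  segs <- vector("list", n_seg)
  support <- integer(n_seg)
  nidx <- function(id) which(nodes$node_id == id)
  for (i in seq_len(n_seg)) {
    ce <- walk[[2L * i - 1L]]
    de <- walk[[2L * i]]
    e <- ce$e
    u <- nidx(e$from); v <- nidx(e$to)  # u = left-side node, v = right-side
    segs[[i]] <- data.frame(
      contig = nodes$contig[u], start = e$seg_start, end = e$seg_end,
      strand = if (ce$fwd) "+" else "-",
      mean_depth = e$seg_mean_depth, fold_enrichment = e$seg_fold,
      ci_start_low = nodes$ci_lo[u], ci_start_high = nodes$ci_hi[u],
      ci_end_low = nodes$ci_lo[v], ci_end_high = nodes$ci_hi[v],
      stringsAsFactors = FALSE)
    support[i] <- de$e$support
  }
  segments <- do.call(rbind, segs)
  list(segments = segments, junction_support = support,
       total_length = sum(segments$end - segments$start),
       key = canonical_structure(segments))
}

#' Enumerate candidate ecDNA circles by alternating-edge depth-first search
#'
#' A valid circle is a closed walk in the breakpoint graph that visits each
#' node at most once and strictly alternates the two edge types, so every
#' circle pairs one genomic segment (consecutive edge) with one junction
#' (discordant edge) per step. At every branch, candidate edges are tried
#' largest-segment-first, then highest-mean-depth (discordant branches by
#' support), so larger, better-covered structures are discovered first.
#' Duplicates under rotation/reflection are removed via
#' [canonical_structure()]; at most `max_outputs` candidates are returned in
#' discovery order.
#'
#' @param graph a `breakpoint_graph` with breakpoint estimates applied and
#'   consecutive edges added.
#' @param max_outputs output cap (default 1000).
#' @param max_raw safety cap on raw (pre-deduplication) cycle enumeration.
#' @return list of circle candidates, each a list with `circle_id`,
#'   `segments` (`data.frame`), `junction_support`, `total_length`.
#' @export
find_circles <- function(graph, max_outputs = 1000, max_raw = 50000) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (!nrow(nodes) || !nrow(edges)) return(list())
  edges$edge_id <- seq_len(nrow(edges))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  seg_len <- ifelse(edges$type == "consecutive",
                    edges$seg_end - edges$seg_start, 0)
  half <- function(node, other) data.frame(
    node = node, other = other, edge_id = edges$edge_id, type = edges$type,
    seg_len = seg_len, depth = ifelse(is.na(edges$seg_mean_depth), 0,
                                      edges$seg_mean_depth),
    support = ifelse(is.na(edges$support), 0, edges$support))
  adj_all <- rbind(half(edges$from, edges$to), half(edges$to, edges$from))
  # branch priority: segments by size then depth, junctions by support
  adj_all <- adj_all[order(adj_all$type != "consecutive", -adj_all$seg_len,
                           -adj_all$depth, -adj_all$support, adj_all$edge_id), ]
  adj <- split(adj_all, adj_all$node)

  st <- new.env(parent = emptyenv())
  st$raw <- list()
  st$n <- 0L

  dfs <- function(cur, start, visited, path, last_type, first_type) {
    if (st$n >= max_raw) return()
    a <- adj[[as.character(cur)]]
    if (is.null(a)) return()
    for (j in seq_len(nrow(a))) {
      if (st$n >= max_raw) return()
      etype <- a$type[j]
      if (!is.na(last_type) && etype == last_type) next
      nxt <- a$other[j]
      if (nxt == start) {
        if (length(path) >= 1L && etype != first_type) {
          st$n <- st$n + 1L
          st$raw[[st$n]] <- c(path, a$edge_id[j])
        }
        next
      }
      if (nxt < start || nxt %in% visited) next
      dfs(nxt, start, c(visited, nxt), c(path, a$edge_id[j]), etype,
          if (is.na(first_type)) etype else first_type)
    }
  }
  for (s in sort(nodes$node_id)) {
    dfs(s, s, s, integer(0), NA_character_, NA_character_)
  }
  if (!st$n) return(list())

  seen <- character(0)
  out <- list()
  for (i in seq_len(st$n)) {
    eids <- st$raw[[i]]
    # the start node of a recorded cycle is the minimum node id it visits
    ends <- edges[edges$edge_id %in% eids, c("from", "to")]
    start <- min(unlist(ends))
    cand <- .assemble_candidate(eids, start, edges, nodes)
    if (is.null(cand)) next
    if (cand$key %in% seen) next
    seen <- c(seen, cand$key)
    cand$circle_id <- sprintf("circle%d", length(out) + 1L)
    out[[length(out) + 1L]] <- cand
    if (length(out) >= max_outputs) break
  }
  out
}

#' Filter candidate circles for reporting
#'
#' Applies the candidate-quality filters: every segment's fold enrichment
#' must exceed `fold_min`, every junction must be supported by at least
#' `support_min` discordant read IDs (default 3, i.e. "more than 2"), and,
#' when repeat intervals are supplied, less than `max_repeat_frac` of the
#' circle's length may overlap them. Circles whose fold enrichment was
#' never annotated (all `NA`) are not fold-filtered.
#'
#' @param cands list of candidates from [find_circles()].
#' @param fold_min minimum per-segment fold enrichment (exclusive).
#' @param support_min minimum junction support (inclusive).
#' @param repeats optional repeat intervals (`data.frame` or BED path).
#' @param max_repeat_frac maximum tolerated repeat-overlap fraction.
#' @return the filtered candidate list.
#' @export
apply_filters <- function(cands, fold_min = 10, support_min = 3,
                          repeats = NULL, max_repeat_frac = 0.05) {
  if (is.character(repeats)) repeats <- read_bed0(repeats)
  keep <- vapply(cands, function(cand) {
    folds <- cand$segments$fold_enrichment
    if (!all(is.na(folds)) && min(folds, na.rm = TRUE) <= fold_min)
      return(FALSE)
    if (any(cand$junction_support < support_min)) return(FALSE)
    if (!is.null(repeats) && nrow(repeats)) {
      cols <- c("contig", "start", "end")
      ov <- GenomicRanges::intersect(
        GenomicRanges::reduce(as_granges0(cand$segments[, cols])),
        GenomicRanges::reduce(as_granges0(repeats[, cols])))
      frac <- sum(GenomicRanges::width(ov)) / cand$total_length
      if (frac >= max_repeat_frac) return(FALSE)
    }
    TRUE
  }, TRUE)
  cands[keep]
}

#' Write candidate circles as BED (one row per segment) and optional JSON
#'
#' BED dialect (tab-separated, 0-based half-open):
#' `chrom, start, end, name=circleID_segIndex_of_N, score=junction support
#' (capped 1000), strand, ci_start_low, ci_start_high, ci_end_low,
#' ci_end_high`.
#'
#' @param cands list of candidates.
#' @param bed_path output BED path.
#' @param json_path optional companion JSON with full records.
#' @return `bed_path`, invisibly.
#' @export
write_circles <- function(cands, bed_path, json_path = NULL) {
  header <- paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                   "ci_start_low\tci_start_high\tci_end_low\tci_end_high")
  rows <- character(0)
  for (cand in cands) {
    seg <- cand$segments
    n <- nrow(seg)
    rows <- c(rows, sprintf(
      "%s\t%d\t%d\t%s_%d_of_%d\t%d\t%s\t%d\t%d\t%d\t%d",
      seg$contig, as.integer(seg$start), as.integer(seg$end),
      cand$circle_id, seq_len(n), n,
      pmin(cand$junction_support, 1000L), seg$strand,
      as.integer(seg$ci_start_low), as.integer(seg$ci_start_high),
      as.integer(seg$ci_end_low), as.integer(seg$ci_end_high)))
  }
  writeLines(c(header, rows), bed_path)
  if (!is.null(json_path)) {
    recs <- lapply(cands, function(cand) list(
      circle_id = cand$circle_id, total_length = cand$total_length,
      junction_support = cand$junction_support, segments = cand$segments))
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(bed_path)
}

#' Read candidate circles back from the companion JSON
#'
#' @param json_path path written by [write_circles()].
#' @return list of candidates in the same shape [find_circles()] returns.
#' @export
read_circles_json <- function(json_path) {
  recs <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  if (!length(recs)) return(list())
  lapply(seq_len(nrow(recs)), function(i) {
    seg <- recs$segments[[i]]
    list(circle_id = recs$circle_id[i],
         segments = seg,
         junction_support = unlist(recs$junction_support[i]),
         total_length = recs$total_length[i],
         key = canonical_structure(seg))
  })
}
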