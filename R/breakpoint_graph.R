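#' Build a breakpoint multigraph from discordant junction regions
#'
#' Nodes are discordant-pair enrichment regions; two edge types connect
#' them: `discordant` edges (node pairs sharing paired-end read IDs with a
#' consistent orientation signature) and `consecutive` edges (the genomic
#' segment between a left-junction node and a downstream right-junction node
#' inside the same consecutive enrichment region). Node IDs are assigned in
#' coordinate order so construction is deterministic.
#'
#' @param disc `data.frame` of discordant regions with `host` column (from
#'   [attach_to_consecutive()]).
#' @param consec `data.frame` of consecutive regions.
#' @return a `breakpoint_graph` object: `list(nodes, edges, consec)`.
#' @export
breakpoint_graph <- function(disc, consec) {
  nodes <- disc[order(disc$contig, disc$start, disc$side), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$node_id <- seq_len(nrow(nodes))
  # origin: innermost base of the region, facing the segment interior
  nodes$origin <- ifelse(nodes$side == "right", nodes$start, nodes$end)
  nodes$breakpoint <- rep(NA_real_, nrow(nodes))
  nodes$ci_lo <- rep(NA_real_, nrow(nodes))
  nodes$ci_hi <- rep(NA_real_, nrow(nodes))
  edges <- data.frame(from = integer(), to = integer(), type = character(),
                      support = integer(), read_ids = I(list()),
                      side_from = character(), side_to = character(),
                      seg_start = numeric(), seg_end = numeric(),
                      seg_mean_depth = numeric(), seg_fold = numeric())
  structure(list(nodes = nodes, edges = edges, consec = consec),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("breakpoint_graph:", nrow(x$nodes), "nodes,",
      sum(x$edges$type == "discordant"), "discordant +",
      sum(x$edges$type == "consecutive"), "consecutive edges\n")
  invisible(x)
}

#' Default minimum read support for a discordant edge
#'
#' The smallest count that is Poisson-significant against the discordant
#' background rate, floored at 3 for consistency with the downstream
#' "more than 2 reads per junction" candidate filter.
#'
#' @param lam_disc background rate of the discordant enrichment model (the
#'   genome-wide mean discordant/total ratio; see the methods vignette).
#' @param alpha significance level (default 0.05).
#' @param floor lower bound on the result (default 3).
#' @return integer minimum support.
#' @export
min_support_default <- function(lam_disc, alpha = 0.05, floor = 3) {
  if (lam_disc <= 0) stop("lambda must be positive")
  k <- poisson_min_signif_count(lam_disc, alpha)
  max(floor, k)
}

# map read records to region keys; returns per read-id the set of distinct
# region intervals it touches
.map_reads_to_regions <- function(nodes, disc_reads) {
  key <- paste0(nodes$contig, ":", nodes$start, "-", nodes$end)
  ukey <- unique(key)
  regions <- nodes[!duplicated(key), c("contig", "start", "end"), drop = FALSE]
  hits <- GenomicRanges::findOverlaps(as_granges0(disc_reads),
                                      as_granges0(regions))
  data.frame(read_row = S4Vectors::queryHits(hits),
             region = ukey[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Add discordant edges from shared read pairs
#'
#' For every pair of junction regions sharing at least `min_support` read
#' IDs whose mates carry the majority orientation signature, one discordant
#' edge is added carrying that support set. Read IDs touching more than two
#' regions are ambiguous and excluded.
#'
#' @param graph a `breakpoint_graph`.
#' @param disc_reads `data.frame` of classified discordant reads.
#' @param min_support minimum shared read IDs (see [min_support_default()]).
#' @return the graph with discordant edges added.
#' @export
add_discordant_edges <- function(graph, disc_reads, min_support = 3) {
  nodes <- graph$nodes
  if (!nrow(nodes) || !nrow(disc_reads)) return(graph)
  m <- .map_reads_to_regions(nodes, disc_reads)
  if (!nrow(m)) return(graph)
  m$read_id <- disc_reads$read_id[m$read_row]
  m$strand <- disc_reads$strand[m$read_row]
  # distinct regions per read id; ambiguous ids (>2 regions) are excluded
  per_id <- split(m, m$read_id)
  per_id <- per_id[vapply(per_id, function(d) length(unique(d$region)) == 2, TRUE)]
  if (!length(per_id)) return(graph)

  node_key <- paste0(nodes$contig, ":", nodes$start, "-", nodes$end)
  pick_node <- function(region, side) {
    cand <- which(node_key == region)
    hit <- cand[nodes$side[cand] == side]
    if (length(hit)) hit[1L] else cand[1L]
  }

  links <- lapply(per_id, function(d) {
    regs <- sort(unique(d$region))
    sA <- unique(d$strand[d$region == regs[1]])
    sB <- unique(d$strand[d$region == regs[2]])
    if (length(sA) != 1 || length(sB) != 1) return(NULL)  # inconsistent mates
    data.frame(read_id = d$read_id[1], A = regs[1], B = regs[2],
               sig = paste0(sA, sB), stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, links[!vapply(links, is.null, TRUE)])
  if (is.null(links) || !nrow(links)) return(graph)

  new_edges <- list()
  for (pair in split(links, paste(links$A, links$B))) {
    tab <- sort(table(pair$sig), decreasing = TRUE)
    sig <- names(tab)[1L]  # majority orientation signature (ties: table order)
    sup <- pair$read_id[pair$sig == sig]
    if (length(sup) < min_support) next
    sides <- ifelse(strsplit(sig, "")[[1]] == "+", "right", "left")
    from <- pick_node(pair$A[1], sides[1])
    to <- pick_node(pair$B[1], sides[2])
    new_edges[[length(new_edges) + 1L]] <- data.frame(
      from = nodes$node_id[from], to = nodes$node_id[to], type = "discordant",
      support = length(sup), read_ids = I(list(sort(sup))),
      side_from = sides[1], side_to = sides[2],
      seg_start = NA_real_, seg_end = NA_real_,
      seg_mean_depth = NA_real_, seg_fold = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(new_edges)) {
    ne <- do.call(rbind, new_edges)
    # one discordant edge per node pair: merge supports
    pair_key <- paste(pmin(ne$from, ne$to), pmax(ne$from, ne$to))
    keep <- !duplicated(pair_key)
    for (k in unique(pair_key[duplicated(pair_key)])) {
      rows <- which(pair_key == k)
      ids <- sort(unique(unlist(ne$read_ids[rows])))
      ne$read_ids[[rows[1]]] <- ids
      ne$support[rows[1]] <- length(ids)
    }
    graph$edges <- rbind(graph$edges, ne[keep, , drop = FALSE])
  }
  graph
}

#' Add consecutive (segment) edges within consecutive regions
#'
#' Inside each consecutive enrichment region, every left-junction node is
#' connected to every downstream right-junction node; the edge carries the
#' spanned genomic segment (between the two breakpoint estimates when
#' available, otherwise between the region origins) plus its mean depth and
#' fold enrichment when a depth track is supplied. Same-side nodes are
#' never connected.
#'
#' @param graph a `breakpoint_graph`.
#' @param total_track optional all-read depth `RleList` to annotate segment
#'   depth.
#' @param lam optional genome-wide mean depth for fold enrichment.
#' @return the graph with consecutive edges added.
#' @export
add_consecutive_edges <- function(graph, total_track = NULL, lam = NULL) {
  nodes <- graph$nodes
  if (!nrow(nodes)) return(graph)
  bp <- ifelse(is.na(nodes$breakpoint), nodes$origin, nodes$breakpoint)
  new_edges <- list()
  for (h in unique(nodes$host)) {
    idx <- which(nodes$host == h)
    lefts <- idx[nodes$side[idx] == "left"]
    rights <- idx[nodes$side[idx] == "right"]
    for (u in lefts) for (v in rights) {
      if (!(nodes$end[u] <= nodes$start[v])) next  # u must precede v
      s <- bp[u]; e <- bp[v]
      if (e <= s) next
      md <- NA_real_
      if (!is.null(total_track)) {
        rl <- total_track[[nodes$contig[u]]]
        md <- mean(S4Vectors::window(rl, start = s + 1, end = e))
      }
      new_edges[[length(new_edges) + 1L]] <- data.frame(
        from = nodes$node_id[u], to = nodes$node_id[v], type = "consecutive",
        support = NA_integer_, read_ids = I(list(character())),
        side_from = "left", side_to = "right",
        seg_start = s, seg_end = e, seg_mean_depth = md,
        seg_fold = if (!is.null(lam)) md / lam else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(new_edges))
    graph$edges <- rbind(graph$edges, do.call(rbind, new_edges))
  graph
}

#' Export a breakpoint graph as a plain edge-list text file
#'
#' @param graph a `breakpoint_graph`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_graph <- function(graph, path) {
  n <- graph$nodes
  e <- graph$edges
  lines <- c("#nodes: id contig start end side origin breakpoint",
             sprintf("N\t%d\t%s\t%d\t%d\t%s\t%d\t%s", n$node_id, n$contig,
                     as.integer(n$start), as.integer(n$end), n$side,
                     as.integer(n$origin),
                     ifelse(is.na(n$breakpoint), ".",
                            as.character(as.integer(n$breakpoint)))),
             "#edges: from to type support",
             sprintf("E\t%d\t%d\t%s\t%s", e$from, e$to, e$type,
                     ifelse(is.na(e$support), ".", as.character(e$support))))
  writeLines(lines, path)
  invisible(path)
}
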