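# Fixture builders. SAM fixtures are assembled as raw text, independently of
# the package's own SAM writer, so reader tests do not lean on the code they
# check.

sam_header <- function(contig_lengths) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths)))
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar,
                     rnext = "*", pnext = 0, tlen = 0, seq = "*", qual = "*") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
          qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen, seq, qual)
}

write_sam_fixture <- function(lines, contig_lengths, dir = tempdir()) {
  path <- tempfile("fixture", tmpdir = dir, fileext = ".sam")
  writeLines(c(sam_header(contig_lengths), lines), path)
  path
}

# a minimal classified-read data.frame for graph-level tests
fake_reads <- function(read_id, contig, start, end, strand,
                       is_discordant = TRUE, clip_left = 0, clip_right = 0) {
  n <- length(read_id)
  data.frame(read_id = read_id, contig = contig, start = start, end = end,
             strand = strand, is_discordant = rep_len(is_discordant, n),
             clip_left = rep_len(clip_left, n),
             clip_right = rep_len(clip_right, n),
             is_clipped = rep_len((clip_left + clip_right) > 0, n),
             stringsAsFactors = FALSE)
}

# node (discordant-region) table in the shape attach_to_consecutive emits
fake_nodes <- function(contig, start, end, side, host, read_ids) {
  data.frame(contig = contig, start = start, end = end, side = side,
             n_fwd = NA_integer_, n_rev = NA_integer_,
             read_ids = I(read_ids), host = host, stringsAsFactors = FALSE)
}

# a hand-built breakpoint graph for circle-search tests; edges as
# (from, to, type, support, seg_start, seg_end, seg_mean_depth)
fake_graph <- function(n_nodes, edges, contig = "chrT") {
  nodes <- data.frame(
    contig = contig, start = seq_len(n_nodes) * 1000,
    end = seq_len(n_nodes) * 1000 + 100,
    side = rep(c("left", "right"), length.out = n_nodes),
    n_fwd = 0L, n_rev = 0L, read_ids = I(rep(list(character()), n_nodes)),
    host = 1L, node_id = seq_len(n_nodes),
    origin = seq_len(n_nodes) * 1000,
    breakpoint = seq_len(n_nodes) * 1000,
    ci_lo = seq_len(n_nodes) * 1000 - 5, ci_hi = seq_len(n_nodes) * 1000 + 5,
    stringsAsFactors = FALSE)
  ed <- do.call(rbind, lapply(edges, function(e) data.frame(
    from = e$from, to = e$to, type = e$type,
    support = if (is.null(e$support)) NA_integer_ else e$support,
    read_ids = I(list(character())),
    side_from = "left", side_to = "right",
    seg_start = if (is.null(e$seg_start)) NA_real_ else e$seg_start,
    seg_end = if (is.null(e$seg_end)) NA_real_ else e$seg_end,
    seg_mean_depth = if (is.null(e$depth)) NA_real_ else e$depth,
    seg_fold = NA_real_, stringsAsFactors = FALSE)))
  consec <- data.frame(contig = contig, start = 0,
                       end = (n_nodes + 1) * 1000 + 100,
                       mean_depth = NA_real_, fold_enrichment = NA_real_)
  structure(list(nodes = nodes, edges = ed, consec = consec),
            class = "breakpoint_graph")
}

# convenience: one consecutive + one discordant edge between u (left) and
# v (right), i.e. a single-segment circle
seg_edge <- function(u, v, s, e, depth = 30) {
  list(from = u, to = v, type = "consecutive", seg_start = s, seg_end = e,
       depth = depth)
}
disc_edge <- function(u, v, support = 10) {
  list(from = u, to = v, type = "discordant", support = support)
}

# independent brute-force oracle: all alternation-valid simple cycles of a
# fake graph, as a sorted set of canonical structure keys. Enumerates node
# sequences by extension (connectivity only), then checks the two possible
# alternating type assignments.
oracle_alt_cycles <- function(graph) {
  edges <- graph$edges
  nodes <- graph$nodes
  n <- nrow(nodes)
  ids <- nodes$node_id
  edge_row <- function(a, b, type) {
    rows <- which(((edges$from == a & edges$to == b) |
                     (edges$from == b & edges$to == a)) & edges$type == type)
    if (length(rows)) rows[1] else NA_integer_
  }
  connected <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  keys <- character(0)
  grow <- function(path) {
    k <- length(path)
    if (k >= 2 && k %% 2 == 0 && connected(path[k], path[1])) {
      for (pat in list(rep(c("consecutive", "discordant"), k / 2),
                       rep(c("discordant", "consecutive"), k / 2))) {
        rows <- integer(k)
        ok <- TRUE
        for (i in seq_len(k)) {
          a <- path[i]; b <- path[if (i == k) 1 else i + 1]
          r <- edge_row(a, b, pat[i])
          if (is.na(r)) { ok <- FALSE; break }
          rows[i] <- r
        }
        if (!ok) next
        # build segments in walk order starting at the first consecutive edge
        first_c <- which(pat == "consecutive")[1]
        rot_path <- path[c(seq.int(first_c, k), if (first_c > 1) seq_len(first_c - 1))]
        rot_rows <- rows[c(seq.int(first_c, k), if (first_c > 1) seq_len(first_c - 1))]
        seg_list <- list()
        for (i in seq(1, k, by = 2)) {
          e <- edges[rot_rows[i], ]
          a <- rot_path[i]
          seg_list[[length(seg_list) + 1L]] <- data.frame(
            contig = nodes$contig[nodes$node_id == e$from],
            start = e$seg_start, end = e$seg_end,
            strand = if (e$from == a) "+" else "-",
            stringsAsFactors = FALSE)
        }
        keys <<- c(keys, canonical_structure(do.call(rbind, seg_list)))
      }
    }
    if (k >= 10) return()
    for (nx in ids) {
      if (nx %in% path) next
      if (nx < path[1]) next  # anchor cycles at their minimum node
      if (!connected(path[k], nx)) next
      grow(c(path, nx))
    }
  }
  for (s in ids) grow(s)
  sort(unique(keys))
}

# random fake graph for the oracle-equivalence property
random_fake_graph <- function(n_nodes, p_cons = 0.3, p_disc = 0.3) {
  edges <- list()
  for (u in seq_len(n_nodes - 1)) for (v in seq.int(u + 1, n_nodes)) {
    if (runif(1) < p_cons)
      edges[[length(edges) + 1L]] <- seg_edge(u, v, u * 1000, v * 1000,
                                              depth = runif(1, 5, 50))
    if (runif(1) < p_disc)
      edges[[length(edges) + 1L]] <- disc_edge(u, v, sample(3:20, 1))
  }
  if (!length(edges)) edges <- list(seg_edge(1, 2, 1000, 2000))
  fake_graph(n_nodes, edges)
}
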