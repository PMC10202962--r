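#' Unnormalized log posterior of a breakpoint offset
#'
#' Combines two independent evidence models for the distance `h` (bp)
#' between the region origin and the true breakpoint:
#' * discordant reads stop short of the breakpoint, so their end offsets
#'   `L` are uniform on `[1, h]` (the German tank problem): any `L > h`
#'   gives probability 0, otherwise each read contributes `-log(h)`;
#' * clipped reads end at the breakpoint within tolerance `e`, so their
#'   clip offsets `S` are normal with mean `h` and standard deviation `e`.
#' The additive normalizing constant of the posterior is never computed; it
#' cancels in the grid normalization of [estimate_breakpoint()].
#'
#' @param h candidate offset(s), >= 1; vectorized.
#' @param L numeric vector of discordant read end offsets (>= 1).
#' @param S numeric vector of clipped read end offsets.
#' @param e clip position tolerance (bp), > 0.
#' @return unnormalized log posterior per `h` (`-Inf` where any `L > h`).
#' @export
log_posterior <- function(h, L = numeric(), S = numeric(), e = 5) {
  n <- length(L); m <- length(S)
  if (n + m == 0) stop("no evidence: both L and S are empty")
  if (e <= 0) stop("e must be positive")
  lp <- -n * log(h)
  if (m > 0)
    lp <- lp - m * log(e * sqrt(2 * pi)) -
      (m * h^2 - 2 * h * sum(S) + sum(S^2)) / (2 * e^2)
  if (n > 0) lp[h < max(L)] <- -Inf
  lp
}

#' Grid-search breakpoint estimate with 95% credible interval
#'
#' Evaluates [log_posterior()] on an integer grid from `max(1, max(L))` to
#' `grid_max`, normalizes, and returns the maximum-likelihood offset
#' (smallest `h` on exact ties) plus the central 95% credible interval
#' (cumulative posterior crossing 0.025 and 0.975).
#'
#' @param L,S,e evidence as in [log_posterior()].
#' @param grid_max upper bound of the grid; defaults to
#'   `max(L) + insert_threshold` when discordant evidence exists, else
#'   `max(S) + 6 e`.
#' @param insert_threshold used only for the default `grid_max`.
#' @return list with `h_hat`, `ci_low`, `ci_high`, `grid`, `log_posterior`,
#'   `posterior` (normalized).
#' @export
estimate_breakpoint <- function(L = numeric(), S = numeric(), e = 5,
                                grid_max = NULL, insert_threshold = 1500) {
  n <- length(L); m <- length(S)
  if (n + m == 0) stop("no evidence: both L and S are empty")
  h_min <- max(1, if (n) max(L) else 1)
  if (is.null(grid_max))
    grid_max <- if (n) max(L) + insert_threshold else max(S) + 6 * e
  grid_max <- max(ceiling(grid_max), h_min)
  grid <- seq.int(h_min, grid_max)
  if (!length(grid)) stop("empty grid")
  lp <- log_posterior(grid, L, S, e)
  w <- exp(lp - max(lp))
  post <- w / sum(w)
  cum <- cumsum(post)
  list(h_hat = grid[which.max(lp)],
       ci_low = grid[which(cum >= 0.025)[1L]],
       ci_high = grid[which(cum >= 0.975)[1L]],
       grid = grid, log_posterior = lp, posterior = post)
}

# collect L/S evidence for one node from pre-subset discordant/clipped
# reads; origin/side semantics:
#   right-side junction: offsets measured rightwards from the region start
#   left-side junction: offsets measured leftwards from the region end
.node_evidence <- function(node, disc, clip, insert_threshold) {
  origin <- node$origin
  if (node$side == "right") {
    sel <- disc$contig == node$contig & disc$strand == "+" &
      disc$end > node$start & disc$start < node$end
    L <- disc$end[sel] - origin
    cs <- clip$contig == node$contig & clip$clip_right > 0 &
      clip$end > origin & clip$end <= origin + insert_threshold
    S <- clip$end[cs] - origin
  } else {
    sel <- disc$contig == node$contig & disc$strand == "-" &
      disc$end > node$start & disc$start < node$end
    L <- origin - disc$start[sel]
    cs <- clip$contig == node$contig & clip$clip_left > 0 &
      clip$start < origin & clip$start >= origin - insert_threshold
    S <- origin - clip$start[cs]
  }
  list(L = L[L >= 1], S = S[S >= 1])
}

#' Estimate and attach breakpoints to every graph node
#'
#' For each junction node the evidence offsets are collected from the
#' supporting discordant reads (uniform-maximum model) and from reads
#' clipped on the junction side (normal model), and the grid posterior is
#' maximized. The grid is capped at the host consecutive-region boundary so
#' a breakpoint cannot escape its region's context. The absolute breakpoint
#' is `origin + h` for a right-side junction and `origin - h` for a
#' left-side one. Nodes without usable evidence are dropped with a warning.
#'
#' @param graph a `breakpoint_graph`.
#' @param reads classified reads `data.frame` (discordant + clipped).
#' @param e clip tolerance in bp (default 5).
#' @param insert_threshold default grid extent beyond `max(L)`.
#' @return the graph with `breakpoint`, `ci_lo`, `ci_hi` filled on nodes.
#' @export
apply_estimates <- function(graph, reads, e = 5, insert_threshold = 1500) {
  nodes <- graph$nodes
  drop <- logical(nrow(nodes))
  disc <- reads[reads$is_discordant,
                c("contig", "start", "end", "strand"), drop = FALSE]
  clip <- reads[reads$clip_left > 0 | reads$clip_right > 0,
                c("contig", "start", "end", "clip_left", "clip_right"),
                drop = FALSE]
  for (i in seq_len(nrow(nodes))) {
    node <- nodes[i, ]
    ev <- .node_evidence(node, disc, clip, insert_threshold)
    if (length(ev$L) + length(ev$S) == 0) {
      warning("node ", node$node_id, " (", node$contig, ":", node$start, "-",
              node$end, ") has no usable breakpoint evidence; dropped")
      drop[i] <- TRUE
      next
    }
    host <- graph$consec[node$host, ]
    cap <- if (node$side == "right") host$end - node$origin
           else node$origin - host$start
    gmax <- if (length(ev$L)) max(ev$L) + insert_threshold else max(ev$S) + 6 * e
    gmax <- min(gmax, max(cap, 1))
    est <- estimate_breakpoint(ev$L, ev$S, e = e, grid_max = gmax,
                               insert_threshold = insert_threshold)
    if (node$side == "right") {
      nodes$breakpoint[i] <- node$origin + est$h_hat
      nodes$ci_lo[i] <- node$origin + est$ci_low
      nodes$ci_hi[i] <- node$origin + est$ci_high
    } else {
      nodes$breakpoint[i] <- node$origin - est$h_hat
      nodes$ci_lo[i] <- node$origin - est$ci_high
      nodes$ci_hi[i] <- node$origin - est$ci_low
    }
  }
  graph$nodes <- nodes
  if (any(drop)) {
    kept <- graph$nodes$node_id[!drop]
    graph$nodes <- graph$nodes[!drop, , drop = FALSE]
    graph$edges <- graph$edges[graph$edges$from %in% kept &
                                 graph$edges$to %in% kept, , drop = FALSE]
  }
  graph
}
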