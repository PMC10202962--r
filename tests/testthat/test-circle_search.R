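test_that("canonical keys are invariant under rotation and reflection", {
  segs <- data.frame(contig = c("c1", "c1", "c2"),
                     start = c(100, 5000, 200), end = c(1100, 6000, 900),
                     strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  rot <- segs[c(2, 3, 1), ]
  expect_equal(canonical_structure(rot), canonical_structure(segs))
  refl <- segs[3:1, ]
  refl$strand <- ifelse(refl$strand == "+", "-", "+")
  expect_equal(canonical_structure(refl), canonical_structure(segs))
  # swapping two non-adjacent segments of a 4-circle changes the structure:
  # check against explicit enumeration of all 8 symmetries
  s4 <- data.frame(contig = "c1", start = c(1, 2, 3, 4) * 1000,
                   end = c(1, 2, 3, 4) * 1000 + 500,
                   strand = c("+", "+", "+", "+"), stringsAsFactors = FALSE)
  swapped <- s4[c(3, 2, 1, 4), ]
  syms <- list()
  for (k in 0:3) {
    idx <- ((seq_len(4) + k - 1) %% 4) + 1
    syms[[length(syms) + 1]] <- s4[idx, ]
    r <- s4[rev(idx), ]
    r$strand <- ifelse(r$strand == "+", "-", "+")
    syms[[length(syms) + 1]] <- r
  }
  expect_false(any(vapply(syms, function(x)
    identical(canonical_structure(x), canonical_structure(swapped)), TRUE)))
})

test_that("a single segment with head-to-tail junction forms one circle", {
  g <- fake_graph(2, list(seg_edge(1, 2, 1000, 41000, depth = 30),
                          disc_edge(1, 2, support = 12)))
  circles <- find_circles(g)
  expect_length(circles, 1)
  expect_equal(nrow(circles[[1]]$segments), 1)
  expect_equal(circles[[1]]$total_length, 40000)
  expect_equal(circles[[1]]$junction_support, 12)
})

test_that("two segments joined by two junctions form exactly one circle", {
  g <- fake_graph(4, list(seg_edge(1, 2, 1000, 2000), seg_edge(3, 4, 3000, 4000),
                          disc_edge(2, 3), disc_edge(4, 1)))
  circles <- find_circles(g)
  expect_length(circles, 1)
  expect_equal(nrow(circles[[1]]$segments), 2)
  expect_equal(oracle_alt_cycles(g), sort(circles[[1]]$key))
})

test_that("an open alternating path yields no circle", {
  g <- fake_graph(4, list(seg_edge(1, 2, 1000, 2000), disc_edge(2, 3),
                          seg_edge(3, 4, 3000, 4000)))
  expect_length(find_circles(g), 0)
})

test_that("edge types must alternate: two consecutive edges never chain", {
  # 1-2 consecutive, 2-3 consecutive, 3-1 discordant: no valid circle
  g <- fake_graph(3, list(seg_edge(1, 2, 1000, 2000), seg_edge(2, 3, 2100, 3000),
                          disc_edge(3, 1)))
  expect_length(find_circles(g), 0)
  # and every emitted circle alternates structurally
  g2 <- fake_graph(4, list(seg_edge(1, 2, 1000, 2000), seg_edge(3, 4, 3000, 4000),
                           seg_edge(1, 4, 1000, 4000),
                           disc_edge(2, 3), disc_edge(4, 1), disc_edge(1, 3)))
  for (cand in find_circles(g2)) {
    expect_equal(length(cand$junction_support), nrow(cand$segments))
  }
})

test_that("search equals exhaustive alternation-valid cycle enumeration", {
  set.seed(97)
  for (i in 1:30) {
    g <- random_fake_graph(sample(2:8, 1))
    got <- sort(vapply(find_circles(g, max_outputs = 10000), `[[`, "", "key"))
    expect_equal(got, oracle_alt_cycles(g))
  }
})

test_that("output is capped, deterministic, and priority-ordered", {
  set.seed(13)
  g <- random_fake_graph(8, p_cons = 0.6, p_disc = 0.6)
  all_c <- find_circles(g, max_outputs = 10000)
  capped <- find_circles(g, max_outputs = 3)
  expect_true(length(all_c) > 3)
  expect_length(capped, 3)
  # truncation preserves the discovery (priority) order
  expect_equal(vapply(capped, `[[`, "", "key"),
               vapply(all_c[1:3], `[[`, "", "key"))
  # determinism
  again <- find_circles(g, max_outputs = 10000)
  expect_equal(vapply(again, `[[`, "", "key"),
               vapply(all_c, `[[`, "", "key"))
})

make_cand <- function(fold = c(15, 15), support = c(5, 5)) {
  segs <- data.frame(contig = "c1", start = c(1000, 9000),
                     end = c(5000, 12000), strand = c("+", "+"),
                     mean_depth = fold * 2, fold_enrichment = fold,
                     ci_start_low = c(995, 8995), ci_start_high = c(1005, 9005),
                     ci_end_low = c(4995, 11995), ci_end_high = c(5005, 12005),
                     stringsAsFactors = FALSE)
  list(circle_id = "c", segments = segs, junction_support = support,
       total_length = 7000, key = canonical_structure(segs))
}

test_that("candidate filters enforce fold, support and repeat thresholds", {
  ok <- make_cand()
  low_support <- make_cand(support = c(5, 2))
  boundary <- make_cand(support = c(3, 3))
  low_fold <- make_cand(fold = c(15, 9))
  expect_length(apply_filters(list(ok, low_support, low_fold)), 1)
  # support exactly 3 passes (">2"), 2 never does
  expect_length(apply_filters(list(boundary)), 1)
  expect_length(apply_filters(list(low_support)), 0)
  # 6% repeat overlap is dropped, 4% is kept
  rep6 <- genomic_intervals("c1", 1000, 1000 + 0.06 * 7000)
  rep4 <- genomic_intervals("c1", 1000, 1000 + 0.04 * 7000)
  expect_length(apply_filters(list(ok), repeats = rep6), 0)
  expect_length(apply_filters(list(ok), repeats = rep4), 1)
})

test_that("tightening any filter never grows the output", {
  set.seed(5)
  cands <- list(make_cand(fold = c(12, 20), support = c(3, 8)),
                make_cand(fold = c(25, 30), support = c(10, 4)),
                make_cand(fold = c(9, 40), support = c(6, 6)))
  base <- length(apply_filters(cands))
  expect_lte(length(apply_filters(cands, fold_min = 15)), base)
  expect_lte(length(apply_filters(cands, support_min = 5)), base)
})

test_that("BED/JSON round trip preserves circle structure", {
  cands <- list(make_cand())
  bed <- tempfile(fileext = ".bed")
  js <- tempfile(fileext = ".json")
  write_circles(cands, bed, js)
  txt <- readLines(bed)
  expect_match(txt[1], "^#chrom")
  expect_length(txt, 3)  # header + 2 segments
  expect_match(txt[2], "c_1_of_2")
  back <- read_circles_json(js)
  expect_length(back, 1)
  expect_equal(back[[1]]$key, cands[[1]]$key)
  expect_equal(back[[1]]$junction_support, cands[[1]]$junction_support)
})
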