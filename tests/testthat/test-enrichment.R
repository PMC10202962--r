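# independent oracle for the Poisson upper tail at integer counts
series_sf <- function(count, lam) {
  if (count <= 0) return(1)
  1 - sum(exp(-lam) * lam^(0:(count - 1)) / factorial(0:(count - 1)))
}

rle_track <- function(values, contig = "c1") {
  setNames(IRanges::RleList(S4Vectors::Rle(values)), contig)
}

test_that("poisson_sf matches closed forms and the finite series", {
  expect_equal(poisson_sf(0, 5), 1.0)
  expect_equal(poisson_sf(4, 1), 1 - exp(-1) * (1 + 1 + 1 / 2 + 1 / 6),
               tolerance = 1e-12)
  expect_equal(signif(poisson_sf(4, 1), 6), 0.0189882)
  expect_equal(poisson_sf(1, 2), 1 - exp(-2), tolerance = 1e-12)
  expect_equal(signif(poisson_sf(1, 2), 7), 0.8646647)
  expect_error(poisson_sf(1, 0), "positive")
  for (lam in c(0.1, 1, 3.7, 12)) {
    err <- vapply(0:50, function(k) abs(poisson_sf(k, lam) - series_sf(k, lam)),
                  0)
    expect_lt(max(err), 1e-12)
  }
})

test_that("pileup matches direct interval arithmetic and conserves bases", {
  reads <- data.frame(read_id = c("a", "b"), contig = "c1",
                      start = c(10, 15), end = c(20, 25))
  tr <- pileup_track(reads, c(c1 = 100))
  v <- as.integer(tr[["c1"]])
  expect_equal(v[11:15], rep(1L, 5))   # [10,15) only read a
  expect_equal(v[16:20], rep(2L, 5))   # [15,20) overlap
  expect_equal(v[21:25], rep(1L, 5))
  expect_equal(sum(v), 20)
  set.seed(7)
  n <- 1000
  s <- sample(0:9000, n, replace = TRUE)
  w <- sample(30:150, n, replace = TRUE)
  rnd <- data.frame(read_id = as.character(seq_len(n)), contig = "c1",
                    start = s, end = s + w)
  tr2 <- pileup_track(rnd, c(c1 = 10000))
  expect_equal(sum(as.numeric(tr2[["c1"]])), sum(w))
  bad <- data.frame(read_id = "over", contig = "c1", start = 9990, end = 10050)
  expect_error(pileup_track(bad, c(c1 = 10000)), "over")
})

test_that("consecutive region calling honors significance and merging", {
  # flat depth exactly at lambda is never significant
  flat <- rle_track(rep(3L, 50000))
  expect_equal(nrow(call_consecutive_regions(flat, lam = 3)), 0)
  # two depth-5 blocks with an 8 kb gap merge; a 20 kb gap does not
  v <- rep(0L, 60000)
  v[10001:12000] <- 5L
  v[20001:22000] <- 5L
  merged <- call_consecutive_regions(rle_track(v), lam = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 10000)
  expect_equal(merged$end, 22000)
  v2 <- rep(0L, 60000)
  v2[10001:12000] <- 5L
  v2[40001:42000] <- 5L
  two <- call_consecutive_regions(rle_track(v2), lam = 1)
  expect_equal(nrow(two), 2)
  # a gap of exactly merge_dist stays split (strict inequality)
  v3 <- rep(0L, 60000)
  v3[10001:12000] <- 5L
  v3[(12000 + 12500 + 1):(12000 + 12500 + 2000)] <- 5L
  expect_equal(nrow(call_consecutive_regions(rle_track(v3), lam = 1)), 2)
  # mean depth and fold enrichment are over the merged interval
  expect_equal(merged$mean_depth, (2000 * 5 + 2000 * 5) / 12000)
  expect_equal(merged$fold_enrichment, merged$mean_depth / 1)
})

test_that("raising depth never shrinks consecutive regions (monotone)", {
  set.seed(21)
  for (rep_i in 1:20) {
    v <- rpois(30000, 1) + sample(c(0L, 8L), 30000, replace = TRUE,
                                  prob = c(0.95, 0.05))
    lo <- call_consecutive_regions(rle_track(v), lam = 1.5)
    hi <- call_consecutive_regions(rle_track(v + 2L), lam = 1.5)
    if (!nrow(lo)) next
    # every low-depth region is contained in some high-depth region
    ov <- GenomicRanges::findOverlaps(
      atacircle:::as_granges0(lo), atacircle:::as_granges0(hi), type = "within")
    expect_equal(length(unique(S4Vectors::queryHits(ov))), nrow(lo))
    # and no output pair is within merge_dist of each other
    if (nrow(hi) > 1) {
      gaps <- hi$start[-1] - hi$end[-nrow(hi)]
      expect_true(all(gaps[hi$contig[-1] == hi$contig[-nrow(hi)]] >= 12500))
    }
  }
})

test_that("discordant region calling finds junction evidence blocks", {
  n <- 100000
  total <- rep(2L, n)
  disc <- rep(0L, n)
  expect_equal(nrow(call_discordant_regions(rle_track(disc), rle_track(total),
                                            fake_reads(character(), character(),
                                                       numeric(), numeric(),
                                                       character()))), 0)
  # a 500 bp block of discordant depth 3 (ratio 1.5) over background ratio
  # ~0.001 clears -log10 p >= 1.301 in both modes
  disc[50001:50500] <- 3L
  total[50001:50500] <- 2L
  dreads <- fake_reads(sprintf("d%02d", 1:6), "c1",
                       seq(50000, 50400, length.out = 6),
                       seq(50100, 50500, length.out = 6), "+")
  for (mode in c("count", "ratio")) {
    reg <- call_discordant_regions(rle_track(disc), rle_track(total + disc),
                                   dreads, mode = mode)
    expect_equal(nrow(reg), 1)
    expect_equal(reg$side, "right")  # all supporting reads on + strand
    expect_setequal(reg$read_ids[[1]], dreads$read_id)
  }
  # score threshold is -log10(0.05)
  expect_equal(1.301, round(-log10(0.05), 3))
  # an exact strand tie emits one node per side
  dreads2 <- fake_reads(sprintf("t%02d", 1:6), "c1",
                        seq(50000, 50400, length.out = 6),
                        seq(50100, 50500, length.out = 6),
                        rep(c("+", "-"), 3))
  reg2 <- call_discordant_regions(rle_track(disc), rle_track(total + disc),
                                  dreads2)
  expect_equal(sort(reg2$side), c("left", "right"))
  expect_equal(reg2$start[1], reg2$start[2])
})

test_that("all-zero total coverage is an error", {
  z <- rle_track(rep(0L, 1000))
  expect_error(call_discordant_regions(z, z, fake_reads("a", "c1", 1, 2, "+")),
               "coverage")
})

test_that("discordant regions attach to their largest-overlap host", {
  consec <- data.frame(contig = "c1", start = c(1000, 5000),
                       end = c(2000, 8000), mean_depth = 10,
                       fold_enrichment = 5)
  disc <- fake_nodes("c1", c(1500, 30000, 1700), c(1800, 30100, 5100),
                     side = c("right", "left", "right"), host = NA,
                     read_ids = list("a", "b", "c"))
  disc$host <- NULL
  out <- attach_to_consecutive(disc, consec)
  # the desert region (30000) is dropped
  expect_equal(nrow(out), 2)
  expect_equal(out$host[out$start == 1500], 1)
  # region [1700,5100) overlaps host1 by 300 bp and host2 by 100 bp
  expect_equal(out$host[out$start == 1700], 1)
})

test_that("bedGraph export round-trips run boundaries", {
  v <- rep(0L, 100)
  v[11:20] <- 4L
  path <- tempfile(fileext = ".bedgraph")
  export_bedgraph(rle_track(v), path)
  got <- read.table(path, sep = "\t")
  expect_equal(got$V2, 10)
  expect_equal(got$V3, 20)
  expect_equal(got$V4, 4)
})
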