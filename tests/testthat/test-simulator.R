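small_ref <- function(seed = 123, with_sequence = TRUE) {
  set.seed(seed)
  synthetic_reference(c(cA = 300000, cB = 200000), n_nruns = 3,
                      nrun_size = c(500, 2000), with_sequence = with_sequence)
}

test_that("mock generation respects size range, segment count and N runs", {
  ref <- small_ref(with_sequence = FALSE)
  set.seed(1)
  for (i in 1:100) {
    mk <- generate_mock_ecdna(ref, n_segments = c(1, 5),
                              total_size = c(8000, 30000),
                              min_segment = 1000, min_gap = 1000)
    expect_equal(mk$circle_length, sum(mk$segments$end - mk$segments$start))
    expect_gte(mk$circle_length, 8000)
    expect_lte(mk$circle_length, 30000 + nrow(mk$segments))  # rounding slack
    expect_lte(nrow(mk$segments), 5)
    # N-scan oracle: no segment touches an N run
    for (j in seq_len(nrow(mk$segments))) {
      s <- mk$segments[j, ]
      nr <- ref$nruns[ref$nruns$contig == s$contig, ]
      expect_true(all(atacircle:::overlap_width0(s$start, s$end,
                                                 nr$start, nr$end) == 0))
    }
    # segments are mutually non-overlapping
    gr <- atacircle:::as_granges0(mk$segments[, c("contig", "start", "end")])
    expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) != 1), 0)
  }
  expect_error(generate_mock_ecdna(ref, n_segments = c(1, 1),
                                   total_size = c(1e7, 1e7)),
               "too small")
})

test_that("single-segment request yields a single segment", {
  ref <- small_ref(with_sequence = FALSE)
  set.seed(2)
  mk <- generate_mock_ecdna(ref, n_segments = c(1, 1),
                            total_size = c(5000, 10000))
  expect_equal(nrow(mk$segments), 1)
})

test_that("circular sequence is the stranded concatenation of segments", {
  ref <- small_ref()
  set.seed(3)
  plus <- structure(list(id = "p",
                         segments = data.frame(contig = "cA", start = 1000,
                                               end = 2000, strand = "+"),
                         circle_length = 1000, cum = 1000),
                    class = "mock_ecdna")
  cs <- circular_sequence(plus, ref)
  expect_equal(as.character(cs),
               as.character(Biostrings::subseq(ref$seqs[["cA"]], 1001, 2000)))
  minus <- plus
  minus$segments$strand <- "-"
  expect_equal(as.character(circular_sequence(minus, ref)),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(ref$seqs[["cA"]], 1001, 2000))))
  # two segments: junction at len(seg1); base -1 is circularly adjacent to 0
  two <- structure(list(id = "t",
                        segments = data.frame(contig = c("cA", "cB"),
                                              start = c(1000, 5000),
                                              end = c(1600, 5400),
                                              strand = c("+", "+")),
                        circle_length = 1000, cum = c(600, 1000)),
                   class = "mock_ecdna")
  cs2 <- as.character(circular_sequence(two, ref))
  expect_equal(substr(cs2, 1, 600),
               as.character(Biostrings::subseq(ref$seqs[["cA"]], 1001, 1600)))
  expect_equal(substr(cs2, 601, 1000),
               as.character(Biostrings::subseq(ref$seqs[["cB"]], 5001, 5400)))
})

test_that("pair counts follow the coverage identity", {
  mk <- structure(list(id = "m", segments = data.frame(contig = "cA",
                                                       start = 0, end = 100000,
                                                       strand = "+"),
                       circle_length = 100000, cum = 100000),
                  class = "mock_ecdna")
  set.seed(4)
  pairs <- simulate_reads(mk, local_depth = 30, read_len = 100)
  expect_equal(nrow(pairs), 15000)
  expect_true(all(pairs$start >= 0 & pairs$start < 100000))
  expect_true(all(pairs$frag_len >= 100 & pairs$frag_len <= 1000))
  expect_error(simulate_reads(mk, read_len = 300, frag_mean = 250),
               "fragment mean")
})

test_that("background pairs meet the coverage identity and stay concordant", {
  ref <- small_ref(with_sequence = FALSE)
  nonN <- atacircle:::non_n_intervals(ref)
  set.seed(5)
  bg <- simulate_background(ref, genome_depth = 2, read_len = 100)
  expect_equal(nrow(bg), round(2 * sum(nonN$end - nonN$start) / 200))
  sam <- perfect_align(bg, NULL, ref, with_seq = FALSE)
  expect_true(all(abs(sam$tlen) <= 1000))
  # empirical mean depth within 10% of target
  reads <- data.frame(read_id = sam$qname, contig = sam$rname,
                      start = sam$pos - 1, end = sam$pos - 1 + 100)
  tr <- pileup_track(reads, ref$lengths)
  lam <- track_lambda(tr, effective_length = sum(nonN$end - nonN$start))
  expect_equal(lam, 2, tolerance = 0.1)
})

test_that("error-free reads are exact substrings of the doubled circle", {
  ref <- small_ref()
  set.seed(6)
  mk <- generate_mock_ecdna(ref, n_segments = c(2, 3),
                            total_size = c(20000, 30000), min_segment = 5000,
                            min_gap = 2000)
  pairs <- simulate_reads(mk, local_depth = 2, read_len = 80)
  r1 <- tempfile(fileext = ".fq"); r2 <- tempfile(fileext = ".fq")
  write_fastq(pairs, mk, ref, r1, r2)
  doubled <- strrep(as.character(circular_sequence(mk, ref)), 2)
  fq1 <- readLines(r1)
  seqs1 <- fq1[seq(2, length(fq1), by = 4)]
  hit1 <- vapply(seqs1[1:50], function(s) grepl(s, doubled, fixed = TRUE), TRUE)
  expect_true(all(hit1))
  fq2 <- readLines(r2)
  seqs2 <- fq2[seq(2, length(fq2), by = 4)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs2[1:50])))
  expect_true(all(vapply(rc, function(s) grepl(s, doubled, fixed = TRUE), TRUE)))
})

test_that("perfect alignment clips reads at junctions by truth arithmetic", {
  ref <- small_ref(with_sequence = FALSE)
  # two + segments of 10 kb each; junction at circle offset 10000
  mk <- structure(list(id = "j",
                       segments = data.frame(contig = c("cA", "cA"),
                                             start = c(20000, 50000),
                                             end = c(30000, 60000),
                                             strand = c("+", "+")),
                       circle_length = 20000, cum = c(10000, 20000)),
                  class = "mock_ecdna")
  # a 100 bp read starting 40 bp before the junction: 40M60S at the end of
  # seg1 or 40S60M at the start of seg2 -- the longer (60 bp) side wins
  pairs <- data.frame(qname = "x", start = 9960, frag_len = 260,
                      read_len = 100)
  sam <- perfect_align(pairs, mk, ref, with_seq = FALSE)
  r1 <- sam[sam$flag %% 128 >= 64, ]
  expect_equal(r1$cigar, "40S60M")
  expect_equal(r1$pos, 50001)  # mapped into segment 2
  # clip + match always conserve read length
  expect_true(all(vapply(sam$cigar, function(cg) {
    sum(as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])) == 100
  }, TRUE)))
  # mate maps into segment 2 interior: same contig here, long template
  expect_equal(abs(sam$tlen[1]) > 1500 || sam$rnext[1] != "=",
               FALSE)  # both mates in seg2 -> concordant pair
})

test_that("pairs straddling an inter-contig junction become discordant", {
  ref <- small_ref(with_sequence = FALSE)
  mk <- structure(list(id = "ic",
                       segments = data.frame(contig = c("cA", "cB"),
                                             start = c(20000, 50000),
                                             end = c(30000, 60000),
                                             strand = c("+", "+")),
                       circle_length = 20000, cum = c(10000, 20000)),
                  class = "mock_ecdna")
  pairs <- data.frame(qname = "y", start = 9800, frag_len = 400,
                      read_len = 100)
  sam <- perfect_align(pairs, mk, ref, with_seq = FALSE)
  expect_setequal(sam$rname, c("cA", "cB"))
  expect_true(all(sam$rnext != "="))
  expect_true(all(sam$tlen == 0))
  path <- tempfile(fileext = ".sam")
  write_sam(sam, ref$lengths, path)
  reads <- classify_reads(load_filtered_reads(path))
  expect_true(all(reads$is_discordant))
})

test_that("simulation is deterministic given a seed", {
  ref <- small_ref(with_sequence = FALSE)
  sam_once <- function() {
    set.seed(77)
    mk <- generate_mock_ecdna(ref, n_segments = c(1, 3),
                              total_size = c(10000, 20000), min_gap = 2000)
    pairs <- simulate_reads(mk, local_depth = 5, read_len = 50)
    recs <- perfect_align(pairs, mk, ref, with_seq = FALSE)
    path <- tempfile(fileext = ".sam")
    write_sam(recs, ref$lengths, path)
    readLines(path)
  }
  expect_identical(sam_once(), sam_once())
})

test_that("circle-local depth hits its target within 10%", {
  ref <- small_ref(with_sequence = FALSE)
  set.seed(8)
  mk <- generate_mock_ecdna(ref, n_segments = c(1, 1),
                            total_size = c(60000, 60000), min_gap = 2000)
  pairs <- simulate_reads(mk, local_depth = 30, read_len = 100)
  # truth-placement pileup on the circle
  cov <- numeric(mk$circle_length)
  for (i in seq_len(nrow(pairs))) {
    for (off in c(0, pairs$frag_len[i] - 100)) {
      idx <- ((pairs$start[i] + off + 0:99) %% mk$circle_length) + 1
      cov[idx] <- cov[idx] + 1
    }
  }
  expect_equal(mean(cov), 30, tolerance = 0.1)
})
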