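---
title: "Detecting ecDNA from ATAC-Seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ecDNA from ATAC-Seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Extrachromosomal circular DNA (ecDNA) carries amplified oncogenes in many
tumors. Because ecDNA is less densely packed in nucleosomes than the linear
genome, ATAC-Seq libraries over-represent its constituent segments: their
"local depth" is tens-fold above the 1–3× genome-wide background. Two
additional signals pinpoint the circle's junctions: paired-end reads whose
mates map unexpectedly far apart (or to different chromosomes), and reads
whose alignments are soft-clipped where they run across a junction.
`atacircle` turns these three signals into reconstructed circle structures.

## The detection model, stage by stage

**Read filters.** Primary alignments with MAPQ strictly greater than 10,
not flagged as duplicates, and not overlapping a blacklist interval (any
overlap, ≥ 1 bp) are kept. Duplicate flags are trusted as set upstream;
the package never re-deduplicates. All internal coordinates are 0-based
half-open; conversion from SAM's 1-based convention happens only in the
reader, and BED output uses the internal convention directly.

**Read classes.** A read is *discordant* when |TLEN| exceeds the insert
threshold (default 1500 bp) or its mate maps to another contig — the
inter-contig rule is on by default because ecDNA freely joins chromosomes,
and it can be disabled. A read is *clipped* when its CIGAR carries soft or
hard clips. The labels compose. Each record is judged on its own: the
package does not require the unobserved mate to have passed MAPQ filtering,
since a junction-spanning pair with one repetitive-side mate still
witnesses the junction from the observed side.

**Consecutive enrichment regions.** All reads are piled up per base (read
alignment spans, not fragment spans). With the genome-wide mean depth λ —
total aligned bases over the effective genome length, excluding blacklist
and N bases when known — a base is significant when the Poisson upper tail
`P(X ≥ depth)` is below 0.05. Maximal significant runs closer than 12.5 kb
are merged (strictly: a gap of exactly 12 500 bp stays split). These merged
regions are the candidate circle segments' home territory.

**Discordant junction regions.** Discordant reads are piled up separately.
The package implements two significance models and the choice is a config
switch (`disc_test_mode`):

* `"count"` (default): discordant depth against the genome-wide mean
  discordant depth as λ, thresholded at score `-log10 P ≥ 1.301`
  (= −log₁₀ 0.05).
* `"ratio"`: the per-base ratio of discordant to total depth against the
  genome-wide mean ratio as Poisson λ, with the survival function extended
  to fractional counts through the gamma duality
  `P(X ≥ c) = pgamma(λ, shape = c)`.

The ratio formulation is the more literal reading of the published
description, but it is not attainable in practice: for any realistic mean
ratio λ_r the continuous threshold works out to c* ≈ 0.23–0.5, while the
discordant fraction of depth achievable next to a genuine junction peaks
around 0.3 with 100 bp reads and 0.17 with 35 bp reads — the literal test
therefore misses true junctions systematically, and integer-truncating
Poisson implementations (as in common peak callers) would never fire on a
fractional ratio track at all. The count model keeps the same Poisson
machinery, the same 1.301 score cutoff, and detects the same kind of
evidence, so it is the default.

Each significant run becomes a junction node. Its *side* is the majority
strand vote of the discordant reads overlapping it: a forward-strand
read's fragment continues rightwards, so the junction lies on the region's
right; reverse-strand, left. An exact tie emits two nodes, one per side.
Regions not overlapping any consecutive region are discarded; the host is
the consecutive region with the largest overlap.

**Breakpoint graph.** Nodes are the junction regions. A *discordant* edge
joins two nodes sharing at least `min_support` read IDs whose mates carry
the majority orientation signature; read IDs touching more than two regions
are ambiguous and excluded; at most one discordant edge exists per node
pair (supports merged). A *consecutive* edge joins every left-side node to
every downstream right-side node inside one consecutive region ("properly
oriented": the junction sides face away from the segment between them, so
that segment is the DNA retained in the circle). All orderable
opposite-side pairs are connected, not only nearest neighbours — the search
stage, not graph construction, resolves alternatives.

`min_support` defaults to the Poisson inverse survival of the discordant
enrichment background (the genome-wide mean discordant rate), floored at 3
to stay consistent with the "more than 2 reads per junction" output filter.
The background rate — not the mean support of already-called regions — is
the right λ here: a junction's support should be tested against what noise
would produce, and calibrating the threshold to the mean of true junctions
would reject roughly half of them at any depth.

**Breakpoint refinement.** A junction region only brackets its breakpoint.
With the region's innermost base as origin and `h` the candidate distance
to the breakpoint:

* discordant read end offsets `L₁…Lₙ` stop short of the breakpoint, so
  `P(L|h)` is uniform on `[1, h]` and zero beyond — the German tank
  problem; the likelihood `(1/h)ⁿ` is maximized at the boundary `max(L)`;
* clipped read end offsets `S₁…Sₘ` mark the breakpoint within a small
  tolerance, `P(S|h) = N(h, e²)`.

The joint log posterior (up to its normalizer, which is never computed
explicitly — normalization happens over the grid) is maximized by a 1 bp
grid search from `max(1, max(L))` to `max(L) + insert_threshold` (or
`max(S) + 6e` without discordant evidence), capped at the host consecutive
region's boundary so a breakpoint cannot escape its region's context. The
reported interval is the central 95% credible interval of the gridded
posterior; argmax ties go to the smallest `h` (the most conservative
extension). Defaults chosen where the source leaves them open: `e = 5` bp,
1 bp grid resolution, clip offsets taken from the junction-side clip only.
The absolute breakpoint is `origin + ĥ` (right-side junction) or
`origin − ĥ` (left-side).

**Circle search.** A candidate ecDNA is a closed walk in the graph that
visits each node at most once and strictly alternates edge types, pairing
one genomic segment with one junction per step (so every circle has an even
number of edges; a single segment joined head-to-tail is the 2-edge case).
Node revisits are prohibited: without copy-number information, repeated or
foldback segments are unidentifiable (breakage–fusion–bridge amplicons are
out of scope by design), and the prohibition bounds the search. At every
branch, edges are tried largest-segment-first, then by mean depth
(discordant branches by support), so larger and better-covered structures
are found first; output order inherits discovery order, globally rather
than per connected component. Duplicates are removed by a canonical key —
the lexicographic minimum over all rotations of both orientations of the
segment tuple sequence — and at most `max_outputs` (default 1000)
candidates are returned, truncating after deduplication.

**Candidate filters.** For reporting, a circle must have every segment's
fold enrichment above 10 (a circle is only as credible as its weakest
segment), every junction supported by more than 2 unique read IDs, and,
when repeat annotation is supplied, less than 5% of its length in repeats.

One consequence of the per-base p < 0.05 test is worth spelling out: by
construction, up to ~5% of plain-background bases are "significant", and
the 12.5 kb merge rule can chain these sporadic false peaks into very large
consecutive regions — with short reads over a uniform background, into
whole contigs. True junction nodes of *different* circles then share a host
and acquire consecutive edges spanning long stretches of background-depth
DNA. Those spans can never survive the fold-enrichment filter, so the
pipeline prunes their edges before the search (an output-equivalent
optimization that keeps the DFS from exhausting its cycle budget on
doomed alternatives); `find_circles()` itself never prunes.

## The simulator: what it emulates, and what it does not

The benchmark protocol builds mock ecDNAs on a bundled ~20 Mb two-contig
synthetic reference (random sequence with seeded N runs): segments drawn
from non-N regions, mutually non-overlapping, independently oriented,
ligated in draw order; paired-end reads drawn uniformly on the circle at a
chosen local depth (pair count = `depth × length / (2 × read_len)`),
fragments wrapping the origin; plus uniform concordant background over the
non-N genome at 1–3× (default 2×). Fragment lengths follow a truncated
normal (mean 250, sd 50, bounds `[read_len, 1000]`) — an ATAC-like insert
profile chosen to keep linear background below the 1500 bp discordance
threshold. A *perfect aligner* maps every read back through the segment
map: junction-crossing reads become primary alignments of their longest
reference-consistent piece with the remainder soft-clipped, exactly the
evidence a real aligner would produce without requiring one.

Scale choices stated once: the desk-scale benchmark uses circles of
20–200 kb total with 1–8 segments (the full-scale ranges, 5 kb–10 Mb and
up to 50 segments, remain configurable), distributed 2 per sample with a
50 kb exclusion gap between placed segments. Both choices keep the
circle-occupied fraction of the 20 Mb reference near the ~1% that circles
drawn from a full-size genome occupy, which matters because the genome-wide
mean depth λ includes the circles' own reads: packing many 30×-covered
circles into a small reference would inflate λ, depress every segment's
fold enrichment below the >10 reporting filter, and make the benchmark
measure reference size rather than the method.

What a green benchmark does **not** establish: the background is uniform
and discordant-free (no chimeric artifacts, no mapping noise, no repeats),
quality strings are constant, there are no indels, PCR duplicates, Tn5
insertion bias, or accessibility peak shape, and substitution errors
default to zero (configurable). Detection on real libraries faces all of
these; the negative-control property (a clean background yields at most one
candidate) is correspondingly easier here than on real tissue data.

## Evaluation

Predictions match a truth circle when there is a segment bijection with
≥ 95% reciprocal overlap per segment on the same contig and the cyclic
order is identical under rotation/reversal-with-strand-flip, plus either
(a) the predicted segments cover ≥ 95% of the truth circle's bases
(coverage mode), or (b) every truth breakpoint lies inside the matched
predicted 95% credible interval (CI mode). Matching is greedy one-to-one,
best coverage first, so one lucky prediction cannot absorb several truths
and duplicated predictions count as false positives. The reciprocal
per-segment rule operationalizes "same ligation structure"; requiring it on
both lengths (not only the truth's) prevents a grossly over-extended
segment from matching.

## Numerical details and degenerate inputs

Poisson tails use `pgamma(λ, shape = c)` (regularized lower incomplete
gamma), continuous in the count and agreeing with the finite series to
1e−12 at integer counts. Empty depth tracks yield empty region lists; an
all-zero total track is an error (no coverage). Nodes with no usable
breakpoint evidence are dropped with a warning. A read ending beyond its
contig is an error naming the record. The whole pipeline is deterministic
given sorted inputs and a seed: node IDs are assigned in coordinate order,
argmax ties break to the smallest grid point, and every source of
randomness in the benchmark derives from one master seed through a fixed
31-bit stream.

## Known limitations

Amplicons with repeated or foldback segments (BFB, HSR) cannot be
reconstructed — the simple-cycle restriction is explicit. Copy-number
balance is not modelled; candidates are not ranked by a whole-circle
significance score. CRAM input, realignment of clipped tails, and
supplementary-alignment junction proof are out of scope. The discordant
`"ratio"` significance mode is retained for fidelity but is not
recommended (see above).
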