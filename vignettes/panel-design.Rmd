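---
title: "Condensing viral sequence space into a capture panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing viral sequence space into a capture panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the redundancy model
behind the condensation workflow, the parameters that matter and why they
default as they do, the numerical choices inside the alignment engine, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## The problem and the model

Hybridization capture enriches sequencing libraries for fragments similar to
a designed probe set. A comprehensive viral panel wants every virus a
vertebrate sample might contain, but public collections are massively
redundant: for each species there is one canonical (parent) reference plus
many complete genomes of the same species — strains, isolates, mutants —
that differ from the parent only in places. Probe budgets (about 200 Mb of
target space in the design regime this package mirrors) cannot afford the
raw union, which is several-fold larger.

The model of redundancy is hybridization itself. A probe of length k
tolerates divergence up to roughly 10 %, so any k-mer of a neighbor genome
with at least 90 % identity to the tiled parent is already capturable and
adds nothing. The workflow therefore is:

1. decompose each neighbor into all k-mers (1-bp sliding window, so every
   possible probe-length subsequence is examined);
2. classify each k-mer as represented (best glocal identity to the parent at
   or above the threshold, either strand) or divergent;
3. merge the divergent k-mer coordinates into contiguous spans and excise
   the spans as supplementary panel entries, recorded with a
   `{SQ start-end}` suffix on the source header.

Because consecutive k-mers overlap by k − 1 bases, a single novel segment of
length L yields a merged span of at most L + 2(k − 1) bases: the excision
carries at most k − 1 bases of redundant flank on each side. That bound is
what the insert-recovery tests and the acceptance script verify.

For collections too large even for this (hundreds of thousands of influenza
records), the package clusters full-length sequences instead: single-pass
greedy centroid clustering at the same identity threshold, processing the
designated parents first and then the input length-descending; only
non-parent centroids enter the panel. Concatenating all parents and
splitting the concatenation into a few long segments guarantees the
canonical references out-seed every strain sequence. The split is near-equal
(sizes within 1 bp) with segment count as the knob; the historical design
used six segments of 18–26 kb over 29 parent records, which a near-equal
split of the same material reproduces to within rounding. Chimeric junctions
created by concatenation are accepted: junction-spanning k-mers are never
used in this mode, and a spurious junction similarity could only cause a
redundant sequence to be retained, never a divergent one to be lost.

## The identity metric

"Identity" is underspecified in most tool documentation, so the package
fixes one definition and uses it everywhere:

* **Glocal alignment**: the shorter sequence aligns end-to-end against a
  free-ended placement in the longer. Affine gap scoring with match +1,
  mismatch −1, gap open 2, gap extend 1 (a gap of length g costs 2 + g).
  These values are exposed in `cluster_params()` and fixed by default so
  results are reproducible.
* **Identity** = matching columns / total alignment columns. Gaps count
  against identity; N never matches anything, including N.
* **Tie-breaking**: among score-optimal alignments the engine selects the
  one maximizing matches, then minimizing columns. This makes identity a
  well-defined function of the two sequences rather than of a traceback
  order, which is what allows the test suite to demand *exact* agreement
  between the Rcpp engine and an independently written R oracle on more
  than a thousand random pairs.
* **Symmetry**: for equal-length pairs both sequences qualify as "the
  shorter", and the two roles can score differently (free ends sit on the
  other sequence). The engine evaluates both and keeps the better, making
  the metric symmetric, as the clustering invariants require.
* **Reverse complement**: when enabled (default), the better orientation is
  reported; forward wins ties.

## The accelerated k-mer classifier

Classifying every one of ~10,000 k-mers per neighbor against a 10-kb parent
with full dynamic programming would cost ~10^6 DP cells per k-mer. The bulk
classifier keeps the decisions exact while skipping almost all of that work:

* **Pigeonhole seeds.** A placement with identity ≥ t has at most
  D = ⌊k(1 − t)/t⌋ unit edits (11 for k = 100, t = 0.90), so it preserves an
  exact seed of length s = ⌊(k − D)/(D + 1)⌋ (7 here). All parent seed
  positions are indexed; a k-mer with no seed hit on a diagonal band has no
  qualifying placement and is divergent — exactly.
* **q-gram support filter.** A placement with ≤ D edits retains at least
  (k − s + 1) − sD seeds, all on nearby diagonals; candidate regions with
  fewer supporting seeds are provably outside the bound and are skipped.
  This removes the spurious single-seed candidates that otherwise dominate
  runtime.
* **Bit-parallel prefilter.** Each surviving region is scanned with a
  blocked Myers edit-distance computation. Distance > D ⟹ divergent
  (exact). Distance ≤ D′ = ⌊k(1 − t)/(1 + t)⌋ (5 here) ⟹ represented: a
  unit-cost alignment with d edits has identity at least (k − d)/(k + d) ≥ t.
  This shortcut reasons about *some* high-identity alignment rather than the
  score-optimal one, so it is the single place the fast path could in
  principle disagree with the full metric; a property test compares the
  scan against full-DP classification across divergence levels, and the
  threshold-boundary cases (10 vs 11 substitutions in a 100-mer) are pinned
  exactly.
* **Ambiguous band.** Distances in (D′, D] get the full lexicographic DP on
  the ~(k + 2D)-wide candidate window — exact by construction.

The host-similarity filter reuses the same machinery without the
represented-shortcut (it needs the identity value, not just the decision),
scanning each probe-sized window of each entry against both strands of the
host sequence.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k`, probe length | 100 | bp | capture probe length; the unit of redundancy |
| `identity_threshold` (design) | 0.90 | fraction | hybridization tolerance assumed at the probe level |
| match/mismatch, open/extend | +1/−1, 2/1 | score | fixed, documented scoring; exposed in `cluster_params()` |
| `n_segments` (long mode) | 6 | count | segments of the concatenated parent construct |
| host `identity_threshold` | 0.75 | fraction | identity to host at which a probe risks off-target capture |
| host `window` | 100 | bp | the probe level; windows step by window/2, final window right-anchored |
| host `mode` | drop_entry | — | conservative default: any host-like window removes the entry; `mask_window` masks windows instead |
| DUST `score_threshold` | 20 | level | de facto standard level; intervals score > level/10 |
| DUST `window` | 64 | bp | maximum scored interval |
| probe tiling | 100/100 | bp | end-to-end tiling, right-anchored final probe |

Open design points were resolved once and documented here rather than left
configurable-by-accident:

* The `{SQ a-b}` header dialect is written and parsed as **1-based
  inclusive** (a 201-bp slice renders as `{SQ 2444-2644}`); internal
  coordinates are 0-based half-open throughout, BED-compatible.
* Bookended spans (end equals next start) merge; a single-base gap keeps
  spans apart. K-mers at consecutive offsets overlap by k − 1, so
  contiguity is the natural excision unit.
* Divergent k-mers are classified against the parent only; folding into
  previously retained neighbor material (secondary centroids) is not done —
  per-neighbor processing stays independent, which also makes results
  order-independent across neighbors.
* Whole entries are dropped (not windows masked) when host similarity is
  found, by default; both behaviours are implemented.
* `reduction_ratio` of an empty input is 0, not NaN.
* Non-N bases form the denominator of offset-coverage metrics: hard-masked
  bases are uncapturable by design and should not count against a design.
* Coverage gaps include uncovered reference ends, so gap totals and covered
  bases partition the reference exactly.
* Zero-pre-capture enrichment uses a one-read pseudo-count and renders as a
  `">"` lower bound, matching how capture-evaluation tables present such
  samples.
* Reference selection per species maximizes covered bases with a
  lexicographic tie-break, making reports deterministic.

## The DUST masker

The cited low-complexity module is implemented as a symmetric, windowed
triplet statistic: every interval of length 4–64 bp is scored
S = Σ_t c_t(c_t − 1)/2 normalized by (l − 1), where c_t counts each of the
64 ACGT triplets in the interval and l is the number of N-free triplets;
intervals with score > level/10 (level 20) are flagged and the mask is the
union of flagged intervals, hard-masked to N. Triplets containing N are
excluded from scoring, which keeps the operation idempotent in practice
(verified by tests). This is the package's own faithful variant of the
classic algorithm — the exact historical implementation is unspecified in
the design literature — and the test suite pins it to a brute-force triplet
counter on every sequence family it exercises (homopolymers, dinucleotide
repeats, random sequence, N-containing sequence).

## The synthetic-data generator

`simulate_parent()` draws i.i.d. bases at a requested GC content.
`simulate_neighbor()` applies i.i.d. substitutions (uniform over the three
alternatives), optional geometric-length indels, and placed novel inserts,
and returns ground truth: the realized insert intervals plus every
probe-sized window whose realized non-parental base count exceeds
⌊k(1 − t)⌋. `simulate_alignments()` builds pre/post-capture alignment sets
with a controlled viral fraction and enrichment factor.

Two modelling choices deserve emphasis:

* **No mutation bias.** Substitutions are uniform (no transition/
  transversion bias, no rate heterogeneity along the genome). This is
  adequate for identity-threshold behaviour — what matters is how many
  mismatches fall in a window, not which — but real strain clouds have
  hotspots and conserved cores the generator does not produce.
* **Deterministic read counts.** The alignment simulator uses rounded
  expected viral read counts with random placements, rather than per-read
  Bernoulli draws. The realized enrichment factor then equals the requested
  one up to rounding, so fold-recovery checks exercise the enrichment
  arithmetic rather than binomial noise. Placements, orientations and
  qualities remain random and seeded.

Consequently, passing tests show that the pipeline recovers the divergence
structure it is pointed at — they do not show that 0.90 is the right
hybridization threshold for any particular chemistry, nor how the pipeline
behaves under real mutational processes, sequencing error, or uneven
coverage. Those are properties of data the package's scope deliberately
excludes (it consumes alignments; it does not map reads or model wet-lab
steps).

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen once:
10-kb parents with 20 neighbors per divergence condition (2 % and 15 %
substitution; 10 seeded replicates in the test suite), 500-bp novel-insert
recovery, ≥ 1,000 random pairs of ≤ 300 bp for exact oracle equivalence of
the identity engine, 1,000 random interval sets and alignment sets for the
interval/coverage conservation laws, and 10^6-read enrichment simulations at
factor 674 with a 0.01 % pre-capture viral fraction. The headline
collection-scale numbers of the original design regime (hundreds of
megabases condensed to a ~200-Mb panel) depend on a specific historical
sequence snapshot and a vendor's proprietary probe redistribution, and are
out of scope by design.

## Known limitations

* Depth counts whole aligned spans; CIGAR-level gaps inside a read are not
  subtracted (SAM ingestion collapses each read to one reference footprint).
  For the short-read, small-gap regime these metrics target, the
  approximation is at the scale of indel lengths.
* The k-mer classifier's represented-shortcut is exact with respect to a
  unit-cost witness alignment, not the affine-optimal one; adversarial
  sequences could in principle slip through the shortcut. Property tests
  compare scan and full-DP classification; no disagreement has been
  observed, and the shortcut can be effectively disabled by lowering the
  identity threshold band if a use case demands it.
* Greedy clustering is order-dependent by construction (first qualifying
  centroid wins); the package pins the order (parents first, then
  length-descending) and is deterministic given it, but a different order
  gives a different — equally valid — centroid set.
* The host filter is exhaustive rather than heuristic; it is meant for
  desk-scale host sequences (its complexity is windows × host length), not
  for screening against a full mammalian genome.
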