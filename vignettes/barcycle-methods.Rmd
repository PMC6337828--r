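---
title: "Calling cell barcodes with circularized de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cell barcodes with circularized de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcycle)
```

## The problem

Split-pool synthesized cell barcodes (Drop-seq and relatives) are short --
typically L = 12 nt -- random, and unlisted: there is no whitelist to
correct against, and no reliable prior on the number of cells. Worse, the
synthesis chemistry makes deletions common, so the observed fixed-length
barcode window of a read can carry mismatches, deletions (which shift
downstream bases into the window) and insertions (which shift barcode
bases out of it). The task `barcycle` solves is to recover the set of
true barcodes from the reads alone and to assign every read to an
error-corrected consensus barcode.

## Circularized k-mer fingerprints

K-mer counting can identify error-free subsequences shared between reads
of the same barcode, but with L = 12 and a useful k (>= 7), a single
error near the middle of a linear window corrupts *every* k-mer. Treating
the window as a circular string fixes this: whatever the error position,
`L - k` contiguous circular k-mers avoid it. Two companion variants
extend the idea to indels:

* **TRUNCATED** -- the window minus its last base, circularized. After a
  deletion the last window position holds the first downstream (UMI or
  adaptor) base; truncation removes the intruder.
* **EXACT** -- the window as observed, circularized.
* **EXTENDED** -- the window plus the first downstream base,
  circularized. After an insertion the last barcode base has been pushed
  just outside the window; extension recovers it.

Each read therefore yields `(L-1) + L + (L+1) = 3L` positioned k-mers (36
for L = 12). Reads with zero or one error always contribute error-free
k-mers of the true barcode; reads with more errors sometimes do,
depending on error spacing.

## The weighted de Bruijn graph and cycle search

K-mers from a subsample of reads are indexed (`build_kmer_index()`); the
index maps each k-mer to the reads, variants and circular offsets that
produced it. For a start k-mer, all reads containing it (or any of its
rotations) are pulled and a directed graph over their (k-1)-mers is
built; the weight of edge `u -> v` is the number of times the k-mer
`u + last(v)` was observed across all variants and positions of those
reads. A cyclic path of L edges spells a candidate barcode; its
**capacity** -- the minimum edge weight on the cycle -- measures how many
observations support its weakest link.

Two properties of the weighting matter:

1. *No single read need contain all the k-mers of a cycle*: overlap
   across many error-containing reads assembles the full circle.
2. *The three-variant counting creates a 3:2:1 hierarchy*: a k-mer in the
   linear region of the barcode occurs in all three variants of a clean
   read, the barcode/next-base junction k-mer in two, and each variant's
   wrap-around k-mers in one. The greedy search below follows locally
   heaviest edges, and this hierarchy reliably steers it along the exact
   cycle rather than into a truncated-variant 11-cycle, which cannot
   close a 12-step walk and would otherwise force closure through
   low-weight error edges. (Capping each read's contribution to an edge
   at one -- a tempting safeguard against repetitive reads -- flattens
   the hierarchy and measurably degrades recovery; it is deliberately not
   done.)

`find_cycle()` performs a greedy depth-first search: from the start node
(the (k-1)-mer prefix of the seed), children are explored in descending
edge weight (ties lexicographic), to exactly L steps; the first walk that
re-enters the start node at step L is returned. Intermediate nodes may be
revisited -- legitimate cycles of short barcodes can repeat (k-1)-mers --
but the start node may not be re-entered early: entering it closes the
cycle by definition, and allowing early passes would let a heavy short
cycle (e.g. from a near-periodic barcode) be traversed twice into a
spurious periodic walk whose extraction also destroys the true cycle.
One consequence is that a barcode that is genuinely d-periodic with d
dividing L (probability ~4^-6 per random 12-mer) cannot be called. A
breadth-first distance-to-start map prunes children that cannot close
the cycle in the remaining steps; the prune only discards walks the
search would reject anyway, so the result is identical to the unpruned
search.

`extract_cycles()` repeats the search, subtracting each found cycle's
capacity from every edge on it -- driving its weakest edge to zero
(weight-0 edges are never traversed, which is how "removal" is
implemented) and removing the cycle's contribution to shared edges --
until no cycle remains or `depth` cycles have been extracted.

Seeds are taken from the most frequent k-mers in the index, skipping any
k-mer already covered by an extracted path (the exact and truncated
circles of a called barcode, or rotations of a used seed): each new
subgraph starts from a new node, so the search breadth is spent
discovering new barcodes instead of re-deriving abundant ones whose
k-mers dominate the count table. Only the first cycle of a subgraph --
the one extracted at full weight -- marks its k-mers as covered; barcodes
surfacing after a decrement keep their own seeds, so they are later
re-derived at full capacity and deduplication keeps the better estimate.

## Rotation resolution

A cycle determines the barcode only up to rotation. Each k-mer on the
cycle votes with its modal EXACT-variant in-read offset from the index:
an error-free read's exact variant starts at offset 0, so the modal
offset of a true k-mer is its position in the barcode. The majority
rotation wins (ties break lexicographically); with no offset evidence at
all, the lexicographically smallest rotation is returned and flagged.

## Thresholding at the capacity knee

True barcode cycles have capacities on the order of the per-cell read
count; spurious cycles sit near 1. Sorted descending, the capacities show
a cliff at the boundary. The knee finder builds the cumulative capacity
curve over path rank, smooths it with a Savitzky-Golay filter
(defaults: window 101 ranks or the largest odd number that fits,
polynomial order 3), and locates the interior extremum of largest
magnitude of the curve's curvature -- equivalently, the local maximum of
the first derivative of the capacity-vs-rank distribution read in
ascending orientation. On a clean two-population fixture this coincides
with the arg-max of the discrete second difference of the unsmoothed
curve. A candidate knee must be a genuine cliff: the smoothed derivative
half a window before it must exceed the derivative half a window after
it by at least a factor `min_drop` (default 2, formalising "a
significantly higher capacity than the rest"). Because smoothing spreads
the cliff over the filter window, the curvature extremum only localises
the knee; the final knee rank snaps to the largest consecutive capacity
drop in the unsmoothed curve within half a window of the candidate.
Paths with capacity strictly above the capacity at the knee rank are
accepted, so the transition value itself is excluded.

When no significant cliff exists the finder raises a no-knee error.
`run_pipeline()` treats that outcome as evidence that there is no
spurious population to reject -- which is exactly what happens on
essentially error-free data, where nearly every called path is a true
barcode -- and accepts all called paths, noting the fallback in the run
log. Callers wanting a hard cut can supply their own threshold.

## Read assignment

Reads are assigned to accepted consensus barcodes either by

* **k-mer compatibility**: count distinct shared k-mer strings between
  the read's three circularization variants and the consensus barcode's
  exact circular k-mers (a consensus has no errors to absorb, so only
  its exact circle is used); assign to the unique maximum if it shares
  at least `min_shared` (default 2); or
* **Levenshtein distance** (the default): assign to the unique nearest
  barcode within `max_dist` (default 2 -- the largest radius at which
  chance collisions between random 12-mers stay rare). Ties and far
  reads stay unassigned.

Levenshtein mode is the conservative choice -- fewer incorrect
assignments, more unassigned reads -- which is the sensible default for
real single-cell data where a wrongly merged cell is worse than a lost
read. Assignment k (`k_assign`) may exceed the graph k to raise
stringency.

## The simulator and what it does (not) capture

`generate_dataset()` emulates the benchmark conditions: around 500 cells
(the count itself drawn from Normal(500, 50) when unspecified), L = 12,
100,000 reads per dataset, per-cell abundances drawn from Normal(200, 20
reads/cell), uniform, or exponential (scale 0.2) distributions and
normalised; each read picks a barcode by abundance and receives a
Poisson(lambda) number of errors, lambda in [0, 3], of configured type
(insertion / deletion / mismatch / any, types drawn uniformly for
"any"), at uniform-random positions in the window. Deletions shift
downstream filler into the window and insertions shift barcode bases
out, so emitted windows always have length L, exactly as in a real read;
the window plus filler also supplies the next-base needed by the
extended variant. The full benchmark grid (3 abundance distributions x 4
error types x lambda in {0, 0.5, 1, 2, 3} x 3 replicates) comprises 180
dataset configurations; the five lambda levels between 0 and 3 are the
grid consistent with that total.

The simulator does not model quality scores, PCR duplication, UMI
collisions, or non-uniform error hotspots. Passing tests on simulated
data therefore demonstrate correctness of the calling machinery under
the stated error model, not performance on any particular instrument's
error profile.

A naive comparison pipeline (`naive_baseline()`) counts exact barcode
windows, thresholds the count-rank curve with the same knee procedure,
and assigns reads by exact match only. It has no mechanism for indels
and serves as the comparison arm; it is a stand-in modelled on simple
exact-counting pipelines, not a reimplementation of any published tool.

## Numerical and scale choices

* Problem sizes in the test-suite: unit tests use 10-100 barcodes at
  500-20,000 reads; the end-to-end property checks run the full
  benchmark condition (500 barcodes, 100,000 reads, breadth 1000, depth
  5, k = 7) once per error rate and share the result across tests.
* k defaults to 8 for real data (recommended minimum for L = 12); the
  benchmark runs use k = 7, matching the real-data analysis setting of
  the original study design.
* The subsample default (500,000 reads) follows the observation that the
  k-mer count distribution is stable at that depth on Drop-seq-scale
  data; `count_stability()` (top-n Jaccard between two subsamples) is
  the diagnostic for tuning it, not a gate.
* All randomness (simulation, optional random subsampling) sits behind
  integer seeds; the search itself is deterministic, with lexicographic
  tie-breaks throughout.
* Degenerate inputs: k greater than the shortest variant is rejected;
  N-containing k-mers are generated but never indexed (an N cannot
  support a consensus); reads too short for the barcode window are
  skipped and counted.

## Known limitations

* Exactly periodic barcodes (period dividing L) are not callable (see
  the cycle-search section).
* Exponentially distributed cell abundances blur the capacity cliff, as
  low-abundance true cycles and high-weight error cycles overlap; the
  knee then under- or over-cuts. This mirrors the method's stated
  behaviour and is visible in the benchmark grid.
* Assignment accuracy decays with error rate faster than barcode
  identification does: a read with several errors may contain no
  error-free k-mer at all.
* The index is in-memory; datasets beyond ~10^7 reads should rely on the
  subsample contract rather than full indexing.
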