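# barcycle

Whitelist-free identification and error correction of single-cell
barcodes from Drop-seq-style sequencing reads.

Split-pool synthesized cell barcodes are short (typically 12 nt),
random, and frequently corrupted — not just by mismatches but by
deletions (which shift downstream bases into the fixed barcode window)
and insertions (which shift barcode bases out of it). `barcycle`
recovers the set of true barcodes and assigns every read to an
error-corrected consensus, without a barcode whitelist and without a
prior estimate of the cell count.

## Method in brief

For each read, the barcode window is circularized three ways — truncated
by one base (absorbs a deletion), exact, and extended by the first
downstream base (absorbs an insertion) — and all `(L−1) + L + (L+1) = 3L`
circular k-mers are enumerated (36 per read for L = 12). Circularization
guarantees that reads with ≤ 1 error always contribute error-free k-mers
of their true barcode, wherever the error falls.

A k-mer index over a subsample of reads drives a per-start-node search:
for each seed k-mer (most frequent first, skipping k-mers already covered
by a found path), the reads containing it are assembled into a weighted
de Bruijn graph over (k−1)-mers, where the weight of edge `u → v` counts
the observations of the k-mer `u + last(v)`. A cyclic path of L edges
spells a candidate barcode; its **capacity** — the minimum edge weight on
the cycle — scores its support. A greedy depth-first search
(`find_cycle()`) follows locally heaviest edges and returns the first
walk that closes in exactly L steps; `extract_cycles()` repeats it,
subtracting each cycle's capacity from its edges, up to `depth` cycles
per subgraph. Pooled cycles are linearized (rotation resolved by modal
in-read k-mer offsets) and deduplicated.

True barcode cycles have capacities near the per-cell read count while
spurious cycles sit near 1, so the rank-ordered cumulative capacity
curve shows a sharp inflection. `find_knee()` smooths the curve with a
Savitzky–Golay filter and thresholds at the interior curvature extremum
of largest magnitude (the local maximum of the first derivative of the
capacity–rank distribution); paths above the knee are the called
barcodes. Reads are then assigned by Levenshtein distance (default;
conservative) or by shared circular k-mers (`assign_reads()`).

The package also ships the benchmark machinery: a read simulator with
configurable abundance distributions and Poisson
insertion/deletion/mismatch errors (`generate_dataset()`), a TP/FP/FN
and read-assignment scorer (`score_barcodes()`), and a naive
exact-counting baseline (`naive_baseline()`).

## Worked example

Simulate 30 cells at one error per read on average, call barcodes, and
score against the ground truth:

```r
library(barcycle)

cfg <- simulation_config(n_barcodes = 30, n_reads = 5000,
                         error_lambda = 1, seed = 42)
sim <- generate_dataset(cfg)
sim
#> barcode_sim: 30 barcodes (L = 12), 5000 reads, lambda = 1 (any), normal abundance

paths <- call_barcodes(sim$windows, k = 7, L = 12,
                       breadth = 200, depth = 5)
knee <- find_knee(paths$capacity, window = 21)
knee
#> knee_threshold: 779 paths, knee at rank 31 (capacity 26), 30 accepted

called <- paths[paths$capacity > knee$threshold_capacity, ]
score_barcodes(called$barcode, sim)
#> benchmark_result: tp = 30, fp = 0, fn = 0

assignments <- assign_reads(sim$windows, called$barcode,
                            method = "levenshtein", max_dist = 2)
score_barcodes(called$barcode, sim, assignments)
#> benchmark_result: tp = 30, fp = 0, fn = 0
#>   reads: 84.3% correct, 0.0% incorrect, 15.7% unassigned
```

The search pools 779 candidate cycles; the capacity knee at rank 31
separates the 30 true barcode cycles (capacities near the per-cell read
count) from spurious low-capacity ones, and all 30 true barcodes are
recovered with no false calls. Read assignment in the conservative
Levenshtein mode leaves ~16% of reads unassigned (mostly multi-error
reads) while mis-assigning essentially none. The
one-call pipeline `run_pipeline()` wraps the same steps (FASTQ input,
index, search, knee, assignment) and writes barcode, assignment, and
knee-diagnostic TSVs.

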