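#' Build a k-mer index over a subsample of reads
#'
#' Maps every (N-free) circularized k-mer to the reads that produced it,
#' together with the variant and circular offset of each occurrence, plus
#' per-k-mer occurrence counts. The index drives start-node selection
#' (frequent k-mers come from frequent barcodes) and per-start-node subgraph
#' construction. It is built from the head of the read stream by default;
#' indexing roughly half a million reads is enough for the count
#' distribution to stabilise on typical Drop-seq-scale data, which a seeded
#' random subsample mode and [count_stability()] let you check.
#'
#' @param windows a window table ([barcode_windows()]); the "stream", in
#'   input order.
#' @param k k-mer length (`k <= L - 1`).
#' @param subsample_size maximum number of reads to index (default 500000).
#' @param seed integer seed, used only when `method = "random"`.
#' @param method `"head"` (default; first `subsample_size` reads, matching
#'   head-based downsampling of a FASTQ) or `"random"` (seeded sample
#'   without replacement).
#' @return an object of class `kmer_index`: a list with elements `k`,
#'   `entries` (data.table `kmer`, `read_id`, `variant`, `offset`, keyed by
#'   `kmer`), `counts` (data.table `kmer`, `count`), `reads_indexed`,
#'   `subsample_size`, and `windows` (the indexed subsample).
#' @export
build_kmer_index <- function(windows, k, subsample_size = 500000L,
                             seed = 1L, method = c("head", "random")) {
  method <- match.arg(method)
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("empty input: no reads to index")
  }
  subsample_size <- as.integer(subsample_size)
  if (subsample_size < 1L) stop("subsample_size must be >= 1")
  n <- nrow(windows)
  if (n > subsample_size) {
    idx <- if (method == "head") {
      seq_len(subsample_size)
    } else {
      sort(withr_seed_sample(seed, n, subsample_size))
    }
    windows <- windows[idx]
  }
  entries <- positioned_kmers(windows, k)
  entries <- entries[valid == TRUE, .(kmer, read_id, variant, offset)]
  data.table::setkey(entries, kmer)
  counts <- entries[, .(count = .N), by = kmer]
  # per-read de Bruijn edge occurrences (one row per positioned k-mer: a
  # k-mer seen in several variants of one read counts each time, giving
  # edges on the exact cycle their 3:2:1 weight hierarchy over variant
  # wrap edges); precomputed once so per-start-node subgraphs are cheap
  # keyed subsets
  edges <- entries[, .(read_id,
                       u = substr(kmer, 1L, k - 1L),
                       v = substr(kmer, 2L, as.integer(k)))]
  data.table::setkey(edges, read_id)
  # modal EXACT-variant in-read offset per k-mer (rotation evidence for
  # linearizing cyclic paths); ties break to the smaller offset
  modal <- entries[variant == "EXACT", .(n = .N), by = .(kmer, offset)][
    order(kmer, -n, offset)][, .(offset = offset[1L]), by = kmer]
  data.table::setkey(modal, kmer)
  structure(list(k = as.integer(k), entries = entries, counts = counts,
                 read_edges = edges, exact_modal = modal,
                 reads_indexed = nrow(windows),
                 subsample_size = subsample_size,
                 windows = windows),
            class = "kmer_index")
}

# draw a size-m sample of 1..n under a local seed, without disturbing the
# caller's RNG stream
withr_seed_sample <- function(seed, n, m) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n, m)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d, %d reads indexed, %d distinct k-mers\n",
              x$k, x$reads_indexed, nrow(x$counts)))
  invisible(x)
}

#' Most frequent k-mers in an index
#'
#' Candidate start nodes for the cycle search, in descending count order
#' with lexicographic tie-breaking (deterministic).
#'
#' @param index a `kmer_index`.
#' @param n number of k-mers to return (fewer if the index is smaller).
#' @return character vector of k-mer strings.
#' @export
top_kmers <- function(index, n) {
  stopifnot(inherits(index, "kmer_index"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  cnt <- index$counts[order(-count, kmer)]
  utils::head(cnt$kmer, n)
}

#' Jaccard stability of the top k-mer sets of two indexes
#'
#' A diagnostic for choosing the subsample size: two disjoint subsamples of
#' a dataset that has been sampled deeply enough share nearly all of their
#' frequent k-mers.
#'
#' @param index_a,index_b two `kmer_index` objects built with the same `k`.
#' @param top_n number of top k-mers to compare.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
count_stability <- function(index_a, index_b, top_n) {
  stopifnot(inherits(index_a, "kmer_index"), inherits(index_b, "kmer_index"))
  if (index_a$k != index_b$k) {
    stop("invalid comparison: indexes were built with different k (",
         index_a$k, " vs ", index_b$k, ")")
  }
  a <- top_kmers(index_a, top_n)
  b <- top_kmers(index_b, top_n)
  length(intersect(a, b)) / length(union(a, b))
}

#' Serialize / restore a k-mer index as plain text
#'
#' Round-trips exactly: the restored index is identical to the original.
#'
#' @param index a `kmer_index`.
#' @param path file path (a `.tsv`-style text file).
#' @return `write_kmer_index` returns `path` invisibly; `read_kmer_index`
#'   returns the restored `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  hdr <- sprintf("#kmer_index\tk=%d\treads_indexed=%d\tsubsample_size=%d",
                 index$k, index$reads_indexed, index$subsample_size)
  writeLines(hdr, path)
  suppressWarnings(data.table::fwrite(
    index$windows, path, sep = "\t", append = TRUE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#kmer_index")) stop("not a kmer_index file: ", path)
  kv <- strsplit(strsplit(hdr, "\t")[[1]][-1], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  windows <- data.table::fread(path, sep = "\t", skip = 1L,
                               colClasses = list(character = "next_base"))
  windows[next_base == "", next_base := NA_character_]
  build_kmer_index(windows, k = as.integer(vals[["k"]]),
                   subsample_size = as.integer(vals[["subsample_size"]]))
}
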