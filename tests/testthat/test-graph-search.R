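# build an L-cycle edge table over arbitrary labels
ring_edges <- function(labels, w) {
  data.frame(u = labels, v = c(labels[-1], labels[1]), w = w,
             stringsAsFactors = FALSE)
}

test_that("a single uniform cycle is found with its capacity", {
  labs <- sprintf("x%02d", 1:12)
  g <- subgraph_from_edges(ring_edges(labs, 7))
  cyc <- find_cycle(g, "x01", 12)
  expect_equal(cyc$nodes, labs)
  expect_equal(cyc$capacity, 7)
  # requesting a length the graph cannot close returns absent
  g10 <- subgraph_from_edges(ring_edges(sprintf("y%02d", 1:10), 5))
  expect_null(find_cycle(g10, "y01", 12))
})

test_that("greedy search prefers the heavy cycle over a light detour", {
  labs <- sprintf("x%02d", 1:12)
  heavy <- ring_edges(labs, 100)
  # light detour: leaves the cycle at x03, rejoins at x06, same length
  detour <- data.frame(u = c("x03", "d1", "d2"), v = c("d1", "d2", "x06"),
                       w = 1, stringsAsFactors = FALSE)
  g <- subgraph_from_edges(rbind(heavy, detour))
  cyc <- find_cycle(g, "x01", 12)
  expect_equal(cyc$nodes, labs)
  expect_equal(cyc$capacity, 100)
  # agrees with the brute-force greedy-first oracle
  oracle <- greedy_first_walk(enumerate_closed_walks(rbind(heavy, detour),
                                                     "x01", 12))
  expect_equal(cyc$nodes, oracle$nodes[1:12])
  expect_equal(cyc$capacity, min(oracle$wts))
})

test_that("find_cycle matches the brute-force oracle on random small graphs", {
  set.seed(501)
  checked <- 0L
  for (i in 1:40) {
    e <- random_small_graph(n_nodes = sample(6:12, 1),
                            n_edges = sample(12:30, 1))
    start <- e$u[1]
    g <- subgraph_from_edges(e)
    L <- sample(c(4L, 6L, 12L), 1)
    got <- find_cycle(g, start, L)
    oracle <- greedy_first_walk(enumerate_closed_walks(e, start, L))
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      checked <- checked + 1L
      expect_equal(got$nodes, oracle$nodes[1:L])
      expect_equal(got$capacity, min(oracle$wts))
    }
  }
  expect_gt(checked, 5L)
})

test_that("extract_cycles pulls disjoint cycles heaviest-first and conserves weight", {
  a <- sprintf("a%02d", 1:11)
  b <- sprintf("b%02d", 1:11)
  e <- rbind(ring_edges(c("s", a), 40), ring_edges(c("s", b), 100))
  g <- subgraph_from_edges(e)
  cys <- extract_cycles(g, "s", 12, max_paths = 5)
  expect_length(cys, 2L)
  expect_equal(vapply(cys, `[[`, 0, "capacity"), c(100, 40))
  expect_equal(cys[[1]]$nodes, c("s", b))
  expect_equal(cys[[2]]$nodes, c("s", a))
  # decrement bookkeeping: removed weight = capacity * cycle length,
  # nothing negative, and each extracted cycle's minimum edge is now 0
  resid <- attr(cys, "residual_edges")
  expect_true(all(resid$w >= 0))
  removed <- sum(e$w) - sum(resid$w)
  expect_equal(removed, 100 * 12 + 40 * 12)
  expect_equal(nrow(resid), 0L)  # both rings fully consumed here
  # single cycle with max_paths = 5 stops after exhaustion
  g1 <- subgraph_from_edges(ring_edges(c("s", a), 9))
  cys1 <- extract_cycles(g1, "s", 12, max_paths = 5)
  expect_length(cys1, 1L)
})

test_that("subgraphs from error-free reads contain the barcode cycle at full weight", {
  bc <- "ATCGGCTAAGTC"
  w <- barcode_windows(sprintf("r%02d", 1:50), rep(bc, 50), "T")
  idx <- build_kmer_index(w, k = 7)
  seed_kmer <- circular_kmers(bc, 7)$kmer[1]
  g <- build_subgraph(seed_kmer, idx)
  cyc <- find_cycle(g, substr(seed_kmer, 1, 6), 12)
  expect_equal(cyc$capacity, 50)
  # every edge of the found cycle carries all 50 reads
  cyc_edges <- data.table::data.table(u = cyc$nodes,
                                      v = cyc$nodes[c(2:12, 1)])
  found <- g$edges[cyc_edges, on = c("u", "v")]
  expect_true(all(found$w >= 50))
  # absent start k-mer is a not-found error
  expect_error(build_subgraph("GGGGGGG", idx), "not found")
})

test_that("linearize undoes the cycle rotation for every seed position", {
  bc <- "ATCGGCTAAGTC"
  w <- barcode_windows(sprintf("r%02d", 1:30), rep(bc, 30), "G")
  idx <- build_kmer_index(w, k = 7)
  for (seed_kmer in circular_kmers(bc, 7)$kmer) {
    g <- build_subgraph(seed_kmer, idx)
    cyc <- find_cycle(g, substr(seed_kmer, 1, 6), 12)
    lin <- linearize(cyc, idx)
    expect_equal(lin$barcode, bc)
    expect_false(lin$flagged)
  }
})

test_that("linearize falls back to the smallest rotation without evidence", {
  bc <- "ATCGGCTAAGTC"
  w <- barcode_windows("r1", "TTTTTTTTTTTT", "T")
  idx <- build_kmer_index(w, k = 7)  # no evidence for bc's k-mers
  nodes <- substring(paste0(bc, bc), 1:12, 1:12 + 5)
  lin <- linearize(nodes, idx)
  expect_true(lin$flagged)
  rots <- substring(paste0(bc, bc), 1:12, 1:12 + 11)
  expect_equal(lin$barcode, min(rots))
})

test_that("linearize recovers the barcode from error-containing reads", {
  sim <- small_sim(n_barcodes = 1, n_reads = 500, lambda = 1, seed = 13)
  bc <- sim$barcodes
  idx <- build_kmer_index(sim$windows, k = 7)
  seed_kmer <- top_kmers(idx, 1)
  g <- build_subgraph(seed_kmer, idx)
  cyc <- find_cycle(g, substr(seed_kmer, 1, 6), 12)
  expect_equal(linearize(cyc, idx)$barcode, bc)
})

test_that("three separated barcodes give three cycles, each decoding itself", {
  sim <- small_sim(n_barcodes = 3, n_reads = 3000, lambda = 1, seed = 21)
  paths <- call_barcodes(sim$windows, k = 7, L = 12, breadth = 50, depth = 5)
  expect_setequal(intersect(paths$barcode, sim$barcodes), sim$barcodes)
  # the three heaviest paths are the three true barcodes
  expect_setequal(paths$barcode[1:3], sim$barcodes)
})

test_that("call_barcodes deduplicates pooled paths by barcode string", {
  w <- barcode_windows(sprintf("r%02d", 1:40), rep("ATCGGCTAAGTC", 40), "A")
  paths <- call_barcodes(w, k = 7, L = 12, breadth = 10, depth = 5)
  # many seeds decode the same barcode; pooled output has one entry
  expect_equal(nrow(paths), sum(paths$barcode == "ATCGGCTAAGTC"))
  expect_equal(paths$barcode[1], "ATCGGCTAAGTC")
  # breadth = 1 still finds it
  p1 <- call_barcodes(w, k = 7, L = 12, breadth = 1, depth = 5)
  expect_equal(p1$barcode[1], "ATCGGCTAAGTC")
})
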