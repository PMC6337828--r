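# Independent oracles used to check the implementation from a second route.

# circular k-mer enumeration by explicit string rotation
rotate_oracle_kmers <- function(s, k) {
  n <- nchar(s)
  vapply(seq_len(n) - 1L, function(off) {
    rot <- paste0(substr(s, off + 1L, n), substr(s, 1L, off))
    substr(rot, 1L, k)
  }, "")
}

# all closed walks of exactly L edges from `start` in a weighted digraph
# given as a data.frame(u, v, w); plain recursion, no ordering, no
# pruning. The start node is only re-entered on the final edge (entering
# it closes the walk).
enumerate_closed_walks <- function(edges, start, L) {
  edges <- edges[edges$w > 0, ]
  out <- list()
  recurse <- function(node, path, wts) {
    if (length(path) == L + 1L) {
      if (node == start) out[[length(out) + 1L]] <<- list(nodes = path, wts = wts)
      return(invisible())
    }
    rows <- which(edges$u == node)
    for (r in rows) {
      if (edges$v[r] == start && length(path) < L) next
      recurse(edges$v[r], c(path, edges$v[r]), c(wts, edges$w[r]))
    }
  }
  recurse(start, start, numeric(0))
  out
}

# among enumerated closed walks, the one a greedy descending-weight DFS
# (ties lexicographic by child) would visit first: order walks by their
# step-wise choice sequence
greedy_first_walk <- function(walks) {
  if (length(walks) == 0L) return(NULL)
  precedes <- function(a, b) {
    for (j in seq_along(a$wts)) {
      if (a$wts[j] != b$wts[j]) return(a$wts[j] > b$wts[j])
      if (a$nodes[j + 1L] != b$nodes[j + 1L]) return(a$nodes[j + 1L] < b$nodes[j + 1L])
    }
    FALSE
  }
  best <- walks[[1L]]
  for (wk in walks[-1L]) if (precedes(wk, best)) best <- wk
  best
}

# random small weighted digraph over fake node labels
random_small_graph <- function(n_nodes, n_edges, max_w = 20L) {
  labels <- paste0("n", sprintf("%02d", seq_len(n_nodes)))
  u <- sample(labels, n_edges, replace = TRUE)
  v <- sample(labels, n_edges, replace = TRUE)
  e <- unique(data.frame(u = u, v = v, stringsAsFactors = FALSE))
  e$w <- sample.int(max_w, nrow(e), replace = TRUE)
  e
}
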