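#' Per-start-node de Bruijn subgraphs and greedy cycle extraction
#'
#' Rather than building one de Bruijn graph of the whole dataset, a fresh
#' subgraph is built for every start k-mer: the index is queried for reads
#' containing the start k-mer in any of its circular rotations, and a
#' directed weighted graph over (k-1)-mer nodes is built from just those
#' reads. A cyclic path of length L through this graph spells a candidate
#' barcode of length L; its capacity (minimum edge weight) ranks how well
#' the data support it. Cycles are pulled out greedily: a depth-first
#' search that visits children in descending edge-weight order finds the
#' heaviest cycle first, the cycle's capacity is subtracted from its edges
#' (breaking it and removing its contribution to shared edges), and the
#' search repeats until no cycle remains or the search depth is exhausted.
#'
#' @name graph_search
#' @keywords internal
NULL

#' Build the de Bruijn subgraph seeded by one start k-mer
#'
#' Nodes are (k-1)-mers; a directed edge `u -> v` records that `u` and `v`
#' are the consecutive (k-1)-mers of a k-mer observed in a contributing
#' read, oriented 5' to 3'. The weight of an edge is the number of times
#' its k-mer was observed across all circularization variants and
#' positions of the contributing reads: k-mers in the linear region of a
#' barcode recur in all three variants while variant wrap k-mers occur in
#' only one, and this 3:2:1 hierarchy is what steers the greedy cycle
#' search along the exact barcode cycle. K-mers containing N are
#' excluded. Only reads whose positioned k-mer set contains `start_kmer`
#' or one of its circular rotations contribute.
#'
#' @param start_kmer the seeding k-mer (length `index$k`); must be indexed.
#' @param index a [build_kmer_index()] result.
#' @param reads optional window table to draw contributing reads from;
#'   defaults to the subsample held by the index. Must contain every
#'   read_id the index reports for the start k-mer.
#' @return an object of class `debruijn_subgraph`: list with `k`, `edges`
#'   (data.table `u`, `v`, `w`), `nodes`, `start_kmer`, `n_reads`.
#' @export
build_subgraph <- function(start_kmer, index, reads = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  if (nchar(start_kmer) != k) stop("start_kmer must have length k = ", k)
  rots <- kmer_rotations(start_kmer)
  hits <- index$entries[data.table::CJ(kmer = rots), on = "kmer",
                        nomatch = NULL]
  if (nrow(hits) == 0L) {
    stop("not found: start k-mer ", start_kmer,
         " (or its rotations) has no reads in the index")
  }
  ids <- unique(hits$read_id)
  if (is.null(reads)) {
    # fast path: keyed subset of the index's precomputed per-read edges
    re <- index$read_edges[data.table::data.table(read_id = ids),
                           on = "read_id", nomatch = NULL]
  } else {
    win <- reads[data.table::data.table(read_id = ids), on = "read_id",
                 nomatch = NULL]
    pk <- positioned_kmers(win, k)
    pk <- pk[valid == TRUE]
    pk[, `:=`(u = substr(kmer, 1L, k - 1L), v = substr(kmer, 2L, k))]
    re <- pk[, .(read_id, u, v)]
  }
  # weight = occurrence count across all variants and positions: k-mers on
  # the exact cycle recur across variants (weight hierarchy 3:2:1 over
  # truncated/extended wrap edges), which steers the greedy search along
  # the true barcode cycle
  edges <- re[, .(w = as.numeric(.N)), by = .(u, v)]
  structure(list(k = k, edges = edges,
                 nodes = union(edges$u, edges$v),
                 start_kmer = start_kmer, n_reads = length(ids)),
            class = "debruijn_subgraph")
}

#' @export
print.debruijn_subgraph <- function(x, ...) {
  cat(sprintf("debruijn_subgraph: start %s, %d nodes, %d edges, %d reads\n",
              x$start_kmer, length(x$nodes), nrow(x$edges), x$n_reads))
  invisible(x)
}

#' Construct a subgraph directly from an edge table
#'
#' Mainly for tests and worked examples: wraps a hand-built weighted edge
#' list in the `debruijn_subgraph` container.
#'
#' @param edges data.frame/data.table with columns `u`, `v`, `w`.
#' @param k k-mer length implied by the node labels (`nchar(u) + 1`).
#' @param start_kmer optional seeding k-mer label.
#' @return a `debruijn_subgraph`.
#' @export
subgraph_from_edges <- function(edges, k = nchar(edges$u[1L]) + 1L,
                                start_kmer = NA_character_) {
  edges <- data.table::as.data.table(edges)[, .(u, v, w = as.numeric(w))]
  if (any(edges$w < 0)) stop("edge weights must be non-negative")
  structure(list(k = as.integer(k), edges = edges,
                 nodes = union(edges$u, edges$v),
                 start_kmer = start_kmer, n_reads = NA_integer_),
            class = "debruijn_subgraph")
}

# adjacency as hashed environments: fwd maps node -> list(v = children,
# w = weights) with children ordered by descending weight, ties
# lexicographic; rev maps node -> predecessor labels. Zero-weight edges
# are dropped (a fully decremented edge is removed from the graph).
.build_adj <- function(edges) {
  keep <- edges$w > 0
  u <- edges$u[keep]; v <- edges$v[keep]; wt <- edges$w[keep]
  fwd <- new.env(hash = TRUE, parent = emptyenv())
  rev <- new.env(hash = TRUE, parent = emptyenv())
  if (length(u) > 0L) {
    o <- order(u, -wt, v, method = "radix")
    u <- u[o]; v <- v[o]; wt <- wt[o]
    st <- which(!duplicated(u))
    en <- c(st[-1L] - 1L, length(u))
    for (g in seq_along(st)) {
      rng <- st[g]:en[g]
      assign(u[st[g]], list(v = v[rng], w = wt[rng]), envir = fwd)
    }
    o2 <- order(v, method = "radix")
    v2 <- v[o2]; u2 <- u[o2]
    st2 <- which(!duplicated(v2))
    en2 <- c(st2[-1L] - 1L, length(v2))
    for (g in seq_along(st2)) {
      assign(v2[st2[g]], u2[st2[g]:en2[g]], envir = rev)
    }
  }
  list(fwd = fwd, rev = rev)
}

# minimum number of steps needed to reach `target` from each node, by
# breadth-first search over reversed edges. Used to prune DFS branches
# that provably cannot close the cycle in the remaining steps; such
# branches would be exhaustively rejected anyway, so pruning does not
# change which cycle the greedy search finds first.
.dist_env <- function(adj, target) {
  dist <- new.env(hash = TRUE, parent = emptyenv())
  assign(target, 0L, envir = dist)
  frontier <- target
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character(0)
    for (nd in frontier) {
      for (p in adj$rev[[nd]]) {
        if (is.null(dist[[p]])) {
          assign(p, d, envir = dist)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# greedy depth-first search for one closed walk of exactly L edges from
# start_node; returns list(nodes, wts) or NULL
.find_cycle_env <- function(adj, start_node, L, dist = NULL) {
  if (is.null(dist)) dist <- .dist_env(adj, start_node)
  path <- character(L)
  wts <- numeric(L)
  fwd <- adj$fwd
  dfs <- function(node, depth) {
    if (depth == L) return(node == start_node)
    ch <- fwd[[node]]
    if (is.null(ch)) return(FALSE)
    rem <- L - depth - 1L
    for (i in seq_along(ch$v)) {
      child <- ch$v[i]
      # the walk may revisit intermediate nodes, but reaching the start
      # node closes the cycle: passing through it early would let a heavy
      # short cycle be traversed repeatedly into a spurious periodic
      # length-L walk
      if (child == start_node && rem > 0L) next
      dd <- dist[[child]]
      if (is.null(dd) || dd > rem) next
      path[depth + 1L] <<- child
      wts[depth + 1L] <<- ch$w[i]
      if (dfs(child, depth + 1L)) return(TRUE)
    }
    FALSE
  }
  if (!dfs(start_node, 0L)) return(NULL)
  list(nodes = c(start_node, path[-L]), wts = wts)
}

# subtract cap from each distinct edge of a cycle, dropping edges that
# reach 0 and keeping children sorted by (-w, v)
.decrement_adj <- function(adj, nodes, cap) {
  nxt <- c(nodes[-1L], nodes[1L])
  eu <- nodes
  ev <- nxt
  seen <- paste0(eu, ">", ev)
  keep <- !duplicated(seen)
  for (j in which(keep)) {
    u <- eu[j]; v0 <- ev[j]
    ch <- adj$fwd[[u]]
    i <- match(v0, ch$v)
    ch$w[i] <- ch$w[i] - cap
    if (ch$w[i] <= 0) {
      ch$v <- ch$v[-i]; ch$w <- ch$w[-i]
      preds <- adj$rev[[v0]]
      preds <- preds[preds != u]
      if (length(preds)) assign(v0, preds, envir = adj$rev)
      else rm(list = v0, envir = adj$rev)
    }
    if (length(ch$v) == 0L) {
      rm(list = u, envir = adj$fwd)
    } else {
      o <- order(-ch$w, ch$v)
      assign(u, list(v = ch$v[o], w = ch$w[o]), envir = adj$fwd)
    }
  }
  adj
}

# edge table of the (residual) adjacency
.adj_edges <- function(adj) {
  us <- ls(adj$fwd)
  if (length(us) == 0L) {
    return(data.table::data.table(u = character(0), v = character(0),
                                  w = numeric(0)))
  }
  chs <- lapply(us, function(x) adj$fwd[[x]])
  nch <- vapply(chs, function(c) length(c$v), 1L)
  data.table::data.table(
    u = rep(us, nch),
    v = unlist(lapply(chs, `[[`, "v"), use.names = FALSE),
    w = unlist(lapply(chs, `[[`, "w"), use.names = FALSE))
}

#' Find one fixed-length cycle by greedy depth-first search
#'
#' Starting from `start_node`, outgoing edges are explored in descending
#' weight order (ties broken lexicographically by child label), for exactly
#' `length` steps; if the walk returns to the start node at step `length`,
#' a cycle has been found and is returned immediately. Dead ends backtrack.
#' Intermediate nodes may be revisited (closed walks are allowed: short
#' barcodes can legitimately repeat (k-1)-mers), but the start node may
#' not be re-entered before the final step: reaching it closes the cycle,
#' and permitting early passes would let a heavy short cycle be traversed
#' repeatedly into a spurious periodic walk. Edges of weight 0 are never
#' traversed.
#'
#' @param graph a `debruijn_subgraph`.
#' @param start_node a (k-1)-mer present in the graph.
#' @param length required cycle length in edges (the barcode length L).
#' @return a list of class `cyclic_path` with `nodes` (the L node labels,
#'   beginning at `start_node`), `capacity` (minimum edge weight along the
#'   cycle at extraction time) and `start_kmer`; or `NULL` if no cycle of
#'   the required length exists.
#' @export
find_cycle <- function(graph, start_node, length) {
  stopifnot(inherits(graph, "debruijn_subgraph"))
  L <- as.integer(length)
  if (L < 2L) stop("cycle length must be >= 2")
  if (!start_node %in% graph$nodes) {
    stop("start_node ", start_node, " is not in the graph")
  }
  adj <- .build_adj(graph$edges)
  res <- .find_cycle_env(adj, start_node, L)
  if (is.null(res)) return(NULL)
  structure(list(nodes = res$nodes, capacity = min(res$wts),
                 start_kmer = graph$start_kmer),
            class = "cyclic_path")
}

#' @export
print.cyclic_path <- function(x, ...) {
  cat(sprintf("cyclic_path: %d nodes, capacity %g\n",
              length(x$nodes), x$capacity))
  invisible(x)
}

#' Extract successive cycles, decrementing by capacity
#'
#' Repeatedly runs [find_cycle()]; after each success the cycle's capacity
#' is subtracted from every edge on it, which drives its minimum edge to 0
#' (breaking the cycle) while removing that cycle's contribution to any
#' shared edges. Stops when no further cycle exists or `max_paths` cycles
#' have been extracted. Each returned path records its capacity at the
#' moment of extraction.
#'
#' @param graph a `debruijn_subgraph` (not modified; a residual copy is
#'   used internally).
#' @param start_node a (k-1)-mer present in the graph.
#' @param length cycle length L.
#' @param max_paths maximum number of cycles to extract (the search depth).
#' @return list of `cyclic_path` objects, in extraction order.
#' @export
extract_cycles <- function(graph, start_node, length, max_paths) {
  stopifnot(inherits(graph, "debruijn_subgraph"))
  max_paths <- as.integer(max_paths)
  if (max_paths < 1L) stop("max_paths must be >= 1")
  L <- as.integer(length)
  if (!start_node %in% graph$nodes) {
    stop("start_node ", start_node, " is not in the graph")
  }
  adj <- .build_adj(graph$edges)
  # distances can only grow as edges are removed, so reusing the initial
  # map across iterations only weakens the prune; results are unchanged
  dist <- .dist_env(adj, start_node)
  out <- list()
  for (i in seq_len(max_paths)) {
    res <- .find_cycle_env(adj, start_node, L, dist = dist)
    if (is.null(res)) break
    cap <- min(res$wts)
    out[[i]] <- structure(list(nodes = res$nodes, capacity = cap,
                               start_kmer = graph$start_kmer),
                          class = "cyclic_path")
    adj <- .decrement_adj(adj, res$nodes, cap)
  }
  attr(out, "residual_edges") <- .adj_edges(adj)
  out
}

#' Resolve a cyclic path's rotation into a linear barcode
#'
#' A length-L cycle spells a circular string; the true barcode is one of
#' its L rotations. Each k-mer on the cycle is looked up in the index, and
#' its modal EXACT-variant in-read offset votes for the rotation that would
#' place it at that offset (an error-free read's exact variant starts at
#' offset 0, grounding the vote). The majority rotation wins; ties break to
#' the lexicographically smaller rotation. With no offset evidence at all,
#' the lexicographically smallest rotation is returned and flagged.
#'
#' @param path_nodes ordered node labels of a valid L-cycle (a
#'   `cyclic_path` or its `nodes`).
#' @param index the `kmer_index` holding offset evidence.
#' @return list with `barcode` (length-L string) and `flagged` (TRUE when
#'   the fallback rotation was used).
#' @export
linearize <- function(path_nodes, index) {
  if (inherits(path_nodes, "cyclic_path")) path_nodes <- path_nodes$nodes
  L <- length(path_nodes)
  k <- index$k
  nxt <- c(path_nodes[-1L], path_nodes[1L])
  cyc_kmers <- paste0(path_nodes, substr(nxt, k - 1L, k - 1L))
  spelled <- paste(substr(path_nodes, 1L, 1L), collapse = "")
  rotations <- function(s) substring(paste0(s, s), seq_len(L), seq_len(L) + L - 1L)
  # modal exact offset per cycle k-mer -> vote for the cycle's rotation
  off <- index$exact_modal[data.table::data.table(kmer = cyc_kmers),
                           on = "kmer", offset]
  has <- !is.na(off)
  if (!any(has)) {
    return(list(barcode = min(rotations(spelled)), flagged = TRUE))
  }
  votes <- (off[has] - (which(has) - 1L)) %% L
  tab <- sort(table(votes), decreasing = TRUE)
  best <- as.integer(names(tab)[tab == tab[1L]])
  cand <- vapply(best, function(r0) {
    st <- ((0L - r0) %% L) + 1L
    substr(paste0(spelled, spelled), st, st + L - 1L)
  }, "")
  list(barcode = min(cand), flagged = FALSE)
}

#' Call candidate barcodes from a read set
#'
#' The full search: index the reads, then repeatedly seed a subgraph from
#' the most frequent k-mer not yet covered by an extracted path (searches
#' start from a new node each time), extract up to `depth` cycles of
#' length L from each of `breadth` subgraphs, linearize every cycle, and
#' pool. A k-mer is covered once it lies on the exact or truncated
#' circularization of a called barcode, or is a rotation of an already
#' used seed, so the search breadth is spent discovering new barcodes
#' rather than re-deriving ones already called. Cycles that linearize to
#' the same barcode string are deduplicated keeping the highest capacity
#' (summing would double-count shared reads).
#'
#' @param reads a window table ([barcode_windows()]).
#' @param k k-mer length for the graph (Drop-seq: 7 or 8; must be
#'   `<= L - 1`).
#' @param L barcode length (cycle length).
#' @param breadth number of start k-mers (subgraphs) to search.
#' @param depth maximum cycles extracted per subgraph.
#' @param subsample_size reads to index (see [build_kmer_index()]).
#' @param seed integer seed (used for the random subsample mode only; the
#'   search itself is deterministic).
#' @param index optionally, a prebuilt `kmer_index` to reuse.
#' @return `data.table` with one row per distinct called barcode:
#'   `barcode`, `capacity`, `start_kmer`, `flagged`, ordered by descending
#'   capacity.
#' @export
call_barcodes <- function(reads, k, L, breadth = 1000L, depth = 5L,
                          subsample_size = 500000L, seed = 1L,
                          index = NULL) {
  k <- as.integer(k); L <- as.integer(L)
  if (k > L - 1L) stop("invalid parameter: k must be <= L - 1")
  if (breadth < 1L || depth < 1L) stop("breadth and depth must be >= 1")
  if (is.null(index)) {
    index <- build_kmer_index(reads, k, subsample_size = subsample_size,
                              seed = seed)
  }
  # candidate seeds in descending count order; a seed is skipped when a
  # previously extracted path already covers it (searches start "from a
  # new node"), so the breadth is spent discovering new barcodes rather
  # than re-seeding ones already called
  starts <- top_kmers(index, nrow(index$counts))
  covered <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(kmers) for (m in kmers) assign(m, TRUE, envir = covered)
  bcs <- caps <- sks <- flags <- vector("list", breadth)
  n_built <- 0L
  for (sk in starts) {
    if (n_built >= breadth) break
    if (!is.null(covered[[sk]])) next
    mark(kmer_rotations(sk))  # rotations seed the identical subgraph
    n_built <- n_built + 1L
    g <- build_subgraph(sk, index)
    start_node <- substr(sk, 1L, k - 1L)
    if (!start_node %in% g$nodes) next
    cycles <- extract_cycles(g, start_node, L, depth)
    if (length(cycles) == 0L) next
    lins <- lapply(cycles, linearize, index = index)
    found <- vapply(lins, `[[`, "", "barcode")
    # only the first cycle is extracted at full weight; later cycles have
    # decrement-reduced capacities, so their barcodes stay eligible to be
    # re-seeded from their own (clean) subgraphs
    mark(circular_kmers(found[1L], k)$kmer)
    mark(circular_kmers(substr(found[1L], 1L, L - 1L), k)$kmer)
    bcs[[n_built]] <- found
    flags[[n_built]] <- vapply(lins, `[[`, TRUE, "flagged")
    caps[[n_built]] <- vapply(cycles, `[[`, 0, "capacity")
    sks[[n_built]] <- rep(sk, length(cycles))
  }
  paths <- data.table::data.table(
    barcode = unlist(bcs, use.names = FALSE),
    capacity = unlist(caps, use.names = FALSE),
    start_kmer = unlist(sks, use.names = FALSE),
    flagged = unlist(flags, use.names = FALSE))
  if (nrow(paths) == 0L) return(paths)
  # dedup identical barcodes, keep the best-supported occurrence
  paths <- paths[order(-capacity, barcode)][, utils::head(.SD, 1L),
                                            by = barcode]
  paths[order(-capacity, barcode)]
}

#' Dump a subgraph in DOT format
#'
#' For visual inspection of the k-mer graph (e.g. with graphviz).
#'
#' @param graph a `debruijn_subgraph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  stopifnot(inherits(graph, "debruijn_subgraph"))
  e <- graph$edges[w > 0]
  lines <- c("digraph debruijn {",
             sprintf('  "%s" -> "%s" [weight=%g, penwidth=%.2f];',
                     e$u, e$v, e$w, 0.5 + 2.5 * e$w / max(e$w)),
             "}")
  writeLines(lines, path)
  invisible(path)
}
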