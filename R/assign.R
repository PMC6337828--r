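#' Read-to-barcode assignment
#'
#' Once consensus barcodes are called, every read is assigned to one of
#' them or marked unassigned. Two modes are provided. K-mer mode counts
#' shared k-mer strings between the read's three circularization variants
#' and each consensus barcode's exact circular k-mers, assigning to the
#' unique maximum when it shares at least `min_shared` k-mers. Levenshtein
#' mode assigns to the unique nearest barcode by edit distance within
#' `max_dist`. Levenshtein mode is more conservative -- fewer incorrect
#' assignments at the cost of more unassigned reads -- and is the default.
#'
#' @name assign
#' @keywords internal
NULL

#' Levenshtein (edit) distance
#'
#' Unit-cost insertions, deletions and substitutions, via [utils::adist()].
#'
#' @param a,b character vectors (recycled to a common length when one is
#'   scalar); distances are computed elementwise.
#' @return integer vector of distances.
#' @export
#' @examples
#' levenshtein("ACGT", "AGT")  # 1
levenshtein <- function(a, b) {
  as.integer(mapply(function(x, y) drop(utils::adist(x, y)), a, b,
                    USE.NAMES = FALSE))
}

#' Hamming distance between equal-length strings
#'
#' Number of substituted positions; undefined (an error) for unequal
#' lengths.
#'
#' @param a,b character vectors, elementwise pairs of equal length.
#' @return integer vector of distances.
#' @export
hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    stop("invalid input: hamming distance requires equal-length strings")
  }
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

# Pairwise Levenshtein of many windows against few barcodes, chunked to
# bound memory; returns per-window min distance, argmin and tie flag.
.lev_nearest <- function(windows, barcodes, chunk = 4000L) {
  n <- length(windows)
  mind <- integer(n); arg <- integer(n); tie <- logical(n)
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    D <- utils::adist(windows[st:en], barcodes)
    mind[st:en] <- apply(D, 1L, min)
    arg[st:en] <- max.col(-D, ties.method = "first")
    tie[st:en] <- rowSums(D == mind[st:en]) > 1L
  }
  list(min = mind, arg = arg, tie = tie)
}

#' Assign reads to consensus barcodes by Levenshtein distance
#'
#' Each read is assigned to the barcode at minimum edit distance from its
#' window, provided that minimum is at most `max_dist` and uniquely
#' attained; ties and far reads are left unassigned. The default
#' `max_dist = 2` is the largest radius at which chance collisions between
#' random 12-mers remain rare.
#'
#' @param windows a window table ([barcode_windows()]), or a character
#'   vector of window sequences.
#' @param barcodes character vector of consensus barcode sequences.
#' @param max_dist maximum accepted edit distance (default 2).
#' @return a `data.table` with columns `read_id`, `barcode` (`NA` when
#'   unassigned), `method` (`"LEVENSHTEIN"`), `score` (the edit distance;
#'   `NA` when unassigned).
#' @export
assign_by_levenshtein <- function(windows, barcodes, max_dist = 2L) {
  if (length(barcodes) == 0L) stop("barcodes must be non-empty")
  if (is.character(windows)) {
    windows <- data.table::data.table(
      read_id = seq_along(windows), bases = windows)
  }
  uw <- unique(windows$bases)
  nn <- .lev_nearest(uw, barcodes)
  ok <- nn$min <= max_dist & !nn$tie
  lut <- data.table::data.table(
    bases = uw,
    barcode = ifelse(ok, barcodes[nn$arg], NA_character_),
    score = ifelse(ok, nn$min, NA_integer_))
  out <- lut[windows[, .(read_id, bases)], on = "bases"]
  out[, .(read_id, barcode, method = "LEVENSHTEIN", score)]
}

#' Assign reads to consensus barcodes by shared k-mers
#'
#' Counts distinct k-mer strings shared between the read's three
#' circularization variants and each consensus barcode's exact circular
#' k-mer set (a consensus has no errors to absorb, so only its exact
#' circularization is used). The read is assigned to the barcode sharing
#' the most k-mers when that count is at least `min_shared` and the
#' maximum is unique; otherwise it is unassigned. A larger `k_assign` than
#' the graph k raises stringency.
#'
#' @param windows a window table ([barcode_windows()]).
#' @param barcodes character vector of consensus barcode sequences.
#' @param k_assign k-mer length for assignment (`<= L - 1`).
#' @param min_shared minimum shared k-mer count (default 2).
#' @return a `data.table` with columns `read_id`, `barcode` (`NA` when
#'   unassigned), `method` (`"KMER"`), `score` (shared-k-mer count; `NA`
#'   when unassigned).
#' @export
assign_by_kmers <- function(windows, barcodes, k_assign, min_shared = 2L) {
  if (length(barcodes) == 0L) stop("barcodes must be non-empty")
  bk <- data.table::rbindlist(lapply(seq_along(barcodes), function(i) {
    data.table::data.table(kmer = unique(circular_kmers(barcodes[i], k_assign)$kmer),
                           bc = i)
  }))
  # distinct (window, kmer) pairs over unique window sequences
  uwin <- unique(windows[, .(bases, next_base)])
  uwin[, uid := .I]
  pk <- positioned_kmers(
    barcode_windows(uwin$uid, uwin$bases, uwin$next_base), k_assign)
  pk <- unique(pk[valid == TRUE, .(read_id, kmer)])
  shared <- pk[bk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE][
    , .(score = .N), by = .(read_id, bc)]
  if (nrow(shared) == 0L) {
    lut <- data.table::data.table(uid = integer(0), barcode = character(0),
                                  score = integer(0))
  } else {
    best <- shared[order(read_id, -score, bc)]
    best[, rank := seq_len(.N), by = read_id]
    top <- data.table::dcast(best[rank <= 2L], read_id ~ rank,
                             value.var = c("score", "bc"))
    if (!"score_2" %in% names(top)) top[, score_2 := NA_integer_]
    top[, unique_max := is.na(score_2) | score_1 > score_2]
    top <- top[score_1 >= min_shared & unique_max]
    lut <- data.table::data.table(
      uid = top$read_id, barcode = barcodes[top$bc_1], score = top$score_1)
  }
  out <- merge(uwin, lut, by = "uid", all.x = TRUE)
  res <- out[windows, on = c("bases", "next_base")]
  res[, .(read_id, barcode, method = "KMER", score)]
}

utils::globalVariables(c("uid", "bc", "rank", "score_1", "score_2", "bc_1",
                         "unique_max", "i.read_id"))

#' Assign every read by the chosen method
#'
#' Thin dispatcher over [assign_by_levenshtein()] (the default) and
#' [assign_by_kmers()].
#'
#' @param windows a window table.
#' @param barcodes consensus barcode sequences.
#' @param method `"levenshtein"` or `"kmer"`.
#' @param max_dist,k_assign,min_shared passed to the respective method.
#' @return assignment `data.table` (see the method functions).
#' @export
assign_reads <- function(windows, barcodes,
                         method = c("levenshtein", "kmer"),
                         max_dist = 2L, k_assign = NULL, min_shared = 2L) {
  method <- match.arg(method)
  if (method == "levenshtein") {
    assign_by_levenshtein(windows, barcodes, max_dist = max_dist)
  } else {
    if (is.null(k_assign)) {
      stop("k_assign must be supplied for k-mer assignment")
    }
    assign_by_kmers(windows, barcodes, k_assign = k_assign,
                    min_shared = min_shared)
  }
}
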