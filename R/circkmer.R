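#' Circularized k-mer fingerprints of barcode windows
#'
#' A cell barcode is short (typically 12 nt) relative to a useful k-mer size
#' (k >= 7), so a single error at many positions would corrupt every linear
#' k-mer of the window. Treating the window as a circular string guarantees
#' that a single mismatch leaves `L - k` contiguous error-free k-mers
#' somewhere on the circle. Deletions and insertions shift downstream bases
#' into or out of the fixed window, so two additional circularization
#' variants are enumerated: the window truncated by its last base (absorbs
#' one deletion) and the window extended by the first base downstream of it
#' (absorbs one insertion). Every read therefore contributes
#' `(L-1) + L + (L+1) = 3L` positioned k-mers (36 for Drop-seq's L = 12).
#'
#' @name circkmer
#' @keywords internal
NULL

.DNA_OK <- c("A", "C", "G", "T", "N")

#' Validate and normalise a DNA string
#'
#' Uppercases the input and rejects characters outside `{A,C,G,T,N}`.
#'
#' @param x character vector of sequences.
#' @return uppercased character vector.
#' @keywords internal
normalize_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid alphabet: sequence contains characters other than A,C,G,T,N: ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  x
}

#' Construct a table of barcode windows
#'
#' The in-memory representation of located barcode reads: one row per read
#' with the fixed-length barcode window and the single base immediately 3'
#' of it (the first UMI/adaptor base, used to build the extended
#' circularization variant). `next_base` is `NA` for reads too short to
#' provide it.
#'
#' @param read_id vector of unique read identifiers.
#' @param bases character vector of barcode windows, all of length `L`.
#' @param next_base character vector of single bases (or `NA`).
#' @param L declared barcode length; defaults to the width of the first
#'   window.
#' @return a `data.table` with columns `read_id`, `bases`, `next_base`.
#' @export
#' @examples
#' barcode_windows("r1", "ACGTACGTACGT", "T")
barcode_windows <- function(read_id, bases, next_base = NA_character_,
                            L = nchar(bases[1L])) {
  if (length(bases) == 0L) stop("empty input: no barcode windows supplied")
  bases <- normalize_dna(bases)
  if (any(nchar(bases) != L)) {
    stop("invalid window: all barcode windows must have length ", L)
  }
  next_base <- toupper(as.character(next_base))
  next_base[!is.na(next_base) & next_base == ""] <- NA_character_
  ok <- is.na(next_base) | next_base %chin% .DNA_OK
  if (!all(ok)) stop("invalid alphabet: next_base must be one of A,C,G,T,N")
  if (anyDuplicated(read_id)) stop("read_id values must be unique")
  dt <- data.table::data.table(read_id = read_id, bases = bases,
                               next_base = rep_len(next_base, length(bases)))
  data.table::setattr(dt, "barcode_length", as.integer(L))
  dt[]
}

#' Enumerate all k-mers of a circular sequence
#'
#' Returns one k-mer per circular start offset, in offset order. Duplicate
#' k-mer strings (from repetitive sequence) are retained as distinct
#' positions, so the result always has exactly `nchar(sequence)` rows.
#'
#' @param sequence a single DNA string (A,C,G,T,N), treated as circular.
#' @param k k-mer length; must satisfy `k <= nchar(sequence)`.
#' @return a `data.table` with columns `kmer` and `offset` (0-based circular
#'   start position).
#' @export
#' @examples
#' circular_kmers("ACGT", 3)  # ACG@0, CGT@1, GTA@2, TAC@3
circular_kmers <- function(sequence, k) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty DNA string")
  }
  sequence <- normalize_dna(sequence)
  n <- nchar(sequence)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("invalid parameter: k must satisfy 1 <= k <= length(sequence) (k = ",
         k, ", length = ", n, ")")
  }
  doubled <- paste0(sequence, substr(sequence, 1L, k - 1L))
  off <- seq_len(n) - 1L
  data.table::data.table(kmer = substring(doubled, off + 1L, off + k),
                         offset = off)
}

.VARIANTS <- c("TRUNCATED", "EXACT", "EXTENDED")

#' The three circularization variants of a barcode window
#'
#' @param bases barcode window of length `L`.
#' @param next_base the base just 3' of the window, or `NA`.
#' @return named character vector with elements `TRUNCATED` (length `L-1`),
#'   `EXACT` (length `L`) and, when `next_base` is available, `EXTENDED`
#'   (length `L+1`).
#' @export
circular_variants <- function(bases, next_base = NA_character_) {
  bases <- normalize_dna(bases)
  L <- nchar(bases)
  v <- c(TRUNCATED = substr(bases, 1L, L - 1L), EXACT = bases)
  if (!is.na(next_base) && nzchar(next_base)) {
    v <- c(v, EXTENDED = paste0(bases, toupper(next_base)))
  }
  v
}

#' Positioned k-mers from all three circularization variants
#'
#' Concatenates [circular_kmers()] over the truncated, exact, and (when the
#' next base is known) extended variants of one window. With `next_base`
#' present the result has exactly `3 * L` rows.
#'
#' @param bases barcode window (length `L`).
#' @param next_base the base just 3' of the window, or `NA`.
#' @param k k-mer length; must satisfy `k <= L - 1` so that all variants
#'   admit k-mers.
#' @return a `data.table` with columns `kmer`, `variant` (one of
#'   `TRUNCATED`, `EXACT`, `EXTENDED`) and `offset` (0-based, in the
#'   variant's own circular coordinates).
#' @export
#' @examples
#' nrow(three_variant_kmers("ACGTACGTACGT", "T", k = 8))  # 36
three_variant_kmers <- function(bases, next_base = NA_character_, k) {
  bases <- normalize_dna(bases)
  L <- nchar(bases)
  k <- as.integer(k)
  if (k > L - 1L) {
    stop("invalid parameter: k must be <= L - 1 so the truncated variant ",
         "admits k-mers (k = ", k, ", L = ", L, ")")
  }
  vs <- circular_variants(bases, next_base)
  out <- lapply(names(vs), function(nm) {
    km <- circular_kmers(vs[[nm]], k)
    km[, variant := nm]
    km
  })
  data.table::rbindlist(out)[, .(kmer, variant, offset)]
}

#' Bulk positioned-k-mer table for many windows
#'
#' Vectorised equivalent of applying [three_variant_kmers()] to every row of
#' a window table; the workhorse behind index and subgraph construction.
#' K-mers containing `N` are flagged (`valid == FALSE`) so downstream
#' consumers can exclude them: an N can never support a consensus and would
#' only create spurious graph nodes.
#'
#' @param windows a window table from [barcode_windows()].
#' @param k k-mer length (`k <= L - 1`).
#' @return `data.table` with columns `read_id`, `variant`, `offset`, `kmer`,
#'   `valid`.
#' @export
positioned_kmers <- function(windows, k) {
  L <- nchar(windows$bases[1L])
  k <- as.integer(k)
  if (k > L - 1L) stop("invalid parameter: k must be <= L - 1")
  one_variant <- function(seqs, ids, kind) {
    len <- nchar(seqs[1L])
    doubled <- paste0(seqs, substr(seqs, 1L, k - 1L))
    off <- rep(seq_len(len) - 1L, each = length(seqs))
    data.table::data.table(
      read_id = rep(ids, times = len),
      variant = kind,
      offset = off,
      kmer = substring(rep(doubled, times = len), off + 1L, off + k))
  }
  parts <- list(
    one_variant(substr(windows$bases, 1L, L - 1L), windows$read_id, "TRUNCATED"),
    one_variant(windows$bases, windows$read_id, "EXACT"))
  has_nb <- !is.na(windows$next_base)
  if (any(has_nb)) {
    parts[[3L]] <- one_variant(
      paste0(windows$bases[has_nb], windows$next_base[has_nb]),
      windows$read_id[has_nb], "EXTENDED")
  }
  dt <- data.table::rbindlist(parts)
  dt[, valid := !grepl("N", kmer, fixed = TRUE)]
  dt[]
}

#' All circular rotations of a k-mer string
#'
#' @param kmer a single DNA string.
#' @return character vector of the `nchar(kmer)` rotations (with
#'   duplicates removed).
#' @export
kmer_rotations <- function(kmer) {
  n <- nchar(kmer)
  doubled <- paste0(kmer, kmer)
  unique(substring(doubled, seq_len(n), seq_len(n) + n - 1L))
}

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "kmer", "variant", "offset", "valid", "read_id", "count", "u", "v", "w",
  "bases", "next_base", "barcode", "capacity", "n_reads", "score", "method",
  "truth_barcode", "correct", "N", ".", "flagged", "start_kmer", "window"))
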