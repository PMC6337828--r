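#' Read structure of a barcode FASTQ
#'
#' Describes where the cell barcode and UMI sit within each read, in
#' 0-based half-open coordinates. Drop-seq defaults: barcode at positions
#' `[0, 12)`, UMI at `[12, 20)`.
#'
#' @param barcode_start 0-based start of the barcode window.
#' @param barcode_length barcode length L.
#' @param umi_start 0-based start of the UMI window.
#' @param umi_length UMI length.
#' @return a list of class `read_structure`.
#' @export
read_structure <- function(barcode_start = 0L, barcode_length = 12L,
                           umi_start = 12L, umi_length = 8L) {
  s <- lapply(list(barcode_start = barcode_start,
                   barcode_length = barcode_length,
                   umi_start = umi_start, umi_length = umi_length),
              as.integer)
  if (s$barcode_start < 0L || s$umi_start < 0L ||
      s$barcode_length < 1L || s$umi_length < 0L) {
    stop("read structure coordinates must be non-negative (0-based, ",
         "half-open) with barcode_length >= 1")
  }
  b <- c(s$barcode_start, s$barcode_start + s$barcode_length)
  u <- c(s$umi_start, s$umi_start + s$umi_length)
  if (s$umi_length > 0L && b[1L] < u[2L] && u[1L] < b[2L]) {
    stop("barcode and UMI windows overlap")
  }
  structure(s, class = "read_structure")
}

#' Extract barcode windows from a FASTQ file
#'
#' Parses a (optionally gzip-compressed) FASTQ and yields one window per
#' record: the barcode bases plus the single base immediately 3' of the
#' window (absent when the read ends at the window). Reads too short to
#' cover the barcode window are skipped and counted.
#'
#' @param path FASTQ file (`.gz` handled transparently).
#' @param structure a [read_structure()].
#' @return a [barcode_windows()] table; the number of skipped too-short
#'   reads is attached as attribute `skipped` (also reported via a
#'   warning when non-zero).
#' @export
read_barcode_fastq <- function(path, structure = read_structure()) {
  if (!file.exists(path)) stop("file not found: ", path)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = FALSE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e)))
  if (length(reads) == 0L) stop("empty input: no reads in ", path)
  bs <- structure$barcode_start
  L <- structure$barcode_length
  wd <- Biostrings::width(reads)
  keep <- wd >= bs + L
  skipped <- sum(!keep)
  if (skipped > 0L) {
    warning(skipped, " read(s) too short for the barcode window; skipped")
  }
  if (!any(keep)) stop("empty input: no read covers the barcode window")
  reads <- reads[keep]
  wd <- wd[keep]
  seqs <- as.character(reads)
  ids <- sub("\\s.*$", "", names(reads))
  if (anyDuplicated(ids)) ids <- paste0(ids, "#", seq_along(ids))
  bases <- substr(seqs, bs + 1L, bs + L)
  next_base <- ifelse(wd >= bs + L + 1L,
                      substr(seqs, bs + L + 1L, bs + L + 1L),
                      NA_character_)
  win <- barcode_windows(ids, bases, next_base, L = L)
  data.table::setattr(win, "skipped", skipped)
  win
}

#' Run the full barcode-calling pipeline
#'
#' Orchestrates index construction, cycle search, knee thresholding, and
#' read assignment: `build_kmer_index` -> `call_barcodes` -> `find_knee`
#' -> `assign_reads`. When the capacity curve shows no significant
#' inflection (e.g. essentially error-free data produces no spurious
#' cycles to reject), all called paths are accepted and the result is
#' flagged (`knee = NULL`).
#'
#' @param windows a window table, or a FASTQ path (parsed with
#'   `structure`).
#' @param structure a [read_structure()] (used when `windows` is a path).
#' @param k k-mer length for the graph (default 8; 7 matches a typical
#'   real-data setting).
#' @param breadth number of subgraphs searched (default 1000).
#' @param depth cycles extracted per subgraph (default 5).
#' @param subsample_size reads indexed (default 500000).
#' @param assign_method `"levenshtein"` (default) or `"kmer"`.
#' @param max_dist,min_shared,k_assign assignment parameters
#'   ([assign_reads()]); `k_assign` defaults to `k`.
#' @param knee_window,knee_polyorder knee parameters ([find_knee()]).
#' @param seed integer seed behind all randomness (subsampling).
#' @param out_dir optional directory: writes `barcodes.tsv`
#'   (sequence, capacity, n_reads_assigned), `assignments.tsv`,
#'   `knee.tsv` and `run_log.txt`.
#' @return a list of class `barcycle_run`: `barcodes` (accepted consensus
#'   table), `paths` (all deduplicated called paths), `knee`
#'   (`knee_threshold` or `NULL` when no knee), `assignments`, `params`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(windows, structure = read_structure(), k = 8L,
                         breadth = 1000L, depth = 5L,
                         subsample_size = 500000L,
                         assign_method = c("levenshtein", "kmer"),
                         max_dist = 2L, min_shared = 2L, k_assign = NULL,
                         knee_window = NULL, knee_polyorder = 3L,
                         seed = 1L, out_dir = NULL) {
  assign_method <- match.arg(assign_method)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.character(windows) && length(windows) == 1L) {
    say("reading FASTQ %s", windows)
    windows <- read_barcode_fastq(windows, structure)
    sk <- attr(windows, "skipped")
    if (!is.null(sk) && sk > 0L) say("skipped %d too-short read(s)", sk)
  }
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("empty input: no reads")
  }
  L <- structure$barcode_length
  if (is.null(k_assign)) k_assign <- k
  say("pipeline: %d reads, L = %d, k = %d, breadth = %d, depth = %d, seed = %d",
      nrow(windows), L, k, breadth, depth, seed)
  index <- build_kmer_index(windows, k, subsample_size = subsample_size,
                            seed = seed)
  say("indexed %d reads, %d distinct k-mers", index$reads_indexed,
      nrow(index$counts))
  paths <- call_barcodes(windows, k = k, L = L, breadth = breadth,
                         depth = depth, seed = seed, index = index)
  say("cycle search: %d distinct candidate barcodes", nrow(paths))
  if (nrow(paths) == 0L) stop("no cyclic paths found")
  knee <- tryCatch(
    find_knee(paths$capacity, window = knee_window,
              polyorder = knee_polyorder),
    error = function(e) {
      say("no capacity knee (%s); accepting all called paths",
          conditionMessage(e))
      NULL
    })
  if (is.null(knee)) {
    accepted <- paths
  } else {
    accepted <- paths[capacity > knee$threshold_capacity]
    say("knee at rank %d (capacity %g): %d accepted barcodes",
        knee$knee_rank, knee$threshold_capacity, nrow(accepted))
  }
  assignments <- assign_reads(windows, accepted$barcode,
                              method = assign_method, max_dist = max_dist,
                              k_assign = k_assign, min_shared = min_shared)
  nr <- assignments[!is.na(barcode), .(n_reads_assigned = .N),
                    by = .(barcode)]
  barcodes <- merge(accepted, nr, by = "barcode", all.x = TRUE)
  barcodes[is.na(n_reads_assigned), n_reads_assigned := 0L]
  barcodes <- barcodes[order(-capacity, barcode)]
  say("assigned %d / %d reads (%s)", sum(!is.na(assignments$barcode)),
      nrow(assignments), assign_method)
  res <- list(barcodes = barcodes, paths = paths, knee = knee,
              assignments = assignments,
              params = list(k = k, L = L, breadth = breadth, depth = depth,
                            subsample_size = subsample_size,
                            assign_method = assign_method,
                            max_dist = max_dist, min_shared = min_shared,
                            k_assign = k_assign, seed = seed),
              log = log)
  class(res) <- "barcycle_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

utils::globalVariables(c("n_reads_assigned"))

#' @export
print.barcycle_run <- function(x, ...) {
  cat(sprintf("barcycle_run: %d accepted barcodes from %d called paths\n",
              nrow(x$barcodes), nrow(x$paths)))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param run a `barcycle_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$barcodes, file.path(out_dir, "barcodes.tsv"),
                     sep = "\t")
  data.table::fwrite(run$assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t")
  if (!is.null(run$knee)) {
    write_knee_table(run$knee, file.path(out_dir, "knee.tsv"))
  }
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Split a mate FASTQ into per-barcode files
#'
#' Writes one FASTQ per accepted barcode containing the mate records of
#' the reads assigned to it, for downstream per-cell quantification.
#'
#' @param assignments an assignment table (`read_id`, `barcode`).
#' @param mate_fastq FASTQ whose records (matched by id prefix) are the
#'   cDNA mates of the barcode reads.
#' @param out_dir output directory.
#' @return named character vector of written paths, invisibly.
#' @export
split_fastq_by_barcode <- function(assignments, mate_fastq, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- readLines(if (grepl("\\.gz$", mate_fastq)) gzfile(mate_fastq)
                     else mate_fastq)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1L, length(lines), 4L)]))
  a <- data.table::as.data.table(assignments)[!is.na(barcode)]
  idx <- match(a$read_id, ids)
  a <- a[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  paths <- character(0)
  for (bc in unique(a$barcode)) {
    rows <- idx[a$barcode == bc]
    rec <- as.vector(vapply(rows, function(r) lines[(4L * (r - 1L) + 1L):(4L * r)],
                            character(4L)))
    p <- file.path(out_dir, paste0(bc, ".fastq"))
    writeLines(rec, p)
    paths[bc] <- p
  }
  invisible(paths)
}
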