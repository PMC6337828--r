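#' Simulated Drop-seq barcode read sets with known ground truth
#'
#' Generates benchmark datasets: a set of random ground-truth barcodes
#' with configurable abundance distribution, and reads each carrying a
#' Poisson-distributed number of insertion/deletion/mismatch errors at
#' uniform-random positions within the barcode. Deletions shift downstream
#' filler bases into the fixed-length window and insertions shift window
#' bases out of it, as happens in a real read, so emitted windows always
#' have the declared length and the truncated/extended correction logic is
#' exercised exactly as on real data.
#'
#' @name simulate
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults reproduce the benchmark conditions: around 500 cells (the cell
#' count itself drawn from Normal(500, 50) when not given), barcode length
#' 12, 100,000 reads, and per-cell abundances that are normal (mean 200
#' reads/cell, sd 20), uniform, or exponential (scale 0.2) before
#' normalisation to a probability simplex. Negative or zero normal draws
#' are clipped to a floor of one read.
#'
#' @param n_barcodes number of cells; `NULL` (default) draws one value
#'   from Normal(500, 50), rounded.
#' @param barcode_length barcode length L (default 12).
#' @param n_reads number of reads to emit (default 100000).
#' @param error_lambda Poisson mean errors per read, in `[0, 3]`.
#' @param error_type one of `"any"`, `"insertion"`, `"deletion"`,
#'   `"mismatch"`; `"any"` draws each error's type uniformly.
#' @param abundance one of `"normal"`, `"uniform"`, `"exponential"`.
#' @param replicate replicate number (bookkeeping only).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_barcodes = NULL, barcode_length = 12L,
                              n_reads = 100000L, error_lambda = 1,
                              error_type = c("any", "insertion", "deletion",
                                             "mismatch"),
                              abundance = c("normal", "uniform",
                                            "exponential"),
                              replicate = 1L, seed = 1L) {
  error_type <- match.arg(error_type)
  abundance <- match.arg(abundance)
  if (error_lambda < 0) stop("error_lambda must be >= 0")
  structure(list(n_barcodes = n_barcodes,
                 barcode_length = as.integer(barcode_length),
                 n_reads = as.integer(n_reads),
                 error_lambda = error_lambda, error_type = error_type,
                 abundance = abundance, replicate = as.integer(replicate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

.random_seqs <- function(n, len) {
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

# apply n_err errors to one read string; positions are uniform over the
# barcode window of the evolving string, so indels shift later bases
.corrupt_read <- function(full, n_err, L, type) {
  desc <- character(n_err)
  for (e in seq_len(n_err)) {
    p <- sample.int(L, 1L)
    ty <- if (type == "any") sample(c("insertion", "deletion", "mismatch"), 1L)
          else type
    if (ty == "mismatch") {
      old <- substr(full, p, p)
      substr(full, p, p) <- sample(setdiff(.BASES, old), 1L)
    } else if (ty == "deletion") {
      full <- paste0(substr(full, 1L, p - 1L),
                     substr(full, p + 1L, nchar(full)))
    } else {
      full <- paste0(substr(full, 1L, p - 1L), sample(.BASES, 1L),
                     substr(full, p, nchar(full)))
    }
    desc[e] <- paste0(substr(ty, 1L, 3L), "@", p)
  }
  list(full = full, desc = paste(desc, collapse = ";"))
}

#' Generate a simulated dataset
#'
#' @param config a [simulation_config()].
#' @return a list of class `barcode_sim` with elements `windows` (a
#'   [barcode_windows()] table), `truth` (data.table `read_id`,
#'   `barcode`, `n_errors`, `errors`), `barcodes`, `abundance`
#'   (normalised probabilities), `reads` (full-length read sequences) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$barcode_length
  nb <- config$n_barcodes
  if (is.null(nb)) nb <- max(1L, round(stats::rnorm(1L, 500, 50)))
  barcodes <- unique(.random_seqs(nb * 2L, L))[seq_len(nb)]
  prob <- switch(config$abundance,
    normal = pmax(stats::rnorm(nb, 200, 20), 1),
    uniform = rep(1, nb),
    exponential = stats::rexp(nb, rate = 1 / 0.2))
  prob <- prob / sum(prob)
  n <- config$n_reads
  origin <- sample.int(nb, n, replace = TRUE, prob = prob)
  # filler long enough to backfill the window after up to several
  # deletions and still provide a next base and a UMI
  filler <- .random_seqs(n, L + 8L)
  full <- paste0(barcodes[origin], filler)
  n_err <- stats::rpois(n, config$error_lambda)
  desc <- character(n)
  bad <- which(n_err > 0L)
  for (i in bad) {
    cr <- .corrupt_read(full[i], n_err[i], L, config$error_type)
    full[i] <- cr$full
    desc[i] <- cr$desc
  }
  ids <- sprintf("read_%07d", seq_len(n))
  windows <- barcode_windows(ids, substr(full, 1L, L),
                             substr(full, L + 1L, L + 1L), L = L)
  truth <- data.table::data.table(read_id = ids,
                                  barcode = barcodes[origin],
                                  n_errors = n_err, errors = desc)
  structure(list(windows = windows, truth = truth, barcodes = barcodes,
                 abundance = prob, reads = full, config = config),
            class = "barcode_sim")
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat(sprintf(
    "barcode_sim: %d barcodes (L = %d), %d reads, lambda = %g (%s), %s abundance\n",
    length(x$barcodes), x$config$barcode_length, nrow(x$windows),
    x$config$error_lambda, x$config$error_type, x$config$abundance))
  invisible(x)
}

#' Write a simulated dataset as FASTQ (plus ground truth)
#'
#' Emits a standard 4-line-per-record FASTQ (gzip when the path ends in
#' `.gz`), a ground-truth TSV (`read_id`, `barcode`, `n_errors`,
#' `errors`), and a small config manifest.
#'
#' @param sim a `barcode_sim`.
#' @param fastq output FASTQ path (`.gz` for compressed).
#' @param truth_tsv optional ground-truth TSV path.
#' @param manifest optional manifest path.
#' @return `fastq`, invisibly.
#' @export
write_sim_fastq <- function(sim, fastq, truth_tsv = NULL, manifest = NULL) {
  stopifnot(inherits(sim, "barcode_sim"))
  qual <- strrep("I", nchar(sim$reads))
  rec <- rbind(paste0("@", sim$truth$read_id), sim$reads, "+", qual)
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "w") else file(fastq, "w")
  writeLines(as.vector(rec), con)
  close(con)
  if (!is.null(truth_tsv)) {
    data.table::fwrite(sim$truth, truth_tsv, sep = "\t")
  }
  if (!is.null(manifest)) {
    cfg <- sim$config
    writeLines(sprintf("%s\t%s", names(unclass(cfg)),
                       vapply(unclass(cfg), function(x)
                         if (is.null(x)) "NULL" else as.character(x), "")),
               manifest)
  }
  invisible(fastq)
}

#' Score called barcodes (and optionally assignments) against truth
#'
#' Barcode-level: exact string-set comparison giving true positives,
#' false positives and false negatives (a truth barcode counts only if at
#' least one read derives from it). Read-level, when assignments are
#' supplied: a read assigned to its ground-truth barcode is correct, one
#' assigned elsewhere is incorrect, and `NA` assignments are unassigned.
#'
#' @param called character vector of called barcode sequences.
#' @param truth either a `barcode_sim` or its `truth` table.
#' @param assignments optional assignment table (`read_id`, `barcode`).
#' @return a list of class `benchmark_result`: `tp`, `fp`, `fn`, and when
#'   assignments are given `read_fractions` (named: correct, incorrect,
#'   unassigned) plus `per_barcode` (per-truth-barcode fractions).
#' @export
score_barcodes <- function(called, truth, assignments = NULL) {
  if (inherits(truth, "barcode_sim")) truth <- truth$truth
  truth_set <- unique(truth$barcode)
  called <- unique(called)
  tp <- length(intersect(called, truth_set))
  res <- list(tp = tp, fp = length(setdiff(called, truth_set)),
              fn = length(setdiff(truth_set, called)))
  if (!is.null(assignments)) {
    a <- data.table::as.data.table(assignments)[, .(read_id, assigned = barcode)]
    m <- a[truth, on = "read_id"]
    m[, status := data.table::fifelse(
      is.na(assigned), "unassigned",
      data.table::fifelse(assigned == barcode, "correct", "incorrect"))]
    tab <- m[, .N, by = status]
    fr <- stats::setNames(rep(0, 3), c("correct", "incorrect", "unassigned"))
    fr[tab$status] <- tab$N / nrow(m)
    res$read_fractions <- fr
    res$per_barcode <- m[, .(
      correct = mean(status == "correct"),
      incorrect = mean(status == "incorrect"),
      unassigned = mean(status == "unassigned"), n_reads = .N),
      by = .(barcode)]
  }
  structure(res, class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: tp = %d, fp = %d, fn = %d\n",
              x$tp, x$fp, x$fn))
  if (!is.null(x$read_fractions)) {
    cat(sprintf("  reads: %.1f%% correct, %.1f%% incorrect, %.1f%% unassigned\n",
                100 * x$read_fractions[["correct"]],
                100 * x$read_fractions[["incorrect"]],
                100 * x$read_fractions[["unassigned"]]))
  }
  invisible(x)
}

utils::globalVariables(c("status", "assigned", "n_errors"))

#' Naive exact-counting baseline caller
#'
#' The comparison arm: counts exact (non-circularized) barcode windows,
#' thresholds the count-vs-rank curve with the same knee procedure, and
#' assigns reads only by exact window match to a called barcode. It has no
#' mechanism for insertion or deletion errors. This is a comparison
#' stand-in modelled on simple k-mer-counting pipelines, not a faithful
#' reimplementation of any published tool.
#'
#' @param windows a window table.
#' @param L barcode length (unused beyond validation; windows are already
#'   fixed-length).
#' @param window,polyorder knee parameters (see [find_knee()]).
#' @return list with `called` (character vector) and `assignments`
#'   (data.table `read_id`, `barcode`, `method`, `score` = window count).
#' @export
naive_baseline <- function(windows, L = nchar(windows$bases[1L]),
                           window = NULL, polyorder = 3L) {
  cnt <- windows[, .(count = .N), by = .(bases)][order(-count, bases)]
  kn <- find_knee(cnt$count, window = window, polyorder = polyorder)
  called <- cnt[count > kn$threshold_capacity, bases]
  out <- cnt[windows, on = "bases"]
  out[, barcode := data.table::fifelse(bases %chin% called, bases,
                                       NA_character_)]
  assignments <- out[, .(
    read_id, barcode, method = "NAIVE",
    score = data.table::fifelse(is.na(barcode), NA_integer_,
                                as.integer(count)))]
  list(called = called, assignments = assignments, knee = kn)
}

#' The full simulation grid
#'
#' The benchmark sweep: 3 abundance distributions x 4 error types x 5
#' Poisson rates (0, 0.5, 1, 2, 3) x 3 replicates = 180 dataset
#' configurations. The five-level rate sweep between 0 and 3 is the grid
#' that yields the 180-dataset total.
#'
#' @param lambdas Poisson rate levels (default `c(0, 0.5, 1, 2, 3)`).
#' @param replicates replicates per condition (default 3).
#' @param base_seed seed for the first configuration; successive
#'   configurations increment it.
#' @return a list of [simulation_config()] objects.
#' @export
methods_grid <- function(lambdas = c(0, 0.5, 1, 2, 3), replicates = 3L,
                         base_seed = 1L) {
  grid <- expand.grid(abundance = c("normal", "uniform", "exponential"),
                      error_type = c("any", "insertion", "deletion",
                                     "mismatch"),
                      error_lambda = lambdas,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    simulation_config(error_lambda = grid$error_lambda[i],
                      error_type = grid$error_type[i],
                      abundance = grid$abundance[i],
                      replicate = grid$replicate[i],
                      seed = base_seed + i - 1L)
  })
}
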