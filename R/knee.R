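#' Knee-point thresholding of path capacities
#'
#' True barcode cycles have capacities on the order of the per-cell read
#' count, while spurious cycles (chance k-mer overlap, residual error
#' paths) have capacities near 1. The cumulative sum of capacities versus
#' path rank therefore shows a steep early segment and a shallow tail with
#' a clear inflection between them. The inflection is the local maximum of
#' the first derivative of the path-weight distribution read in ascending
#' orientation -- equivalently, the interior extremum of largest magnitude
#' of the curvature of the (smoothed) cumulative curve, which on a clean
#' step fixture coincides with the argmax of the discrete second
#' difference of the unsmoothed curve. A Savitzky-Golay filter smooths the
#' cumulative curve before differentiation so that sampling noise does not
#' create spurious extrema.
#'
#' @param capacities numeric vector of path capacities (any order).
#' @param window odd Savitzky-Golay window length in ranks. Default: 101,
#'   reduced to the largest odd number `<= length(capacities)` when the
#'   input is smaller. Supplying a window larger than the input is an
#'   error.
#' @param polyorder Savitzky-Golay polynomial order (default 3; must be
#'   `< window`).
#' @param min_drop required significance of the knee: the smoothed
#'   derivative half a window before the candidate must be at least
#'   `min_drop` times the derivative half a window after it (default 2).
#'   This formalises "a subset of paths with significantly higher capacity
#'   than the rest"; candidates failing it are curvature noise, and if no
#'   candidate passes a no-knee error is raised.
#' @return an object of class `knee_threshold`: list with
#'   `sorted_capacities` (descending), `cumulative`, `smoothed`,
#'   `derivative` (first difference of the smoothed curve), `knee_rank`
#'   (1-based rank of the first path at or below the knee),
#'   `threshold_capacity` (`sorted_capacities[knee_rank]`), `accepted`
#'   (logical over the sorted order: capacity strictly above threshold),
#'   `n_accepted`, and `candidates` (ranks of all interior curvature
#'   extrema, strongest first, for diagnostics).
#' @export
#' @examples
#' res <- find_knee(c(rep(100, 20), rep(2, 200)), window = 21)
#' res$n_accepted  # 20
find_knee <- function(capacities, window = NULL, polyorder = 3L,
                      min_drop = 2) {
  capacities <- as.numeric(capacities)
  if (anyNA(capacities)) stop("capacities must not contain NA")
  n <- length(capacities)
  auto_window <- is.null(window)
  if (auto_window) {
    window <- min(101L, n - (1L - n %% 2L))  # largest odd <= min(101, n)
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (n < window) {
    stop("degenerate input: ", n, " paths but window = ", window,
         "; supply a smaller (odd) window")
  }
  polyorder <- as.integer(polyorder)
  if (polyorder >= window) stop("polyorder must be < window")
  sorted <- sort(capacities, decreasing = TRUE)
  cumulative <- cumsum(sorted)
  smoothed <- signal::sgolayfilt(cumulative, p = polyorder, n = window)
  derivative <- diff(smoothed)
  curvature <- diff(derivative)
  # interior strict local extrema of curvature magnitude; the boundary
  # half-windows are excluded (filter edge artifacts)
  mag <- abs(curvature)
  m <- length(mag)
  lo <- max(2L, window %/% 2L)
  hi <- min(m - 1L, m - window %/% 2L + 1L)
  eps <- 1e-9 * max(mag, 0)
  is_ext <- logical(m)
  if (hi >= lo) {
    i <- lo:hi
    is_ext[i] <- mag[i] > eps & mag[i] >= mag[i - 1L] & mag[i] >= mag[i + 1L] &
      (mag[i] > mag[i - 1L] | mag[i] > mag[i + 1L])
  }
  cand <- which(is_ext)
  cand <- cand[order(-mag[cand], cand)]
  # a candidate is a real knee only if the derivative genuinely drops
  # across it: a cliff, not sampling noise on a smooth curve
  h <- max(1L, window %/% 2L)
  nd <- length(derivative)
  ok_cliff <- vapply(cand, function(ci) {
    before <- derivative[max(1L, ci - h)]
    after <- derivative[min(nd, ci + h)]
    before > after && before >= min_drop * max(after, 0)
  }, logical(1L))
  cand <- cand[ok_cliff]
  if (length(cand) == 0L) {
    stop("no knee: capacity curve has no significant interior inflection ",
         "(single capacity population or degenerate input); ",
         "supply an explicit threshold instead")
  }
  # the smoothed curvature extremum localizes the knee to within about
  # half a window; the raw capacity curve pins it: the knee rank is the
  # first rank after the largest consecutive capacity drop in that
  # neighbourhood (curvature index i spans ranks i..i+2)
  centre <- cand[1L] + 1L
  lo_r <- max(2L, centre - h)
  hi_r <- min(n, centre + h + 1L)
  rr <- lo_r:hi_r
  drops <- sorted[rr - 1L] - sorted[rr]
  knee_rank <- rr[which.max(drops)]
  threshold_capacity <- sorted[knee_rank]
  accepted <- sorted > threshold_capacity
  structure(list(sorted_capacities = sorted, cumulative = cumulative,
                 smoothed = smoothed, derivative = derivative,
                 knee_rank = knee_rank,
                 threshold_capacity = threshold_capacity,
                 accepted = accepted, n_accepted = sum(accepted),
                 candidates = cand + 1L,
                 window = window, polyorder = polyorder),
            class = "knee_threshold")
}

#' @export
print.knee_threshold <- function(x, ...) {
  cat(sprintf(paste0("knee_threshold: %d paths, knee at rank %d ",
                     "(capacity %g), %d accepted\n"),
              length(x$sorted_capacities), x$knee_rank,
              x$threshold_capacity, x$n_accepted))
  invisible(x)
}

#' Write the knee diagnostic trace as TSV
#'
#' One row per rank: `rank`, `capacity`, `cumulative`, `smoothed`,
#' `derivative` -- everything needed to re-plot the capacity-vs-rank and
#' derivative curves by which the threshold was chosen.
#'
#' @param knee a `knee_threshold` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_knee_table <- function(knee, path) {
  stopifnot(inherits(knee, "knee_threshold"))
  n <- length(knee$sorted_capacities)
  dt <- data.table::data.table(
    rank = seq_len(n),
    capacity = knee$sorted_capacities,
    cumulative = knee$cumulative,
    smoothed = knee$smoothed,
    derivative = c(knee$derivative, NA_real_))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
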