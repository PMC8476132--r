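#' Bootstrap tail counts (kappa) for every window
#'
#' Calibrates the windowed multinomial scores by bootstrap: each of the
#' `n_b` replicates resamples the `2n` sampled haplotypes with
#' replacement, recomputes every local SFS *and* the genome-wide SFS,
#' scores each window with [sfs_log_probability()], and flags the
#' `tail_size` windows with the lowest probability (the lower 1% tail;
#' ties broken by window index, empty windows never enter the tail).
#' `kappa[w]` is the number of replicates in which window `w` was
#' flagged, so `sum(kappa) == n_b * tail_size` always.
#'
#' @param sample a `haplotype_sample`.
#' @param window_size window width in bp.
#' @param n_b number of bootstrap replicates.
#' @param tail_size windows flagged per replicate; defaults to
#'   `max(1, floor(0.01 * W))` (10 when the genome tiles into 1000
#'   windows).
#' @param seed optional integer seed for reproducibility.
#' @return A `tail_counts` object: list with `kappa` (integer vector over
#'   windows), `n_b`, `tail_size`, `W`, `window_size` and `generation`.
#' @export
bootstrap_tail_counts <- function(sample, window_size, n_b = 1000,
                                  tail_size = NULL, seed = NULL) {
  stopifnot(inherits(sample, "haplotype_sample"))
  if (!is.null(seed)) set.seed(seed)
  W <- as.integer(ceiling(sample$L / window_size))
  if (is.null(tail_size)) tail_size <- max(1L, as.integer(floor(0.01 * W)))
  win <- as.integer(floor(sample$positions / window_size))
  kappa <- boot_kappa(sample$geno, win, W, as.integer(n_b),
                      as.integer(tail_size))
  structure(list(kappa = kappa, n_b = as.integer(n_b),
                 tail_size = as.integer(tail_size), W = W,
                 window_size = window_size,
                 generation = sample$generation),
            class = "tail_counts")
}

#' @export
print.tail_counts <- function(x, ...) {
  cat(sprintf(
    "tail_counts: %d windows, n_b = %d, tail size %d; max kappa = %d\n",
    x$W, x$n_b, x$tail_size, max(x$kappa)))
  invisible(x)
}

#' Neighborhood-averaged tail counts (kappa_d)
#'
#' `kappa_d[i]` is the mean of `kappa` over the windows
#' `max(1, i-d) .. min(W, i+d)` - the focal window and its `d` neighbors
#' on each side, truncated at the chromosome ends (the divisor is the
#' number of windows actually averaged).
#'
#' @param kappa a `tail_counts` object or a numeric vector.
#' @param d neighborhood half-width in windows, `d >= 0`.
#' @return Numeric vector of the same length as `kappa`.
#' @export
smoothed_counts <- function(kappa, d) {
  if (inherits(kappa, "tail_counts")) kappa <- kappa$kappa
  stopifnot(d >= 0)
  d <- as.integer(d)
  W <- length(kappa)
  cs <- cumsum(c(0, kappa))
  i <- seq_len(W)
  lo <- pmax(i - d, 1L)
  hi <- pmin(i + d, W)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Two-threshold outlier calling
#'
#' A window is a *candidate* outlier when its tail count exceeds `thr1`
#' (`kappa > thr1`), and is *called* when additionally the mean tail
#' count of its `[i-d, i+d]` neighborhood exceeds `thr2`
#' (`kappa_d > thr2`).  The second condition discards isolated peaks:
#' selection is expected to distort the SFS beyond a single window, while
#' chance outliers are typically solitary.  Overlapping call regions are
#' reported separately, not merged.
#'
#' @param kappa a `tail_counts` object.
#' @param d neighborhood half-width in windows.
#' @param thr1 candidacy threshold on `kappa`.
#' @param thr2 threshold on the neighborhood mean `kappa_d`.
#' @return A data frame with one row per called window: `window`
#'   (1-based index), `kappa`, `kappa_d`, `region_lo`, `region_hi`
#'   (window span `[i-d, i+d]` clamped to the chromosome) and
#'   `start_bp`, `end_bp` of the region.
#' @export
call_outliers <- function(kappa, d, thr1, thr2) {
  stopifnot(inherits(kappa, "tail_counts"))
  stopifnot(d >= 0, thr1 >= 0, thr1 <= kappa$n_b, thr2 >= 0,
            thr2 <= kappa$n_b)
  kd <- smoothed_counts(kappa, d)
  k <- kappa$kappa
  hit <- which(k > thr1 & kd > thr2)
  data.frame(
    window = as.integer(hit),
    kappa = k[hit],
    kappa_d = kd[hit],
    region_lo = as.integer(pmax(hit - d, 1L)),
    region_hi = as.integer(pmin(hit + d, kappa$W)),
    start_bp = (pmax(hit - d, 1L) - 1) * kappa$window_size,
    end_bp = pmin(hit + d, kappa$W) * kappa$window_size
  )
}

#' Upper bound on the number of candidate outliers
#'
#' Each bootstrap replicate hands out `tail_size` tail slots, so over
#' `n_b` replicates at most `floor(n_b * tail_size / thr1)` windows can
#' have `kappa > thr1`.  This bound (25 at `thr1 = 400`, 10 at
#' `thr1 = 1000`, with the default 10,000 slots) is the effective number
#' of tests used in Bonferroni corrections.
#'
#' @param thr1 candidacy threshold, `> 0`.
#' @param n_b bootstrap replicates.
#' @param tail_size tail slots per replicate.
#' @return Integer bound on the candidate count.
#' @seealso [fpr_ceiling()]
#' @export
candidate_bound <- function(thr1, n_b = 1000, tail_size = 10) {
  if (any(thr1 <= 0)) stop("thr1 must be positive")
  as.integer(floor(n_b * tail_size / thr1))
}

#' Bonferroni-corrected false-positive-rate ceiling
#'
#' The performance constraint used when tuning thresholds: the
#' false-positive window rate must stay below `5 * thr1 / 10000` percent
#' (at the default 10,000 tail slots), i.e. a 5% genome-wide error budget
#' divided by the `n_b * tail_size / thr1` effective number of tests of
#' [candidate_bound()].  Returned as a proportion (`4.5e-3` at
#' `thr1 = 900`).
#'
#' @inheritParams candidate_bound
#' @return The ceiling as a proportion.
#' @export
fpr_ceiling <- function(thr1, n_b = 1000, tail_size = 10) {
  if (any(thr1 <= 0)) stop("thr1 must be positive")
  0.05 * thr1 / (n_b * tail_size)
}
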