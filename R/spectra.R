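#' Windowed unfolded site frequency spectra
#'
#' Tiles the chromosome with non-overlapping half-open windows
#' `[k w, (k+1) w)` (the final window may be partial) and tabulates, per
#' window, the unfolded SFS of the sample: counts of sites by
#' derived-allele count `1 .. 2n-1`.  The genome-wide SFS is the bin-wise
#' sum over windows.
#'
#' @param sample a `haplotype_sample`.
#' @param window_size window width in bp.
#' @return A `windowed_sfs` object: list with `counts` (integer matrix,
#'   windows x frequency bins), `global` (bin-wise column sums), `W`
#'   (window count `ceiling(L / window_size)`), `window_size`, `n_hap`,
#'   `snp_count` (per-window totals) and `window_start` (bp).
#' @export
#' @examples
#' geno <- matrix(c(1,0,0,0, 1,1,0,0, 0,1,1,0), nrow = 3, byrow = TRUE)
#' s <- haplotype_sample(geno, positions = c(10, 20, 30), L = 100)
#' window_sfs(s, window_size = 50)$counts
window_sfs <- function(sample, window_size) {
  stopifnot(inherits(sample, "haplotype_sample"), window_size > 0)
  H <- sample$n_hap
  W <- as.integer(ceiling(sample$L / window_size))
  nb <- H - 1L
  counts <- matrix(0L, nrow = W, ncol = nb,
                   dimnames = list(NULL, as.character(seq_len(nb))))
  if (nrow(sample$geno)) {
    win <- as.integer(floor(sample$positions / window_size)) + 1L
    dac <- as.integer(rowSums(sample$geno))
    tab <- tabulate((win - 1L) * nb + dac, nbins = W * nb)
    counts[] <- matrix(tab, nrow = W, ncol = nb, byrow = TRUE)
  }
  structure(list(counts = counts,
                 global = as.integer(colSums(counts)), W = W,
                 window_size = window_size, n_hap = H,
                 snp_count = as.integer(rowSums(counts)),
                 window_start = (seq_len(W) - 1) * window_size),
            class = "windowed_sfs")
}

#' @export
print.windowed_sfs <- function(x, ...) {
  cat(sprintf("windowed_sfs: %d windows of %g bp, %d haplotypes, %d SNPs\n",
              x$W, x$window_size, x$n_hap, sum(x$global)))
  invisible(x)
}

#' Multinomial log-probability of a local SFS given the genome-wide SFS
#'
#' Treats the genome-wide SFS as a multinomial distribution over
#' frequency bins (`p_i` = global share of bin `i`) and returns, for each
#' local SFS with counts `x_i` and total `k`, the log-probability
#' `log( k! / prod(x_i!) * prod(p_i^x_i) )` of drawing exactly that local
#' spectrum in `k` draws.  Everything is computed in log space via
#' `lgamma`; raw factorials are never formed.  An empty local SFS has
#' log-probability 0 (probability 1).
#'
#' @param local a `windowed_sfs` (scores every window against its own
#'   `global`), or a numeric vector / matrix (rows = spectra) of bin
#'   counts.
#' @param global numeric vector of genome-wide bin counts; ignored (taken
#'   from the object) when `local` is a `windowed_sfs`.
#' @return Numeric vector of log-probabilities, one per spectrum; all
#'   values are `<= 0`.
#' @export
#' @examples
#' # drawing each of 100 equiprobable categories exactly once in 100
#' # draws: probability 100!/100^100 = 9.33e-43
#' exp(sfs_log_probability(rep(1, 100), rep(1, 100)))
sfs_log_probability <- function(local, global = NULL) {
  if (inherits(local, "windowed_sfs")) {
    global <- local$global
    local <- local$counts
  }
  if (is.null(dim(local))) local <- matrix(local, nrow = 1)
  if (length(global) != ncol(local))
    stop("local and global spectra must have the same number of bins")
  if (any(local < 0) || any(global < 0)) stop("SFS counts must be >= 0")
  tot <- sum(global)
  occ <- global > 0
  if (any(local[, !occ, drop = FALSE] > 0))
    stop("local SFS occupies a bin with zero genome-wide probability")
  k <- rowSums(local)
  lp <- lgamma(k + 1) - rowSums(lgamma(local + 1))
  if (any(occ)) {
    lpb <- log(global[occ] / tot)
    lp <- lp + as.vector(local[, occ, drop = FALSE] %*% lpb)
  }
  pmin(lp, 0)
}

#' Observed per-window log-probabilities of a sample
#'
#' Convenience wrapper: windowed SFS of the sample, each window scored by
#' [sfs_log_probability()] against the genome-wide SFS.  Windows with no
#' SNPs get log-probability 0.
#'
#' @inheritParams window_sfs
#' @return A data frame with one row per window: `window` (1-based),
#'   `start`, `end` (bp), `n_snp` and `log_prob`.
#' @export
window_log_probabilities <- function(sample, window_size) {
  ws <- window_sfs(sample, window_size)
  data.frame(window = seq_len(ws$W), start = ws$window_start,
             end = pmin(ws$window_start + window_size, sample$L),
             n_snp = ws$snp_count,
             log_prob = sfs_log_probability(ws))
}

#' Expected hybrid SFS at founding
#'
#' Expected unfolded spectrum of a sample from the hybrid population at
#' generation 0, given the two parental sample spectra and the number of
#' fixed differences between the sources.  Each parental polymorphic site
#' of sample frequency `f` segregates in the newly founded hybrid
#' population at expected frequency `f / 2` (the other source contributes
#' only ancestral alleles there), so it adds a Binomial(`2n`, `f/2`) mass
#' over the hybrid frequency bins; each of the `n_fixed_diff` differences
#' fixed between the sources contributes a Binomial(`2n`, 1/2) mass
#' centred on frequency 0.5 - the hallmark intermediate-frequency peak of
#' a freshly formed hybrid population.  Mass falling outside the
#' polymorphic bins (sites lost or fixed in the hybrid sample) is
#' dropped, not renormalized.
#'
#' @param parent1,parent2 numeric vectors of parental SFS counts over
#'   bins `1 .. 2n-1` (equal length).
#' @param n_fixed_diff number of fixed differences between the sources.
#' @return Numeric vector of expected counts over bins `1 .. 2n-1`.
#' @export
predict_initial_hybrid_sfs <- function(parent1, parent2, n_fixed_diff = 0) {
  if (length(parent1) != length(parent2))
    stop("parental spectra must be on the same number of haplotypes")
  if (any(parent1 < 0) || any(parent2 < 0) || n_fixed_diff < 0)
    stop("counts must be non-negative")
  nb <- length(parent1)
  n_hap <- nb + 1L
  bins <- seq_len(nb)
  expected <- numeric(nb)
  src <- parent1 + parent2
  for (i in bins) {
    if (src[i] > 0)
      expected <- expected + src[i] * dbinom(bins, n_hap, (i / n_hap) / 2)
  }
  expected + n_fixed_diff * dbinom(bins, n_hap, 0.5)
}

#' Genome-wide sample SFS
#'
#' @param sample a `haplotype_sample`.
#' @return Integer vector of counts over derived-allele counts
#'   `1 .. 2n-1`.
#' @export
sample_sfs <- function(sample) {
  stopifnot(inherits(sample, "haplotype_sample"))
  nb <- sample$n_hap - 1L
  setNames(tabulate(rowSums(sample$geno), nbins = nb),
           as.character(seq_len(nb)))
}
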