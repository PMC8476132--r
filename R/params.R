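#' Simulation parameters for a two-source / hybrid-sink system
#'
#' Bundles every demographic, genomic and selective parameter of the hybrid
#' zone model.  Two parental (source) populations of `Np` diploids diverge
#' in allopatry for `n_burnin` generations, each fixed from the start for
#' the derived allele at one of the two incompatibility loci (`A` in source
#' 1, `B` in source 2).  A hybrid (sink) population of `N` diploids is then
#' founded as a 50:50 mixture of the sources and keeps receiving migrants
#' from each source at rate `m` per generation, while viability selection
#' acts against carriers of both derived alleles through the epistasis
#' coefficient `eps` (see [epistatic_fitness()]).
#'
#' @param Np parental (source) population size, diploid individuals.
#' @param N hybrid (sink) population size, diploid individuals.
#' @param n_burnin number of allopatric divergence generations before the
#'   hybrid population is founded.
#' @param mu neutral mutation rate per base pair per generation (before
#'   `rescale` is applied).
#' @param r recombination rate per base pair per generation (before
#'   `rescale` is applied); crossovers are Poisson with no interference.
#' @param m migration rate into the hybrid population from *each* source
#'   per generation (total replacement fraction is `2 m`).
#' @param L chromosome length in base pairs.
#' @param pos_A,pos_B positions (bp, 0-based) of the two incompatibility
#'   loci; must satisfy `0 <= pos_A < pos_B < L`.
#' @param eps epistasis coefficient of the incompatibility, `-1 <= eps <= 0`.
#' @param s_a,s_b selection coefficients of the *ancestral* alleles at the
#'   two loci (non-positive models local adaptation of the derived alleles).
#' @param dominance `"codominant"` or `"recessive"`; controls whether the
#'   double heterozygote pays the epistatic cost (see [epistatic_fitness()]).
#' @param rescale integer factor by which `mu` and `r` are multiplied at
#'   simulation time so a shorter chromosome stands in for a longer one
#'   (`L mu` and `L r` preserved); the full-scale presets use 10.
#' @param sample_size number of diploids drawn (without replacement) per
#'   sample of the hybrid population.
#' @param sample_generations generations of the hybrid population (counted
#'   from founding = 0) at which samples are scheduled.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [scenario_params()] for the named presets, [scale_params()] for
#'   desk-scale rescaling.
#' @export
#' @examples
#' p <- sim_params(Np = 50, N = 100, n_burnin = 100, L = 1e6,
#'                 pos_A = 2.5e5, pos_B = 7.5e5, mu = 1e-7, r = 1e-7,
#'                 rescale = 1)
#' p
sim_params <- function(Np = 5000, N = 10000, n_burnin = 50000,
                       mu = 1e-9, r = 5e-9, m = 0.005,
                       L = 5e8, pos_A = 1.75e8, pos_B = 3.25e8,
                       eps = -0.1, s_a = 0, s_b = 0,
                       dominance = c("codominant", "recessive"),
                       rescale = 10, sample_size = 50,
                       sample_generations = c(100, 1000, 5000, 10000)) {
  dominance <- match.arg(dominance)
  p <- list(Np = as.integer(Np), N = as.integer(N),
            n_burnin = as.integer(n_burnin),
            mu = mu, r = r, m = m, L = as.numeric(L),
            pos_A = as.numeric(pos_A), pos_B = as.numeric(pos_B),
            eps = eps, s_a = s_a, s_b = s_b, dominance = dominance,
            rescale = as.integer(rescale),
            sample_size = as.integer(sample_size),
            sample_generations = as.integer(sort(unique(sample_generations))))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  with(p, {
    if (Np <= 0 || N <= 0 || n_burnin < 0 || L <= 0)
      stop("Np, N and L must be positive; n_burnin must be non-negative")
    if (mu < 0 || r < 0) stop("mu and r must be non-negative")
    if (m < 0 || m > 0.5) stop("m must lie in [0, 0.5] per source")
    if (!(pos_A >= 0 && pos_A < pos_B && pos_B < L))
      stop("locus positions must satisfy 0 <= pos_A < pos_B < L")
    if (eps < -1 || eps > 0) stop("eps must lie in [-1, 0]")
    if (s_a > 0 || s_b > 0 || s_a < -1 || s_b < -1)
      stop("s_a and s_b are ancestral-allele disadvantages in [-1, 0]")
    if (rescale < 1) stop("rescale must be a positive integer")
    if (sample_size < 1) stop("sample_size must be at least 1")
  })
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Hybrid-zone simulation parameters\n")
  cat(sprintf("  sources: 2 x %d diploids, burn-in %d generations\n",
              x$Np, x$n_burnin))
  cat(sprintf("  hybrid sink: %d diploids, m = %g per source per generation\n",
              x$N, x$m))
  cat(sprintf("  chromosome: %g bp, mu = %g, r = %g (x%d rescale)\n",
              x$L, x$mu, x$r, x$rescale))
  cat(sprintf("  incompatibility: A @ %g bp, B @ %g bp, eps = %g (%s), s = (%g, %g)\n",
              x$pos_A, x$pos_B, x$eps, x$dominance, x$s_a, x$s_b))
  cat(sprintf("  sampling: %d diploids at generations %s\n",
              x$sample_size, paste(x$sample_generations, collapse = ", ")))
  invisible(x)
}

# Table of named scenarios: epistasis, ancestral-allele selection and
# migration per scenario; recessive variants exist only where eps < 0.
scenario_table <- function() {
  data.frame(
    name = c("Default", "Low ep.", "High ep.", "Low mig.", "High mig.",
             "High mig. high ep.", "Neu.", "SL-sel.", "High SL-sel.",
             "SL-sel. and ep."),
    eps  = c(-0.1, -0.02, -0.5, -0.1, -0.1, -0.5, 0, 0, 0, -0.1),
    s    = c(0, 0, 0, 0, 0, 0, 0, -0.02, -0.1, -0.02),
    m    = c(0.005, 0.005, 0.005, 0.0005, 0.05, 0.05, 0.005, 0.005, 0.005,
             0.05),
    has_recessive = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                      FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Named scenario presets
#'
#' Returns the [sim_params()] object for one of the named study scenarios.
#' Scenarios differ in the epistasis coefficient, the single-locus
#' selection coefficients of the ancestral alleles, and the migration rate;
#' every scenario with `eps < 0` also exists in a recessive variant.
#'
#' Two scales are available.  `"full"` is the full-size system (`Np` =
#' 5000, `N` = 10000, 500 Mb chromosome scanned in 500 kb windows, with
#' the factor-10 mu/r rescaling).  `"toy"` is the calibrated desk-scale
#' system used throughout the validation studies: `Np` = 250, `N` = 500,
#' a burn-in of 2500 generations and a 5 Mb chromosome scanned in 200
#' windows of 25 kb (loci in windows 71 and 131).  Its rates keep the
#' forces that shape the detectable signature in the same relative
#' position against the 20-fold faster genetic drift: `mu` = 4e-7 gives
#' on the order of 150 SNPs per window, `r` = 1e-6 preserves the
#' full-scale expected crossover density per window (`r * w` = 0.025)
#' while each window still spans about a dozen parental linkage blocks,
#' selection coefficients are scaled 5-fold and capped at magnitude 0.5
#' (full drift compensation would make the incompatibility lethal and
#' sever admixture entirely), and migration is scaled 8-fold and capped
#' at 0.5 (20 migrants per source per generation, sustaining the
#' migration-selection balance that maintains the local distortion).
#' Samples are scheduled at hybrid generations 50, 100, 250 and 500 on
#' the compressed timescale.  The attached `"window_size"` attribute
#' (25 kb toy, 500 kb full) is the scan width the preset was designed
#' for; desk-scale scans keep the full-scale bootstrap tail of 10 slots
#' per replicate rather than 1% of the window count (see
#' [bootstrap_tail_counts()]).
#'
#' @param name scenario name, one of `"Default"`, `"Low ep."`,
#'   `"High ep."`, `"Low mig."`, `"High mig."`, `"High mig. high ep."`,
#'   `"Neu."`, `"SL-sel."`, `"High SL-sel."`, `"SL-sel. and ep."`.
#' @param dominance `"codominant"` or `"recessive"`; the purely neutral and
#'   single-locus scenarios have no recessive variant.
#' @param scale `"full"` or `"toy"`.
#' @return A [sim_params()] object.
#' @export
#' @examples
#' scenario_params("Default", scale = "toy")
scenario_params <- function(name = "Default",
                            dominance = c("codominant", "recessive"),
                            scale = c("full", "toy")) {
  dominance <- match.arg(dominance)
  scale <- match.arg(scale)
  tab <- scenario_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown scenario '", name, "'; see scenario_table()")
  if (dominance == "recessive" && !tab$has_recessive[i])
    stop("scenario '", name, "' has no recessive variant")
  base <- if (scale == "full") {
    sim_params(eps = tab$eps[i], s_a = tab$s[i], s_b = tab$s[i],
               m = tab$m[i], dominance = dominance)
  } else {
    cap_sel <- function(x) sign(x) * pmin(5 * abs(x), 0.5)
    sim_params(Np = 250, N = 500, n_burnin = 2500,
               mu = 4e-7, r = 1e-6, rescale = 1,
               L = 5e6, pos_A = 1.75e6, pos_B = 3.25e6,
               m = min(8 * tab$m[i], 0.5), eps = cap_sel(tab$eps[i]),
               s_a = cap_sel(tab$s[i]), s_b = cap_sel(tab$s[i]),
               dominance = dominance, sample_size = 50,
               sample_generations = c(50, 100, 250, 500))
  }
  attr(base, "scenario") <- name
  attr(base, "window_size") <- if (scale == "full") 5e5 else 25e3
  base
}

#' Rescale a parameter set for desk-scale runs
#'
#' Applies a single scaling factor `lambda` to a parameter set: population
#' sizes, burn-in length and sampling generations are divided by `lambda`,
#' and the per-generation rates `mu`, `r`, `m`, `|s|` and `|eps|` are
#' multiplied by `lambda`, capped at the boundary of their valid ranges
#' (`m <= 0.5`; `|eps|`, `|s| <= 0.9`, since a fully lethal genotype
#' severs all gene flow between the two genomic backgrounds and removes
#' the recombination-driven signature the scan relies on).  Optionally the
#' chromosome is shortened by `length_factor` with the locus positions
#' scaled proportionally.
#'
#' This crude compression preserves the population-scaled compound
#' parameters (`N mu`, `N r`, `N m`, `N |eps|`) but necessarily changes
#' their per-generation values; the curated `"toy"` preset of
#' [scenario_params()] instead preserves per-generation selection and
#' migration and is what the validation studies use.
#'
#' @param params a [sim_params()] object.
#' @param lambda scaling factor (> 1 shrinks the system).
#' @param length_factor factor by which to shorten the chromosome.
#' @return A rescaled [sim_params()] object.
#' @export
scale_params <- function(params, lambda, length_factor = 1) {
  validate_sim_params(params)
  stopifnot(lambda >= 1, length_factor >= 1)
  cap <- function(x, lim) sign(x) * pmin(abs(x) * lambda, lim)
  sim_params(
    Np = max(2L, as.integer(round(params$Np / lambda))),
    N = max(2L, as.integer(round(params$N / lambda))),
    n_burnin = as.integer(round(params$n_burnin / lambda)),
    mu = params$mu * lambda, r = params$r * lambda,
    m = min(params$m * lambda, 0.5),
    L = params$L / length_factor,
    pos_A = params$pos_A / length_factor,
    pos_B = params$pos_B / length_factor,
    eps = cap(params$eps, 0.9),
    s_a = cap(params$s_a, 0.9), s_b = cap(params$s_b, 0.9),
    dominance = params$dominance, rescale = params$rescale,
    sample_size = params$sample_size,
    sample_generations = pmax(1L, as.integer(round(
      params$sample_generations / lambda)))
  )
}
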