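#' Run the allopatric burn-in and return a simulation state
#'
#' Creates the two source populations (each fixed from generation 0 for
#' the derived allele at one incompatibility locus and the ancestral
#' allele at the other) and lets them diverge for `params$n_burnin`
#' generations of neutral mutation, recombination and drift.  The
#' returned state can be [clone_sim()]ed, so a single burn-in can be
#' reused by every scenario that shares the same genomic architecture.
#'
#' `hz_sim` objects have reference semantics: [found_hybrid()] and
#' [advance_generations()] modify the state in place (and return it
#' invisibly).  Use [clone_sim()] to branch independent continuations.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer; if given, `set.seed(seed)` is called
#'   first so the whole run is reproducible.  All randomness (in R and in
#'   the compiled engine) flows through R's RNG.
#' @return An object of class `hz_sim`.
#' @export
run_burn_in <- function(params, seed = NULL) {
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  h1 <- if (params$dominance == "recessive") 0 else 1
  ptr <- sim_new(params$L, params$pos_A, params$pos_B,
                 params$mu * params$rescale, params$r * params$rescale,
                 params$eps, params$s_a, params$s_b, params$m, h1,
                 params$Np, params$N)
  sim <- structure(list(ptr = ptr, params = params,
                        scenario = attr(params, "scenario")),
                   class = "hz_sim")
  if (params$n_burnin > 0) sim_advance(ptr, params$n_burnin)
  sim
}

#' Found the hybrid population
#'
#' Forms the hybrid sink population in a single generation as a 50:50
#' mixture of the two sources: each of the `N` founders is an independent
#' copy of a random individual from source 1 with probability 1/2, else
#' from source 2 (the sources are not depleted).  The hybrid generation
#' counter starts at 0.
#'
#' @param sim an `hz_sim` state from [run_burn_in()].
#' @return The state, invisibly (modified in place).
#' @export
found_hybrid <- function(sim) {
  stopifnot(inherits(sim, "hz_sim"))
  sim_found(sim$ptr)
  invisible(sim)
}

#' Advance the simulation
#'
#' Runs `n` complete life cycles.  Each cycle the two sources reproduce
#' neutrally (continuing to diverge and accumulate fixed differences);
#' once the hybrid exists it reproduces by random mating with Poisson
#' recombination and mutation, viability selection per
#' [epistatic_fitness()] (survival probability, with rejected juveniles
#' redrawn so the census size stays exactly `N`), and then a
#' Binomial(`N`, `m`) number of its individuals is replaced by copies of
#' random individuals from each new source generation.  There is no
#' migration out of the hybrid population.
#'
#' @param sim an `hz_sim` state.
#' @param n number of generations.
#' @return The state, invisibly (modified in place).
#' @export
advance_generations <- function(sim, n) {
  stopifnot(inherits(sim, "hz_sim"), n >= 0)
  sim_advance(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Deep-copy a simulation state
#'
#' @param sim an `hz_sim` state.
#' @return An independent copy that shares no state with `sim`.
#' @export
clone_sim <- function(sim) {
  stopifnot(inherits(sim, "hz_sim"))
  structure(list(ptr = sim_clone(sim$ptr), params = sim$params,
                 scenario = sim$scenario),
            class = "hz_sim")
}

#' @export
print.hz_sim <- function(x, ...) {
  info <- sim_info(x$ptr)
  cat("hz_sim state\n")
  cat(sprintf("  sources: 2 x %d diploids, %d burn-in generations done\n",
              info$Np, as.integer(info$gen_burnin)))
  if (info$founded) {
    cat(sprintf("  hybrid: %d diploids at generation %d\n", info$N,
                as.integer(info$generation)))
  } else {
    cat("  hybrid: not yet founded\n")
  }
  invisible(x)
}

#' Current generation counters of a simulation state
#'
#' @param sim an `hz_sim` state.
#' @return A list with `gen_burnin` (parental generations completed),
#'   `generation` (hybrid generation, `-1` before founding) and `founded`.
#' @export
sim_generation <- function(sim) {
  stopifnot(inherits(sim, "hz_sim"))
  info <- sim_info(sim$ptr)
  list(gen_burnin = as.integer(info$gen_burnin),
       generation = as.integer(info$generation),
       founded = info$founded)
}

#' Population summaries of a simulation state
#'
#' Segregating-site and fixed-derived-site counts per source population,
#' the number of neutral fixed differences between the sources, and (once
#' founded) the hybrid frequencies of the two incompatible derived
#' alleles.
#'
#' @param sim an `hz_sim` state.
#' @return A list; see Details in the engine documentation.
#' @export
sim_summary <- function(sim) {
  stopifnot(inherits(sim, "hz_sim"))
  sim_stats(sim$ptr)
}

#' Draw a polarized haplotype sample
#'
#' Samples `sample_size` diploid individuals without replacement (sampled
#' individuals are not removed from the population) and returns their
#' `2 * sample_size` haplotypes at every site that is biallelic and
#' polymorphic *in the sample*; sites fixed or absent in the sample are
#' dropped even if polymorphic in the population.  The two selected loci
#' enter as ordinary biallelic sites when polymorphic in the sample.
#'
#' @param sim an `hz_sim` state.
#' @param pop `"hybrid"` (default), `"parent1"` or `"parent2"`.
#' @param sample_size diploids to draw; defaults to the value in the
#'   state's parameters.
#' @return A `haplotype_sample` object: a list with `geno` (0/1 integer
#'   matrix, sites x haplotypes, derived-allele coding), `positions`
#'   (strictly increasing, bp, 0-based), `L`, `n_hap`, `generation` and
#'   `scenario`.
#' @export
sample_haplotypes <- function(sim, pop = "hybrid", sample_size = NULL) {
  stopifnot(inherits(sim, "hz_sim"))
  if (is.null(sample_size)) sample_size <- sim$params$sample_size
  raw <- sim_sample(sim$ptr, pop, as.integer(sample_size))
  info <- sim_info(sim$ptr)
  haplotype_sample(geno = raw$geno, positions = raw$positions,
                   L = sim$params$L,
                   generation = as.integer(info$generation),
                   scenario = sim$scenario)
}

#' Construct / validate a haplotype sample
#'
#' @param geno 0/1 integer matrix, sites in rows, haplotypes in columns.
#' @param positions site positions (bp, 0-based), strictly increasing.
#' @param L chromosome length in bp.
#' @param generation sampling generation (hybrid clock), or `NA`.
#' @param scenario optional free-text tag.
#' @return A `haplotype_sample` object.
#' @export
haplotype_sample <- function(geno, positions, L, generation = NA_integer_,
                             scenario = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(positions))
    stop("positions must have one entry per row of geno")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(positions) && (min(positions) < 0 || max(positions) >= L))
    stop("positions must lie in [0, L)")
  if (length(geno) && !all(geno %in% 0:1))
    stop("geno must be a 0/1 derived-allele matrix")
  if (nrow(geno)) {
    dac <- rowSums(geno)
    if (any(dac == 0) || any(dac == ncol(geno)))
      stop("every retained site must be polymorphic in the sample")
  }
  structure(list(geno = geno, positions = as.numeric(positions),
                 L = as.numeric(L), n_hap = ncol(geno),
                 generation = generation, scenario = scenario),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf(
    "haplotype_sample: %d segregating sites x %d haplotypes (L = %g bp)\n",
    nrow(x$geno), x$n_hap, x$L))
  if (!is.na(x$generation))
    cat(sprintf("  sampled at hybrid generation %d\n", x$generation))
  if (!is.null(x$scenario)) cat(sprintf("  scenario: %s\n", x$scenario))
  invisible(x)
}

#' Simulate a scenario end to end
#'
#' Convenience pipeline: burn-in, hybrid founding, then advancing through
#' the scheduled sampling generations, drawing a haplotype sample at each.
#' An existing burned-in state can be supplied to reuse one burn-in across
#' replicates and scenarios sharing a genomic architecture (the supplied
#' state is cloned, never modified).
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed.
#' @param burn_in optional `hz_sim` state that has completed its burn-in.
#' @param sample_generations overrides `params$sample_generations`.
#' @return A list with `samples` (named list of `haplotype_sample`s, one
#'   per sampling generation), `truth` (locus positions), and `state`
#'   (the final `hz_sim`).
#' @export
run_scenario <- function(params, seed = NULL, burn_in = NULL,
                         sample_generations = NULL) {
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  gens <- sort(unique(as.integer(
    if (is.null(sample_generations)) params$sample_generations
    else sample_generations)))
  sim <- if (is.null(burn_in)) {
    run_burn_in(params)
  } else {
    same <- function(f) isTRUE(all.equal(params[[f]], burn_in$params[[f]]))
    if (!all(vapply(c("Np", "N", "L", "pos_A", "pos_B", "mu", "r",
                      "rescale"), same, TRUE)))
      stop("burn_in state has a different genomic architecture")
    s <- clone_sim(burn_in)
    sim_set_selection(s$ptr, params$eps, params$s_a, params$s_b, params$m,
                      if (params$dominance == "recessive") 0 else 1)
    s$params <- params
    s$scenario <- attr(params, "scenario") %||% s$scenario
    s
  }
  found_hybrid(sim)
  samples <- list()
  at <- 0L
  for (g in gens) {
    advance_generations(sim, g - at)
    at <- g
    samples[[as.character(g)]] <- sample_haplotypes(sim)
  }
  list(samples = samples,
       truth = list(pos_A = params$pos_A, pos_B = params$pos_B),
       state = sim)
}

#' Window indices of the incompatibility loci
#'
#' @param params a [sim_params()] object.
#' @param window_size window width in bp.
#' @return Integer vector of length 2 (1-based window indices).
#' @export
locus_windows <- function(params, window_size) {
  validate_sim_params(params)
  as.integer(floor(c(params$pos_A, params$pos_B) / window_size)) + 1L
}
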