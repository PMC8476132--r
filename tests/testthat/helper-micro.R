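# Shared micro-scale fixtures, built lazily and cached for the test run.

micro_params <- function(eps = -0.1, m = 0.01, mu = 5e-7, r = 1e-7,
                         Np = 50, N = 100, n_burnin = 200,
                         sample_size = 20, ...) {
  sim_params(Np = Np, N = N, n_burnin = n_burnin, mu = mu, r = r,
             rescale = 1, L = 1e6, pos_A = 2.5e5, pos_B = 7.5e5,
             m = m, eps = eps, sample_size = sample_size,
             sample_generations = c(5, 20), ...)
}

.micro_cache <- new.env(parent = emptyenv())

# a small hybrid sample reused by spectra / detection / io tests
micro_sample <- function() {
  if (is.null(.micro_cache$sample)) {
    p <- micro_params()
    sim <- run_burn_in(p, seed = 421)
    found_hybrid(sim)
    advance_generations(sim, 20)
    .micro_cache$sample <- sample_haplotypes(sim)
  }
  .micro_cache$sample
}

# hand-constructable tail_counts object
fake_tail <- function(kappa, n_b = 1000, tail_size = 10,
                      window_size = 5e5) {
  structure(list(kappa = kappa, n_b = n_b, tail_size = tail_size,
                 W = length(kappa), window_size = window_size,
                 generation = NA_integer_),
            class = "tail_counts")
}

# brute-force multinomial probability by exhaustive enumeration of all
# ordered draw sequences (independent oracle for sfs_log_probability)
enumerate_multinomial_prob <- function(local, p) {
  k <- sum(local)
  if (k == 0) return(1)
  nb <- length(local)
  seqs <- do.call(expand.grid, rep(list(seq_len(nb)), k))
  tot <- 0
  for (i in seq_len(nrow(seqs))) {
    draw <- as.integer(seqs[i, ])
    if (all(tabulate(draw, nbins = nb) == local))
      tot <- tot + prod(p[draw])
  }
  tot
}
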