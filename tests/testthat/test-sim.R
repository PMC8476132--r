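test_that("identical parameters and seed give bit-identical samples", {
  p <- micro_params()
  run <- function() {
    sim <- run_burn_in(p, seed = 99)
    found_hybrid(sim)
    advance_generations(sim, 10)
    sample_haplotypes(sim)
  }
  s1 <- run()
  s2 <- run()
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$positions, s2$positions)
})

test_that("without mutation the sources differ only at the two loci", {
  p <- micro_params(mu = 0, n_burnin = 50)
  sim <- run_burn_in(p, seed = 7)
  st <- sim_summary(sim)
  expect_identical(unname(st$seg_sites), c(0L, 0L))
  expect_identical(st$n_fixed_diff, 0L)  # neutral fixed differences only
  # a sample from a monomorphic source is empty but well-formed
  s <- sample_haplotypes(sim, pop = "parent1", sample_size = 5)
  expect_identical(nrow(s$geno), 0L)
  ws <- window_sfs(s, 1e5)
  expect_true(all(ws$counts == 0))
})

test_that("founding is a seeded 50:50 lottery with the expected allele
           frequencies", {
  p <- micro_params(mu = 0, n_burnin = 0, N = 2)
  # N = 2: exact founder composition reproducible under the seed
  draw <- function(seed) {
    sim <- run_burn_in(p, seed = seed)
    found_hybrid(sim)
    sim_founder_sources(sim$ptr)
  }
  expect_identical(draw(5), draw(5))
  # the fixed difference lands at frequency ~1/2 on average at founding,
  # and every founder is a pure parental copy (AAbb or aaBB)
  p2 <- micro_params(mu = 0, n_burnin = 0, N = 50)
  freqs <- vapply(1:40, function(seed) {
    sim <- run_burn_in(p2, seed = seed)
    found_hybrid(sim)
    fs <- sim_founder_sources(sim$ptr)
    expect_true(all((fs$XA == 2 & fs$XB == 0) | (fs$XA == 0 & fs$XB == 2)))
    mean(fs$XA) / 2
  }, numeric(1))
  expect_gt(mean(freqs), 0.42)
  expect_lt(mean(freqs), 0.58)
})

test_that("burn-in diversity matches the neutral Watterson expectation", {
  # theta = 4 Np mu L = 40; E[S] = theta * a_{2Np-1}; three replicate
  # burn-ins of 10 * 2Np generations should land near it
  Np <- 50; mu <- 1e-6; L <- 1e6
  theta <- 4 * Np * mu * L
  a1 <- sum(1 / seq_len(2 * Np - 1))
  a2 <- sum(1 / seq_len(2 * Np - 1)^2)
  expectS <- theta * a1
  sdS <- sqrt(theta * a1 + theta^2 * a2)
  p <- micro_params(mu = mu, Np = Np, n_burnin = 10 * 2 * Np)
  S <- vapply(1:3, function(seed) {
    st <- sim_summary(run_burn_in(p, seed = 100 + seed))
    mean(st$seg_sites)
  }, numeric(1))
  expect_gt(mean(S), expectS - 2.5 * sdS / sqrt(3))
  expect_lt(mean(S), expectS + 2.5 * sdS / sqrt(3))
})

test_that("sampling respects size, polymorphism and population bounds", {
  s <- micro_sample()
  expect_identical(ncol(s$geno), 40L)          # 20 diploids
  dac <- rowSums(s$geno)
  expect_true(all(dac >= 1 & dac <= 39))       # polymorphic in sample
  expect_true(all(diff(s$positions) > 0))
  p <- micro_params()
  sim <- run_burn_in(p, seed = 1)
  expect_error(sample_haplotypes(sim, pop = "parent1", sample_size = 51),
               "exceeds")
  expect_error(sample_haplotypes(sim), "not been founded")
})

test_that("migration pins the sink SFS mass at intermediate frequency", {
  # same burn-in, two futures: an isolated hybrid population loses its
  # frequency-0.5 mode while a sink population keeps it
  p_mig <- micro_params(eps = 0, m = 0.05, n_burnin = 1500, Np = 60,
                        N = 120, mu = 1e-6)
  sim0 <- run_burn_in(p_mig, seed = 2026)
  # fraction of SNPs at intermediate frequency (the fixed-difference
  # mass lives here; at this population size it wanders around 1/2)
  intermediate <- function(burn, params, gens) {
    res <- run_scenario(params, burn_in = burn, sample_generations = gens)
    sfs <- sample_sfs(res$samples[[as.character(gens)]])
    bins <- seq_along(sfs) / (length(sfs) + 1)
    sum(sfs[bins >= 0.2 & bins <= 0.8]) / sum(sfs)
  }
  p_iso <- micro_params(eps = 0, m = 0, n_burnin = 1500, Np = 60,
                        N = 120, mu = 1e-6)
  set.seed(31)
  with_mig <- intermediate(sim0, p_mig, 300)
  set.seed(31)
  no_mig <- intermediate(sim0, p_iso, 300)
  # migration keeps refuelling the intermediate-frequency mode that an
  # isolated hybrid population loses to drift; a 1/f spectrum would put
  # only ~30% of SNPs in these bins
  expect_gt(with_mig, 0.5)
  expect_gt(with_mig, 1.3 * no_mig)
})

test_that("a neutral symmetric sink drifts around allele frequency 1/2", {
  p <- micro_params(eps = 0, m = 0.1, mu = 0, n_burnin = 0)
  f <- vapply(1:5, function(seed) {
    res <- run_scenario(p, seed = seed, sample_generations = 100)
    st <- sim_summary(res$state)
    c(st$hybrid_freq_A, st$hybrid_freq_B)
  }, numeric(2))
  expect_gt(mean(f), 0.35)
  expect_lt(mean(f), 0.65)
})

test_that("burn-in states can be cloned and branched independently", {
  p <- micro_params()
  bi <- run_burn_in(p, seed = 77)
  base <- sim_summary(bi)$seg_sites
  cl <- clone_sim(bi)
  found_hybrid(cl)
  advance_generations(cl, 5)
  # the original is untouched by work on the clone
  expect_identical(sim_summary(bi)$seg_sites, base)
  expect_false(sim_generation(bi)$founded)
  expect_true(sim_generation(cl)$founded)
  # retargeting to a different scenario needs a matching architecture
  p_bad <- micro_params(Np = 40)
  expect_error(run_scenario(p_bad, burn_in = bi, sample_generations = 5),
               "architecture")
})
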