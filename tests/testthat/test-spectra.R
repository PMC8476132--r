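test_that("windows tile the chromosome and conserve the global SFS", {
  # 500 Mb in 500 kb windows -> 1000 windows
  g <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L), nrow = 2)
  s <- haplotype_sample(g, positions = c(1e6, 4.99e8), L = 5e8)
  ws <- window_sfs(s, 5e5)
  expect_identical(ws$W, 1000L)
  expect_identical(as.integer(colSums(ws$counts)), ws$global)
  expect_identical(sum(ws$global), 2L)
  # per-window placement: floor(pos / w)
  expect_identical(unname(which(ws$snp_count > 0)), c(3L, 999L))
  # a partial final window is kept
  expect_identical(window_sfs(s, 3e5)$W, 1667L)
  # conservation holds on a real simulated sample
  ws2 <- window_sfs(micro_sample(), 5e4)
  expect_identical(as.integer(colSums(ws2$counts)), ws2$global)
  expect_identical(sum(ws2$global), nrow(micro_sample()$geno))
})

test_that("a window's SFS counts derived copies per site", {
  # 4 haplotypes, derived counts (1, 2, 2) -> SFS [1, 2, 0]
  g <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L))
  s <- haplotype_sample(g, positions = c(10, 20, 30), L = 100)
  ws <- window_sfs(s, 100)
  expect_identical(as.integer(ws$counts[1, ]), c(1L, 2L, 0L))
})

test_that("multinomial window probabilities match their anchors", {
  # all-ones over 100 equiprobable categories: 100! / 100^100
  lp <- sfs_log_probability(rep(1, 100), rep(1, 100))
  expect_equal(lp, lgamma(101) - 100 * log(100), tolerance = 1e-12)
  expect_equal(exp(lp), 9.33e-43, tolerance = 5e-4)
  # empty local spectrum is certain
  expect_identical(sfs_log_probability(c(0, 0), c(3, 1)), 0)
  # two bins: p = (3/4, 1/4), local (2, 0) -> 0.75^2
  expect_equal(exp(sfs_log_probability(c(2, 0), c(3, 1))), 0.5625,
               tolerance = 1e-12)
  # a bin occupied locally but empty globally is impossible
  expect_error(sfs_log_probability(c(1, 1), c(2, 0)), "zero")
})

test_that("log-probabilities agree with exhaustive enumeration", {
  set.seed(88)
  for (nb in 2:4) {
    p <- rgamma(nb, 2) + 0.1
    p <- p / sum(p)
    global <- round(p * 1e6)
    for (k in c(1, 3, 6)) {
      locals <- as.matrix(expand.grid(rep(list(0:k), nb)))
      locals <- locals[rowSums(locals) == k, , drop = FALSE]
      for (i in seq_len(nrow(locals))) {
        got <- exp(sfs_log_probability(locals[i, ], global))
        want <- enumerate_multinomial_prob(locals[i, ],
                                           global / sum(global))
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("window scores are permutation-invariant, non-positive and
           shrink with the SNP count", {
  set.seed(12)
  global <- c(40, 25, 10, 5)
  local <- c(4, 2, 1, 0)
  base <- sfs_log_probability(local, global)
  expect_lte(base, 0)
  for (i in 1:5) {
    perm <- sample(4)
    expect_equal(sfs_log_probability(local[perm], global[perm]), base,
                 tolerance = 1e-12)
  }
  # local spectra exactly proportional to the global frequencies still
  # become less probable as the number of SNPs grows (coin-flip effect)
  props <- c(3, 2, 1)
  lps <- vapply(c(6, 12, 18, 24), function(k)
    sfs_log_probability(k / 6 * props, props * 100), numeric(1))
  expect_true(all(diff(lps) < 0))
})

test_that("windowed scoring runs off a sample and flags empty windows as
           certain", {
  df <- window_log_probabilities(micro_sample(), 5e4)
  expect_identical(nrow(df), 20L)
  expect_true(all(df$log_prob <= 0))
  expect_true(all(df$log_prob[df$n_snp == 0] == 0))
  # the least probable window need not be the SNP-richest one
  expect_false(which.min(df$log_prob) == which.max(df$n_snp) &&
                 cor(df$n_snp, df$log_prob) > -0.999)
})

test_that("the predicted founding spectrum halves parental frequencies
           and stacks fixed differences at 1/2", {
  nb <- 39
  par1 <- c(rep(10, 5), rep(0, nb - 5))
  pred <- predict_initial_hybrid_sfs(par1, par1 * 0, 0)
  # a site at parental frequency f segregates at expected frequency f/2,
  # so the expected total number of derived copies is halved (bin 0
  # carries no copies and the fixed bin is negligible here)
  expect_equal(sum(seq_len(nb) * pred), sum(seq_len(5) * 10) / 2,
               tolerance = 1e-3)
  # fixed differences pile up around frequency 0.5
  pred_fd <- predict_initial_hybrid_sfs(rep(0, nb), rep(0, nb), 1000)
  expect_identical(which.max(pred_fd), 20L)
  expect_equal(sum(pred_fd), 1000, tolerance = 0.01)
  # the relative central mass grows with the divergence level
  central <- function(nfd) {
    x <- predict_initial_hybrid_sfs(par1, par1, nfd)
    sum(x[18:22]) / sum(x)
  }
  expect_gt(central(500), central(50))
  expect_error(predict_initial_hybrid_sfs(1:3, 1:4), "same number")
})

test_that("the simulator's founding spectrum matches the prediction", {
  p <- micro_params(mu = 1e-6, Np = 60, N = 120, n_burnin = 1200,
                    sample_size = 30)
  sim <- run_burn_in(p, seed = 3001)
  nfd <- sim_summary(sim)$n_fixed_diff
  s1 <- sample_haplotypes(sim, pop = "parent1", sample_size = 30)
  s2 <- sample_haplotypes(sim, pop = "parent2", sample_size = 30)
  pred <- predict_initial_hybrid_sfs(sample_sfs(s1), sample_sfs(s2), nfd)
  # the prediction is an expectation over foundings: average re-founded
  # replicates, one generation after founding so that haplotypes are no
  # longer tied in founder pairs
  obs <- rowMeans(vapply(1:10, function(i) {
    h <- clone_sim(sim)
    found_hybrid(h)
    advance_generations(h, 1)
    as.numeric(sample_sfs(sample_haplotypes(h, sample_size = 30)))
  }, numeric(59)))
  # the fixed-difference mode sits at frequency 1/2 ...
  expect_gt(sum(obs[28:32]), sum(obs[14:18]))
  # ... and the averaged spectrum tracks the prediction closely
  expect_gt(cor(pred, obs), 0.85)
  expect_lt(abs(sum(pred) - sum(obs)) / sum(obs), 0.25)
})
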