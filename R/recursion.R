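#' Deterministic two-locus gamete-frequency recursion for the hybrid sink
#'
#' Infinite-population recursion on the four gamete frequencies (AB, Ab,
#' aB, ab) in the hybrid population: random union of gametes, viability
#' selection per [epistatic_fitness()], meiosis with recombination
#' fraction `c_rec` between the loci, then replacement of a fraction `m`
#' of the gamete pool by `Ab` gametes (source 1) and `m` by `aB` gametes
#' (source 2).  Iterated from the 50:50 founding composition
#' `(0, 1/2, 1/2, 0)` until stationarity, it gives the deterministic limit
#' of the simulator's allele-frequency dynamics at the two selected loci,
#' and serves as an independent check on the individual-based engine.
#'
#' Under strong codominant epistasis (`eps = -0.5`) and high migration
#' (`m = 0.05` per source) the incompatible derived alleles equilibrate
#' near frequency 0.3, a migration-selection balance in which neither
#' parental haplotype can be purged.
#'
#' @param eps,s_a,s_b,dominance selection parameters as in
#'   [epistatic_fitness()].
#' @param m migration rate per source per generation.
#' @param c_rec recombination fraction between the two loci (0.5 = free
#'   recombination).
#' @param init initial gamete frequencies `c(AB, Ab, aB, ab)`.
#' @param max_gen iteration cap.
#' @param tol stationarity tolerance on the gamete frequencies.
#' @return A list with elements `gametes` (named stationary frequencies),
#'   `p_A`, `p_B` (derived-allele frequencies), `generations` (iterations
#'   used) and `converged`.
#' @export
#' @examples
#' two_locus_recursion(eps = -0.5, m = 0.05)$p_A
two_locus_recursion <- function(eps = -0.1, s_a = 0, s_b = 0,
                                dominance = c("codominant", "recessive"),
                                m = 0.005, c_rec = 0.5,
                                init = c(AB = 0, Ab = 0.5, aB = 0.5, ab = 0),
                                max_gen = 100000, tol = 1e-12) {
  dominance <- match.arg(dominance)
  stopifnot(length(init) == 4, all(init >= 0), abs(sum(init) - 1) < 1e-8,
            m >= 0, m <= 0.5, c_rec >= 0, c_rec <= 0.5)
  a_of <- c(1, 1, 0, 0)  # derived-A content of gametes AB, Ab, aB, ab
  b_of <- c(1, 0, 1, 0)
  # fitness of the 16 ordered genotypes
  W <- outer(1:4, 1:4, function(i, j)
    epistatic_fitness(a_of[i] + a_of[j], b_of[i] + b_of[j],
                      eps = eps, s_a = s_a, s_b = s_b,
                      dominance = dominance))
  # meiosis tensor: P(gamete g | parent haplotypes i, j)
  Tr <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (g in 1:4) {
    p <- 0
    if (a_of[g] == a_of[i] && b_of[g] == b_of[i]) p <- p + 0.5 * (1 - c_rec)
    if (a_of[g] == a_of[i] && b_of[g] == b_of[j]) p <- p + 0.5 * c_rec
    if (a_of[g] == a_of[j] && b_of[g] == b_of[j]) p <- p + 0.5 * (1 - c_rec)
    if (a_of[g] == a_of[j] && b_of[g] == b_of[i]) p <- p + 0.5 * c_rec
    Tr[i, j, g] <- p
  }
  x <- init / sum(init)
  mig <- m * c(0, 1, 0, 0) + m * c(0, 0, 1, 0)
  converged <- FALSE
  gen <- 0L
  while (gen < max_gen) {
    gen <- gen + 1L
    xw <- outer(x, x) * W
    if (sum(xw) <= 0) stop("mean fitness is zero; no viable genotypes")
    xp <- vapply(1:4, function(g) sum(xw * Tr[, , g]), numeric(1))
    xp <- xp / sum(xp)
    xp <- (1 - 2 * m) * xp + mig
    if (max(abs(xp - x)) < tol) {
      x <- xp
      converged <- TRUE
      break
    }
    x <- xp
  }
  names(x) <- c("AB", "Ab", "aB", "ab")
  list(gametes = x, p_A = unname(x[1] + x[2]), p_B = unname(x[1] + x[3]),
       generations = gen, converged = converged)
}
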