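#' Viability of a two-locus incompatibility genotype
#'
#' Multiplicative fitness of a diploid genotype at the two interacting
#' loci.  With `XA` and `XB` the derived-allele counts (0, 1 or 2) at loci
#' A and B,
#'
#' \deqn{w = (1+s_a)^{2-X_A} (1+s_b)^{2-X_B} (1 + h_{X_A X_B}\,\epsilon)^{X_A X_B}}
#'
#' where `s_a`, `s_b` are the (non-positive) selection coefficients of the
#' ancestral alleles, `eps` is the epistasis coefficient of the
#' incompatibility, and the dominance coefficient of the epistatic term,
#' `h_k` with `k = XA * XB`, equals 1 for `k` in {2, 4} in both dominance
#' modes; for the double heterozygote (`k = 1`) it is 0 when the
#' incompatibility is recessive and 1 when it is codominant.  Fitness is
#' interpreted by the simulator as the probability of surviving to
#' adulthood.
#'
#' @param XA,XB derived-allele counts at loci A and B; each must be 0, 1
#'   or 2 (vectors are recycled).
#' @param eps epistasis coefficient, `-1 <= eps <= 0`.
#' @param s_a,s_b ancestral-allele selection coefficients, in `[-1, 0]`.
#' @param dominance `"codominant"` or `"recessive"`.
#' @return Numeric vector of fitness values.
#' @export
#' @examples
#' # a codominant incompatibility with eps = -0.5 halves F1 viability and
#' # reduces the double homozygote's by 94% (0.5^4 = 0.0625):
#' epistatic_fitness(1, 1, eps = -0.5)
#' epistatic_fitness(2, 2, eps = -0.5)
#' # the recessive double heterozygote pays no cost:
#' epistatic_fitness(1, 1, eps = -0.5, dominance = "recessive")
epistatic_fitness <- function(XA, XB, eps = -0.1, s_a = 0, s_b = 0,
                              dominance = c("codominant", "recessive")) {
  dominance <- match.arg(dominance)
  if (!all(XA %in% 0:2) || !all(XB %in% 0:2))
    stop("XA and XB must be derived-allele counts in {0, 1, 2}")
  n <- max(length(XA), length(XB))
  XA <- rep_len(XA, n); XB <- rep_len(XB, n)
  k <- XA * XB
  h <- ifelse(k == 1, if (dominance == "recessive") 0 else 1, 1)
  (1 + s_a)^(2 - XA) * (1 + s_b)^(2 - XB) * (1 + h * eps)^k
}
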