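// Individual-based forward simulator of a two-source / hybrid-sink system
// with two-locus epistatic viability selection.
//
// Genomes are sparse: each haplotype is a sorted vector of the (continuous,
// effectively unique) positions at which it carries the derived allele at a
// neutral site.  The two selected loci are tracked separately as 0/1 states
// per haplotype, so neutral machinery never has to special-case them.
// All randomness goes through R's RNG, so a set.seed() on the R side makes
// whole runs bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

struct Pop {
  int nd = 0;                            // diploid individuals
  std::vector<std::vector<double>> hap;  // 2*nd sorted derived positions
  std::vector<uint8_t> A, B;             // derived state at the selected loci

  void init(int nd_, uint8_t a, uint8_t b) {
    nd = nd_;
    hap.assign(2 * (size_t)nd_, std::vector<double>());
    A.assign(2 * (size_t)nd_, a);
    B.assign(2 * (size_t)nd_, b);
  }
};

struct SimState {
  double L, posA, posB, mu, r, eps, sa, sb, m, h1;
  int Np, N;
  double muL, rL;
  long gen_burnin = 0;  // parental generations completed
  long gen = -1;        // hybrid generation; -1 before founding
  bool founded = false;
  Pop p1, p2, hyb;
  // scratch buffers reused across gametes / generations
  std::vector<double> bp, mut;
  Pop np1, np2, nhyb;
};

inline double genotype_fitness(const SimState& S, int XA, int XB) {
  double w = 1.0;
  if (S.sa != 0.0 && XA != 2) w *= std::pow(1.0 + S.sa, 2 - XA);
  if (S.sb != 0.0 && XB != 2) w *= std::pow(1.0 + S.sb, 2 - XB);
  int k = XA * XB;
  if (k > 0) {
    double h = (k == 1) ? S.h1 : 1.0;
    w *= std::pow(1.0 + h * S.eps, (double)k);
  }
  return w;
}

// One meiotic product of individual `ind`: Poisson(rL) crossovers at
// uniform positions, no interference; Poisson(muL) new mutations at
// uniform (continuous) positions, i.e. infinite sites.
void make_gamete(SimState& S, const Pop& P, int ind, std::vector<double>& out,
                 uint8_t& gA, uint8_t& gB) {
  out.clear();
  int k = (int)R::rpois(S.rL);
  S.bp.resize(k);
  for (int i = 0; i < k; ++i) S.bp[i] = unif_rand() * S.L;
  std::sort(S.bp.begin(), S.bp.end());
  int start = (unif_rand() < 0.5) ? 0 : 1;
  const std::vector<double>* h[2] = {&P.hap[2 * (size_t)ind],
                                     &P.hap[2 * (size_t)ind + 1]};
  double lo = 0.0;
  int cur = start;
  for (int j = 0; j <= k; ++j) {
    double hi = (j < k) ? S.bp[j] : S.L;
    const std::vector<double>& v = *h[cur];
    auto it0 = std::lower_bound(v.begin(), v.end(), lo);
    auto it1 = std::lower_bound(it0, v.end(), hi);
    out.insert(out.end(), it0, it1);
    lo = hi;
    cur ^= 1;
  }
  int parA = (int)(std::lower_bound(S.bp.begin(), S.bp.end(), S.posA) -
                   S.bp.begin());
  int parB = (int)(std::lower_bound(S.bp.begin(), S.bp.end(), S.posB) -
                   S.bp.begin());
  gA = P.A[2 * (size_t)ind + ((start + parA) & 1)];
  gB = P.B[2 * (size_t)ind + ((start + parB) & 1)];
  int nm = (int)R::rpois(S.muL);
  if (nm > 0) {
    S.mut.resize(nm);
    for (int i = 0; i < nm; ++i) S.mut[i] = unif_rand() * S.L;
    std::sort(S.mut.begin(), S.mut.end());
    size_t mid = out.size();
    out.insert(out.end(), S.mut.begin(), S.mut.end());
    std::inplace_merge(out.begin(), out.begin() + mid, out.end());
  }
}

// Wright-Fisher generation without selection (the sources: the selected
// loci are fixed within each source, so fitness is constant there).
void reproduce_neutral(SimState& S, const Pop& P, Pop& next) {
  next.nd = P.nd;
  next.hap.resize(2 * (size_t)P.nd);
  next.A.resize(2 * (size_t)P.nd);
  next.B.resize(2 * (size_t)P.nd);
  uint8_t gA, gB;
  for (int i = 0; i < P.nd; ++i) {
    int mom = (int)(unif_rand() * P.nd);
    int dad = (int)(unif_rand() * P.nd);
    make_gamete(S, P, mom, next.hap[2 * (size_t)i], gA, gB);
    next.A[2 * (size_t)i] = gA;
    next.B[2 * (size_t)i] = gB;
    make_gamete(S, P, dad, next.hap[2 * (size_t)i + 1], gA, gB);
    next.A[2 * (size_t)i + 1] = gA;
    next.B[2 * (size_t)i + 1] = gB;
  }
}

// Hybrid generation: random mating, then viability selection implemented
// as rejection sampling of juveniles (survival probability = fitness),
// keeping the census size constant.
void reproduce_hybrid(SimState& S, const Pop& P, Pop& next) {
  next.nd = P.nd;
  next.hap.resize(2 * (size_t)P.nd);
  next.A.resize(2 * (size_t)P.nd);
  next.B.resize(2 * (size_t)P.nd);
  uint8_t a1, b1, a2, b2;
  long attempts = 0;
  const long cap = 10000L * (long)P.nd + 100000L;
  for (int i = 0; i < P.nd;) {
    if (++attempts > cap)
      stop("viability selection rejected essentially all offspring; "
           "check the fitness parameters");
    int mom = (int)(unif_rand() * P.nd);
    int dad = (int)(unif_rand() * P.nd);
    make_gamete(S, P, mom, next.hap[2 * (size_t)i], a1, b1);
    make_gamete(S, P, dad, next.hap[2 * (size_t)i + 1], a2, b2);
    double w = genotype_fitness(S, a1 + a2, b1 + b2);
    if (w >= 1.0 || unif_rand() < w) {
      next.A[2 * (size_t)i] = a1;
      next.B[2 * (size_t)i] = b1;
      next.A[2 * (size_t)i + 1] = a2;
      next.B[2 * (size_t)i + 1] = b2;
      ++i;
    }
  }
}

void copy_individual(Pop& dst, int di, const Pop& src, int si) {
  dst.hap[2 * (size_t)di] = src.hap[2 * (size_t)si];
  dst.hap[2 * (size_t)di + 1] = src.hap[2 * (size_t)si + 1];
  dst.A[2 * (size_t)di] = src.A[2 * (size_t)si];
  dst.A[2 * (size_t)di + 1] = src.A[2 * (size_t)si + 1];
  dst.B[2 * (size_t)di] = src.B[2 * (size_t)si];
  dst.B[2 * (size_t)di + 1] = src.B[2 * (size_t)si + 1];
}

// One full life cycle: the sources reproduce (and keep diverging); if the
// hybrid exists it reproduces under selection and then receives
// Binomial(N, m) migrant copies from each new source generation (no
// back-migration; migrants face selection at their first reproduction).
void step(SimState& S) {
  reproduce_neutral(S, S.p1, S.np1);
  std::swap(S.p1, S.np1);
  reproduce_neutral(S, S.p2, S.np2);
  std::swap(S.p2, S.np2);
  if (!S.founded) {
    ++S.gen_burnin;
    return;
  }
  reproduce_hybrid(S, S.hyb, S.nhyb);
  std::swap(S.hyb, S.nhyb);
  int m1 = (int)R::rbinom((double)S.N, S.m);
  int m2 = (int)R::rbinom((double)S.N, S.m);
  if (m1 + m2 > S.N) {  // only reachable when m is at its upper bound
    m1 = std::min(m1, S.N);
    m2 = S.N - m1;
  }
  int tot = m1 + m2;
  if (tot > 0) {
    std::vector<int> idx(S.N);
    std::iota(idx.begin(), idx.end(), 0);
    for (int t = 0; t < tot; ++t) {
      int j = t + (int)(unif_rand() * (S.N - t));
      std::swap(idx[t], idx[j]);
    }
    for (int t = 0; t < tot; ++t) {
      const Pop& src = (t < m1) ? S.p1 : S.p2;
      int si = (int)(unif_rand() * src.nd);
      copy_individual(S.hyb, idx[t], src, si);
    }
  }
  ++S.gen;
}

const Pop& pick_pop(const SimState& S, const std::string& which) {
  if (which == "parent1") return S.p1;
  if (which == "parent2") return S.p2;
  if (which == "hybrid") {
    if (!S.founded) stop("the hybrid population has not been founded yet");
    return S.hyb;
  }
  stop("unknown population '%s'", which);
}

// derived-allele counts over the whole population, position-sorted
void position_counts(const Pop& P, std::vector<double>& pos,
                     std::vector<int>& cnt) {
  std::vector<double> all;
  size_t tot = 0;
  for (const auto& h : P.hap) tot += h.size();
  all.reserve(tot);
  for (const auto& h : P.hap) all.insert(all.end(), h.begin(), h.end());
  std::sort(all.begin(), all.end());
  pos.clear();
  cnt.clear();
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    pos.push_back(all[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP sim_new(double L, double posA, double posB, double mu, double r,
             double eps, double sa, double sb, double m, double h1, int Np,
             int N) {
  XPtr<SimState> S(new SimState(), true);
  S->L = L;
  S->posA = posA;
  S->posB = posB;
  S->mu = mu;
  S->r = r;
  S->eps = eps;
  S->sa = sa;
  S->sb = sb;
  S->m = m;
  S->h1 = h1;
  S->Np = Np;
  S->N = N;
  S->muL = mu * L;
  S->rL = r * L;
  S->p1.init(Np, 1, 0);  // source 1 fixed for derived A, ancestral b
  S->p2.init(Np, 0, 1);  // source 2 fixed for ancestral a, derived B
  return S;
}

// [[Rcpp::export]]
SEXP sim_clone(SEXP sp) {
  XPtr<SimState> S(sp);
  XPtr<SimState> C(new SimState(*S), true);
  return C;
}

// [[Rcpp::export]]
void sim_set_selection(SEXP sp, double eps, double sa, double sb, double m,
                       double h1) {
  // retarget a (cloned) state to another scenario sharing the same
  // genomic architecture; the burn-in itself is neutral, so only the
  // selection and migration parameters need to change
  XPtr<SimState> S(sp);
  S->eps = eps;
  S->sa = sa;
  S->sb = sb;
  S->m = m;
  S->h1 = h1;
}

// [[Rcpp::export]]
void sim_advance(SEXP sp, int ngen) {
  XPtr<SimState> S(sp);
  for (int g = 0; g < ngen; ++g) {
    if ((g & 15) == 0) Rcpp::checkUserInterrupt();
    step(*S);
  }
}

// [[Rcpp::export]]
void sim_found(SEXP sp) {
  XPtr<SimState> S(sp);
  if (S->founded) stop("the hybrid population has already been founded");
  S->hyb.init(S->N, 0, 0);
  for (int i = 0; i < S->N; ++i) {
    const Pop& src = (unif_rand() < 0.5) ? S->p1 : S->p2;
    int si = (int)(unif_rand() * src.nd);
    copy_individual(S->hyb, i, src, si);
  }
  S->founded = true;
  S->gen = 0;
}

// [[Rcpp::export]]
List sim_info(SEXP sp) {
  XPtr<SimState> S(sp);
  return List::create(_["gen_burnin"] = (double)S->gen_burnin,
                      _["generation"] = (double)S->gen,
                      _["founded"] = S->founded, _["Np"] = S->Np,
                      _["N"] = S->N);
}

// [[Rcpp::export]]
List sim_founder_sources(SEXP sp) {
  // diagnostic: per hybrid individual, whether both its selected-locus
  // alleles descend from source 1 (A) or source 2 (B) backgrounds
  XPtr<SimState> S(sp);
  if (!S->founded) stop("the hybrid population has not been founded yet");
  IntegerVector XA(S->N), XB(S->N);
  for (int i = 0; i < S->N; ++i) {
    XA[i] = S->hyb.A[2 * (size_t)i] + S->hyb.A[2 * (size_t)i + 1];
    XB[i] = S->hyb.B[2 * (size_t)i] + S->hyb.B[2 * (size_t)i + 1];
  }
  return List::create(_["XA"] = XA, _["XB"] = XB);
}

// [[Rcpp::export]]
List sim_sample(SEXP sp, std::string pop, int nind) {
  XPtr<SimState> S(sp);
  const Pop& P = pick_pop(*S, pop);
  if (nind > P.nd)
    stop("sample_size (%d) exceeds the population size (%d)", nind, P.nd);
  if (nind < 1) stop("sample_size must be at least 1");
  // sample individuals without replacement (partial Fisher-Yates)
  std::vector<int> idx(P.nd);
  std::iota(idx.begin(), idx.end(), 0);
  for (int t = 0; t < nind; ++t) {
    int j = t + (int)(unif_rand() * (P.nd - t));
    std::swap(idx[t], idx[j]);
  }
  int H = 2 * nind;
  // neutral sites segregating in the sample
  std::vector<double> all;
  size_t tot = 0;
  for (int t = 0; t < nind; ++t)
    tot += P.hap[2 * (size_t)idx[t]].size() +
           P.hap[2 * (size_t)idx[t] + 1].size();
  all.reserve(tot);
  for (int t = 0; t < nind; ++t)
    for (int c = 0; c < 2; ++c) {
      const auto& h = P.hap[2 * (size_t)idx[t] + c];
      all.insert(all.end(), h.begin(), h.end());
    }
  std::sort(all.begin(), all.end());
  std::vector<double> pos;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    int c = (int)(j - i);
    if (c >= 1 && c <= H - 1) pos.push_back(all[i]);  // polymorphic in sample
    i = j;
  }
  // the selected loci enter as ordinary biallelic sites if polymorphic
  int cA = 0, cB = 0;
  for (int t = 0; t < nind; ++t)
    for (int c = 0; c < 2; ++c) {
      cA += P.A[2 * (size_t)idx[t] + c];
      cB += P.B[2 * (size_t)idx[t] + c];
    }
  bool useA = (cA > 0 && cA < H), useB = (cB > 0 && cB < H);
  std::vector<double> fpos;
  fpos.reserve(pos.size() + 2);
  {
    size_t k = 0;
    while (k < pos.size() && pos[k] < S->posA) fpos.push_back(pos[k++]);
    if (useA) fpos.push_back(S->posA);
    while (k < pos.size() && pos[k] < S->posB) fpos.push_back(pos[k++]);
    if (useB) fpos.push_back(S->posB);
    while (k < pos.size()) fpos.push_back(pos[k++]);
  }
  int Sn = (int)fpos.size();
  IntegerMatrix geno(Sn, H);
  int* g = geno.begin();  // column-major
  for (int t = 0; t < nind; ++t)
    for (int c = 0; c < 2; ++c) {
      int col = 2 * t + c;
      int* colp = g + (size_t)col * Sn;
      const auto& h = P.hap[2 * (size_t)idx[t] + c];
      for (double x : h) {
        auto it = std::lower_bound(fpos.begin(), fpos.end(), x);
        if (it != fpos.end() && *it == x) colp[it - fpos.begin()] = 1;
      }
      if (useA) {
        int rA = (int)(std::lower_bound(fpos.begin(), fpos.end(), S->posA) -
                       fpos.begin());
        colp[rA] = P.A[2 * (size_t)idx[t] + c];
      }
      if (useB) {
        int rB = (int)(std::lower_bound(fpos.begin(), fpos.end(), S->posB) -
                       fpos.begin());
        colp[rB] = P.B[2 * (size_t)idx[t] + c];
      }
    }
  IntegerVector ind(nind);
  for (int t = 0; t < nind; ++t) ind[t] = idx[t] + 1;
  return List::create(
      _["positions"] = NumericVector(fpos.begin(), fpos.end()),
      _["geno"] = geno, _["individuals"] = ind,
      _["selected_in_sample"] = LogicalVector::create(useA, useB));
}

// [[Rcpp::export]]
List sim_stats(SEXP sp) {
  XPtr<SimState> S(sp);
  std::vector<double> pos1, pos2;
  std::vector<int> cnt1, cnt2;
  position_counts(S->p1, pos1, cnt1);
  position_counts(S->p2, pos2, cnt2);
  auto summarize = [](const std::vector<int>& cnt, int H, int& seg,
                      int& fixed) {
    seg = fixed = 0;
    for (int c : cnt) {
      if (c == H)
        ++fixed;
      else if (c > 0)
        ++seg;
    }
  };
  int seg1, fix1, seg2, fix2;
  summarize(cnt1, 2 * S->Np, seg1, fix1);
  summarize(cnt2, 2 * S->Np, seg2, fix2);
  // neutral fixed differences: fixed in one source, absent from the other
  std::vector<double> f1, f2;
  for (size_t k = 0; k < pos1.size(); ++k)
    if (cnt1[k] == 2 * S->Np) f1.push_back(pos1[k]);
  for (size_t k = 0; k < pos2.size(); ++k)
    if (cnt2[k] == 2 * S->Np) f2.push_back(pos2[k]);
  std::vector<double> d12, d21;
  std::set_difference(f1.begin(), f1.end(), pos2.begin(), pos2.end(),
                      std::back_inserter(d12));
  std::set_difference(f2.begin(), f2.end(), pos1.begin(), pos1.end(),
                      std::back_inserter(d21));
  double fA = NA_REAL, fB = NA_REAL;
  int seg_h = NA_INTEGER;
  if (S->founded) {
    double sA = 0, sB = 0;
    for (size_t k = 0; k < S->hyb.A.size(); ++k) {
      sA += S->hyb.A[k];
      sB += S->hyb.B[k];
    }
    fA = sA / (2.0 * S->N);
    fB = sB / (2.0 * S->N);
    std::vector<double> ph;
    std::vector<int> ch;
    position_counts(S->hyb, ph, ch);
    int fx;
    summarize(ch, 2 * S->N, seg_h, fx);
  }
  return List::create(
      _["seg_sites"] = IntegerVector::create(_["parent1"] = seg1,
                                             _["parent2"] = seg2),
      _["fixed_derived"] = IntegerVector::create(_["parent1"] = fix1,
                                                 _["parent2"] = fix2),
      _["n_fixed_diff"] = (int)(d12.size() + d21.size()),
      _["hybrid_freq_A"] = fA, _["hybrid_freq_B"] = fB,
      _["hybrid_seg_sites"] = seg_h);
}
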