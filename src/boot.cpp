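// Bootstrap calibration of window SFS probabilities.
//
// Each replicate resamples the 2n sampled haplotypes with replacement,
// recomputes every window's unfolded SFS and the genome-wide SFS, scores
// each non-empty window by the multinomial log-probability of its local
// SFS given the genome-wide one, and records which windows fall in the
// lowest-1% tail.  kappa[w] counts, over replicates, how often window w
// lands in that tail.  Randomness comes from R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector boot_kappa(const IntegerMatrix& geno, const IntegerVector& win,
                         int W, int n_b, int tail_size) {
  const int S = geno.nrow(), H = geno.ncol();
  if (H < 2) stop("need at least 2 haplotypes to bootstrap");
  if (W < 1) stop("need at least one window");
  if (n_b < 1) stop("n_b must be at least 1");
  if (tail_size < 1 || tail_size > W) stop("invalid tail size");
  if (win.size() != S) stop("window index length must match site count");
  for (int s = 0; s < S; ++s)
    if (win[s] < 0 || win[s] >= W) stop("window index out of range");

  // sparse per-haplotype derived-site lists
  std::vector<std::vector<int>> sites(H);
  for (int j = 0; j < H; ++j) {
    const int* col = &geno(0, j);
    for (int s = 0; s < S; ++s)
      if (col[s]) sites[j].push_back(s);
  }

  std::vector<double> lgam(S + 2);
  for (int i = 0; i <= S + 1; ++i) lgam[i] = std::lgamma((double)i);

  std::vector<int> cnt(S), gt(H + 1), kw(W), wb((size_t)W * (H + 1));
  std::vector<double> lpbin(H + 1), lp(W);
  std::vector<std::pair<double, int>> ord;
  ord.reserve(W);
  IntegerVector kappa(W);

  for (int b = 0; b < n_b; ++b) {
    if ((b & 63) == 0) Rcpp::checkUserInterrupt();
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int t = 0; t < H; ++t) {
      int j = (int)(unif_rand() * H);
      for (int s : sites[j]) ++cnt[s];
    }
    std::fill(gt.begin(), gt.end(), 0);
    std::fill(kw.begin(), kw.end(), 0);
    std::fill(wb.begin(), wb.end(), 0);
    long ktot = 0;
    for (int s = 0; s < S; ++s) {
      int c = cnt[s];
      if (c <= 0 || c >= H) continue;  // monomorphic in the resample
      ++gt[c];
      ++kw[win[s]];
      ++wb[(size_t)win[s] * (H + 1) + c];
      ++ktot;
    }
    for (int c = 1; c < H; ++c)
      lpbin[c] = gt[c] > 0 ? std::log((double)gt[c] / (double)ktot) : 0.0;
    ord.clear();
    for (int w = 0; w < W; ++w) {
      if (kw[w] == 0) continue;  // empty windows never enter the tail
      double v = lgam[kw[w] + 1];
      const int* row = &wb[(size_t)w * (H + 1)];
      for (int c = 1; c < H; ++c) {
        int x = row[c];
        if (x) v += x * lpbin[c] - lgam[x + 1];
      }
      ord.emplace_back(v, w);
    }
    if ((int)ord.size() < tail_size)
      stop("fewer non-empty windows (%d) than the bootstrap tail size (%d)",
           (int)ord.size(), tail_size);
    // lowest-probability windows; ties broken by window index
    std::partial_sort(ord.begin(), ord.begin() + tail_size, ord.end());
    for (int t = 0; t < tail_size; ++t) ++kappa[ord[t].second];
  }
  return kappa;
}
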