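// Two-locus genealogy sampler for Monte Carlo two-locus sampling
// probabilities in the theta -> 0 limit: for each replicate simulate the
// joint genealogy of two loci separated by scaled recombination rate rho,
// then place exactly one mutation per locus at a point chosen uniformly on
// that locus's marginal tree below its local MRCA (i.e. proportional to
// branch length, conditioned on the locus being polymorphic).  The
// resulting gamete counts are folded/exchange-canonicalized and tallied.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

inline uint64_t key4(int c00, int c01, int c10, int c11, int base) {
  return ((uint64_t)((c00 * base + c01) * base + c10)) * base + c11;
}

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

} // namespace

// Canonical key for a gamete-count configuration: minimum of the 8
// equivalent configurations under allele relabeling at either locus and
// locus exchange, encoded base (n+1) as ((c00*b + c01)*b + c10)*b + c11.
// [[Rcpp::export]]
NumericVector canon_key_cpp(IntegerMatrix counts, int n) {
  int base = n + 1;
  NumericVector out(counts.nrow());
  for (int r = 0; r < counts.nrow(); ++r) {
    int c00 = counts(r, 0), c01 = counts(r, 1), c10 = counts(r, 2), c11 = counts(r, 3);
    uint64_t best = UINT64_MAX;
    for (int fa = 0; fa < 2; ++fa)
      for (int fb = 0; fb < 2; ++fb)
        for (int sw = 0; sw < 2; ++sw) {
          int a00 = c00, a01 = c01, a10 = c10, a11 = c11;
          if (fa) { std::swap(a00, a10); std::swap(a01, a11); }
          if (fb) { std::swap(a00, a01); std::swap(a10, a11); }
          if (sw) { std::swap(a01, a10); }
          uint64_t k = key4(a00, a01, a10, a11, base);
          if (k < best) best = k;
        }
    out[r] = (double)best;
  }
  return out;
}

// [[Rcpp::export]]
List sim_two_locus_cpp(int n, double rho, int reps) {
  if (n < 2 || n > 64) stop("two-locus tables support sample sizes 2..64");
  const uint64_t full = (n == 64) ? ~uint64_t(0) : ((uint64_t(1) << n) - 1);

  std::unordered_map<uint64_t, int> tally;
  std::vector<std::pair<uint64_t, uint64_t>> lin;
  lin.reserve(2 * n);

  for (int rep = 0; rep < reps; ++rep) {
    lin.clear();
    for (int i = 0; i < n; ++i)
      lin.push_back(std::make_pair(uint64_t(1) << i, uint64_t(1) << i));

    double wA = 0.0, wB = 0.0;
    uint64_t selA = 0, selB = 0;

    while (lin.size() >= 2) {
      size_t k = lin.size();
      double crate = 0.5 * double(k) * double(k - 1);
      int nboth = 0;
      for (const auto& x : lin)
        if (x.first && x.second) ++nboth;
      double rrate = 0.5 * rho * nboth;
      double tot = crate + rrate;
      double dt = exp_rand() / tot;

      // reservoir sampling of one branch point per locus, weight = time alive
      for (const auto& x : lin) {
        if (x.first) {
          wA += dt;
          if (unif_rand() * wA < dt) selA = x.first;
        }
        if (x.second) {
          wB += dt;
          if (unif_rand() * wB < dt) selB = x.second;
        }
      }

      if (unif_rand() * tot < crate) {
        int a = int(unif_rand() * k); if (a >= int(k)) a = int(k) - 1;
        int b = int(unif_rand() * (k - 1)); if (b >= int(k) - 1) b = int(k) - 2;
        if (b >= a) ++b;
        uint64_t na = lin[a].first | lin[b].first;
        uint64_t nb = lin[a].second | lin[b].second;
        if (na == full) na = 0; // local MRCA at locus A
        if (nb == full) nb = 0;
        int hi = std::max(a, b), lo = std::min(a, b);
        lin.erase(lin.begin() + hi);
        lin.erase(lin.begin() + lo);
        if (na || nb) lin.push_back(std::make_pair(na, nb));
      } else {
        // recombination: split a lineage carrying both loci
        int pick = int(unif_rand() * nboth); if (pick >= nboth) pick = nboth - 1;
        for (size_t i = 0; i < lin.size(); ++i) {
          if (lin[i].first && lin[i].second) {
            if (pick-- == 0) {
              uint64_t a = lin[i].first, b = lin[i].second;
              lin[i] = std::make_pair(a, uint64_t(0));
              lin.push_back(std::make_pair(uint64_t(0), b));
              break;
            }
          }
        }
      }
    }

    int c11 = popcount64(selA & selB);
    int c10 = popcount64(selA & ~selB & full);
    int c01 = popcount64(~selA & selB & full);
    int c00 = n - c11 - c10 - c01;

    int base = n + 1;
    uint64_t best = UINT64_MAX;
    for (int fa = 0; fa < 2; ++fa)
      for (int fb = 0; fb < 2; ++fb)
        for (int sw = 0; sw < 2; ++sw) {
          int a00 = c00, a01 = c01, a10 = c10, a11 = c11;
          if (fa) { std::swap(a00, a10); std::swap(a01, a11); }
          if (fb) { std::swap(a00, a01); std::swap(a10, a11); }
          if (sw) { std::swap(a01, a10); }
          uint64_t kk = key4(a00, a01, a10, a11, base);
          if (kk < best) best = kk;
        }
    ++tally[best];
  }

  int K = (int)tally.size();
  NumericVector keys(K);
  IntegerVector counts(K);
  int i = 0;
  for (const auto& kv : tally) {
    keys[i] = (double)kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["key"] = keys, _["count"] = counts);
}
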