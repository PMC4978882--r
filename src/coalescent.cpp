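// Neutral constant-size coalescent with recombination under a
// piecewise-constant recombination map (Hudson-style ancestral
// recombination graph, exact, tracking ancestral material per lineage).
//
// Time is measured in units of 2N generations: each pair of lineages
// coalesces at rate 1, a lineage recombines at rate rho_span/2 where
// rho_span is the scaled (4Ner) map length covered by its ancestral
// material, and mutations fall at rate theta_bp * material / 2.  Only the
// embedded jump chain is simulated for mutation/recombination/coalescence
// ordering; event times are not needed for the output.  Material whose
// descendant set reaches the full sample (local MRCA) is dropped, so every
// recorded mutation is segregating, i.e. the output is conditioned on
// biallelic sites only.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

constexpr int MW = 2; // 64-bit words per descendant mask => n <= 128

struct Mask {
  uint64_t w[MW];
  Mask() { w[0] = 0; w[1] = 0; }
  bool operator==(const Mask& o) const { return w[0] == o.w[0] && w[1] == o.w[1]; }
  bool any() const { return (w[0] | w[1]) != 0; }
};

inline Mask mask_or(const Mask& a, const Mask& b) {
  Mask r;
  r.w[0] = a.w[0] | b.w[0];
  r.w[1] = a.w[1] | b.w[1];
  return r;
}

inline void mask_set(Mask& m, int bit) { m.w[bit >> 6] |= (uint64_t(1) << (bit & 63)); }
inline bool mask_get(const Mask& m, int bit) { return (m.w[bit >> 6] >> (bit & 63)) & 1; }

struct Seg {
  double l, r; // physical bp, half-open
  Mask m;      // descendant samples of this material
};

struct GeneticMap {
  std::vector<double> xs;   // piece boundaries (size P+1), xs[0]=0, xs[P]=L
  std::vector<double> rate; // scaled rho per bp per piece (size P)
  std::vector<double> cum;  // cumulative scaled rho at boundaries

  void init() {
    cum.resize(xs.size());
    cum[0] = 0.0;
    for (size_t i = 0; i < rate.size(); ++i)
      cum[i + 1] = cum[i] + rate[i] * (xs[i + 1] - xs[i]);
  }
  double g(double x) const {
    size_t i = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
    if (i == 0) return cum.front();
    --i;
    if (i >= rate.size()) return cum.back();
    return cum[i] + (x - xs[i]) * rate[i];
  }
  double ginv(double gv) const {
    size_t i = std::upper_bound(cum.begin(), cum.end(), gv) - cum.begin();
    if (i == 0) return xs.front();
    --i;
    if (i >= rate.size()) return xs.back();
    if (rate[i] <= 0.0) return xs[i];
    return xs[i] + (gv - cum[i]) / rate[i];
  }
};

struct Lineage {
  std::vector<Seg> segs; // disjoint, sorted
  double mat;            // total material, bp
  double gl, gr;         // genetic coordinates of material span

  void refresh(const GeneticMap& map) {
    mat = 0.0;
    for (const Seg& s : segs) mat += s.r - s.l;
    if (segs.empty()) { gl = gr = 0.0; return; }
    gl = map.g(segs.front().l);
    gr = map.g(segs.back().r);
  }
};

// Union of two disjoint sorted segment lists; overlapping portions get the
// union of descendant sets, and portions whose union is the full sample are
// dropped (local MRCA reached there).
std::vector<Seg> merge_segs(std::vector<Seg> A, std::vector<Seg> B, const Mask& full) {
  std::vector<Seg> out;
  out.reserve(A.size() + B.size());
  auto push = [&out](double l, double r, const Mask& m) {
    if (r <= l) return;
    if (!out.empty() && out.back().r == l && out.back().m == m) {
      out.back().r = r;
      return;
    }
    out.push_back(Seg{l, r, m});
  };
  size_t ia = 0, ib = 0;
  while (ia < A.size() && ib < B.size()) {
    Seg& a = A[ia];
    Seg& b = B[ib];
    if (a.r <= b.l) { push(a.l, a.r, a.m); ++ia; continue; }
    if (b.r <= a.l) { push(b.l, b.r, b.m); ++ib; continue; }
    double ovl = std::max(a.l, b.l);
    double ovr = std::min(a.r, b.r);
    if (a.l < ovl) push(a.l, ovl, a.m);
    if (b.l < ovl) push(b.l, ovl, b.m);
    Mask u = mask_or(a.m, b.m);
    if (!(u == full)) push(ovl, ovr, u);
    bool a_more = a.r > ovr, b_more = b.r > ovr;
    if (a_more) a.l = ovr; else ++ia;
    if (b_more) b.l = ovr; else ++ib;
  }
  for (; ia < A.size(); ++ia) push(A[ia].l, A[ia].r, A[ia].m);
  for (; ib < B.size(); ++ib) push(B[ib].l, B[ib].r, B[ib].m);
  return out;
}

} // namespace

// [[Rcpp::export]]
List sim_region_cpp(int n, double region_length, NumericVector piece_bounds,
                    NumericVector piece_rates_bp, double theta_bp,
                    double max_events = 5e7) {
  if (n < 2 || n > 128) stop("sample size must be between 2 and 128");
  if (piece_bounds.size() != piece_rates_bp.size() + 1)
    stop("piece_bounds must have one more element than piece_rates_bp");

  GeneticMap map;
  map.xs = as<std::vector<double>>(piece_bounds);
  map.rate = as<std::vector<double>>(piece_rates_bp);
  map.init();

  Mask full;
  for (int i = 0; i < n; ++i) mask_set(full, i);

  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    Seg s;
    s.l = 0.0;
    s.r = region_length;
    mask_set(s.m, i);
    lin[i].segs.push_back(s);
    lin[i].refresh(map);
  }

  std::vector<double> mut_pos;
  std::vector<Mask> mut_mask;
  std::vector<double> breakpoints;

  double events = 0.0;
  while (lin.size() >= 2) {
    if (++events > max_events) stop("coalescent event budget exceeded");
    size_t k = lin.size();
    double crate = 0.5 * double(k) * double(k - 1);
    double rrate = 0.0, mrate = 0.0;
    for (const Lineage& x : lin) {
      rrate += 0.5 * (x.gr - x.gl);
      mrate += 0.5 * theta_bp * x.mat;
    }
    double tot = crate + rrate + mrate;
    double u = unif_rand() * tot;

    if (u < crate) {
      // coalescence of a uniform pair
      int a = int(unif_rand() * k); if (a >= int(k)) a = int(k) - 1;
      int b = int(unif_rand() * (k - 1)); if (b >= int(k) - 1) b = int(k) - 2;
      if (b >= a) ++b;
      Lineage merged;
      merged.segs = merge_segs(lin[a].segs, lin[b].segs, full);
      merged.refresh(map);
      int hi = std::max(a, b), lo = std::min(a, b);
      lin.erase(lin.begin() + hi);
      lin.erase(lin.begin() + lo);
      if (!merged.segs.empty()) lin.push_back(std::move(merged));
    } else if (u < crate + rrate) {
      // recombination on a lineage chosen proportional to its genetic span
      double target = u - crate;
      size_t i = 0;
      for (; i + 1 < lin.size(); ++i) {
        double w = 0.5 * (lin[i].gr - lin[i].gl);
        if (target < w) break;
        target -= w;
      }
      Lineage& x = lin[i];
      double gv = x.gl + unif_rand() * (x.gr - x.gl);
      double bp = map.ginv(gv);
      if (bp > x.segs.front().l && bp < x.segs.back().r) {
        Lineage left, right;
        for (const Seg& s : x.segs) {
          if (s.r <= bp) left.segs.push_back(s);
          else if (s.l >= bp) right.segs.push_back(s);
          else {
            left.segs.push_back(Seg{s.l, bp, s.m});
            right.segs.push_back(Seg{bp, s.r, s.m});
          }
        }
        if (!left.segs.empty() && !right.segs.empty()) {
          left.refresh(map);
          right.refresh(map);
          lin[i] = std::move(left);
          lin.push_back(std::move(right));
          breakpoints.push_back(bp);
        }
      }
    } else {
      // mutation on a lineage chosen proportional to its material
      double target = (u - crate - rrate) / (0.5 * theta_bp);
      size_t i = 0;
      for (; i + 1 < lin.size(); ++i) {
        if (target < lin[i].mat) break;
        target -= lin[i].mat;
      }
      const Lineage& x = lin[i];
      double off = unif_rand() * x.mat;
      for (const Seg& s : x.segs) {
        double len = s.r - s.l;
        if (off < len) {
          mut_pos.push_back(s.l + off);
          mut_mask.push_back(s.m);
          break;
        }
        off -= len;
      }
    }
  }

  // order mutations by position and expand masks to an n x S 0/1 matrix
  int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });

  NumericVector pos(S);
  IntegerMatrix geno(n, S);
  for (int j = 0; j < S; ++j) {
    int m = ord[j];
    pos[j] = mut_pos[m];
    for (int i = 0; i < n; ++i) geno(i, j) = mask_get(mut_mask[m], i) ? 1 : 0;
  }

  return List::create(_["positions"] = pos,
                      _["alleles"] = geno,
                      _["breakpoints"] = NumericVector(breakpoints.begin(), breakpoints.end()));
}
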