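#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Reference folding backend: nested secondary structure over {AU, GC, GU}
// pairs, minimum hairpin loop of 3 nt, no lonely pairs (every helix carries
// >= 2 stacked pairs).  Two objectives share one DP:
//   mode 0 ("maxpair")   maximise the number of base pairs (Nussinov);
//   mode 1 ("reference") maximise total stacking benefit, i.e. minimise a
//                        simple stacking energy.
// Stack benefit of two adjacent pairs = mean of their pair weights
// (GC 1.8, AU 1.0, GU 0.6 kcal/mol), so a helix of h pairs contributes
// (h-1) * mean weight.  The energy mode additionally charges a hairpin-loop
// initiation penalty (+3 kcal/mol per hairpin loop, Turner-like magnitude),
// which suppresses marginal side hairpins the way thermodynamic folding
// does.  The scale is calibrated so a 30-bp 50%-GC stem scores about
// -38 kcal/mol (see the methods vignette).

static const int HLOOP = 3;
static const double HP_PENALTY = 3.0;
static const double NEG_INF = -1e18;

static double pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 1.8;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 1.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 0.6;
  return 0.0;
}

struct FoldDP {
  int n;
  int mode; // 0 maxpair, 1 energy
  const std::string &s;
  std::vector<double> W; // best score on [i,j]
  std::vector<double> H; // best score on [i,j] with outer helix closing (i,j)
  std::vector<int> pairs;

  FoldDP(const std::string &seq, int m)
      : n((int)seq.size()), mode(m), s(seq),
        W((size_t)n * n, 0.0), H((size_t)n * n, NEG_INF),
        pairs(n, -1) {}

  inline double &Wat(int i, int j) { return W[(size_t)i * n + j]; }
  inline double &Hat(int i, int j) { return H[(size_t)i * n + j]; }
  inline bool can_pair(int i, int j) const {
    return pair_weight(s[i], s[j]) > 0.0;
  }
  inline double stack_benefit(int i, int j) const {
    // stack formed by pairs (i,j) and (i+1,j-1)
    return (pair_weight(s[i], s[j]) + pair_weight(s[i + 1], s[j - 1])) / 2.0;
  }

  // score of a helix of exactly h pairs closing (i,j)
  inline double helix_score(int i, int j, int h) const {
    if (mode == 0) return (double)h;
    double sc = 0.0;
    for (int d = 0; d < h - 1; ++d) sc += stack_benefit(i + d, j - d);
    return sc;
  }

  void run() {
    // spans increasing; minimal foldable span = 2*2 + HLOOP
    for (int span = 2 * 2 + HLOOP; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        // H(i,j): outer helix of h >= 2 pairs, inner segment >= HLOOP nt
        double hbest = NEG_INF;
        int hmax = (j - i + 1 - HLOOP) / 2;
        double hsc = 0.0; // cumulative stacking score of the helix
        bool ok = can_pair(i, j);
        for (int h = 2; h <= hmax && ok; ++h) {
          if (!can_pair(i + h - 1, j - h + 1)) break;
          hsc += stack_benefit(i + h - 2, j - h + 2);
          double inner = 0.0;
          int ii = i + h, jj = j - h;
          if (jj - ii + 1 >= 2 * 2 + HLOOP) inner = Wat(ii, jj);
          double sc;
          if (mode == 0) {
            sc = (double)h + inner;
          } else {
            // helix closing an empty segment opens a hairpin loop
            sc = hsc + (inner > 0.0 ? inner : -HP_PENALTY);
          }
          if (sc > hbest) hbest = sc;
        }
        Hat(i, j) = hbest;
        // W(i,j)
        double best = Wat(i + 1, j);
        for (int k = i + 2 * 2 + HLOOP - 1; k <= j; ++k) {
          double hk = Hat(i, k);
          if (hk <= NEG_INF / 2) continue;
          double rest = (k + 1 <= j - 1 && j - k >= 2 * 2 + HLOOP)
                            ? Wat(k + 1, j) : 0.0;
          double sc = hk + rest;
          if (sc > best) best = sc;
        }
        Wat(i, j) = best;
      }
    }
  }

  void trace_H(int i, int j) {
    double target = Hat(i, j);
    int hmax = (j - i + 1 - HLOOP) / 2;
    int pick = -1;
    double pickin = 0.0;
    if (!can_pair(i, j)) return;
    double hsc = 0.0;
    for (int h = 2; h <= hmax; ++h) {
      if (!can_pair(i + h - 1, j - h + 1)) break;
      hsc += stack_benefit(i + h - 2, j - h + 2);
      double inner = 0.0;
      int ii = i + h, jj = j - h;
      if (jj - ii + 1 >= 2 * 2 + HLOOP) inner = Wat(ii, jj);
      double sc = (mode == 0) ? (double)h + inner
                              : hsc + (inner > 0.0 ? inner : -HP_PENALTY);
      if (sc >= target - 1e-9) {
        pick = h; pickin = inner; // prefer the largest h achieving the score
      }
    }
    if (pick < 0) return;
    for (int d = 0; d < pick; ++d) {
      pairs[i + d] = j - d;
      pairs[j - d] = i + d;
    }
    if (pickin > 0.0) trace_W(i + pick, j - pick);
  }

  void trace_W(int i, int j) {
    while (i < j) {
      if (j - i + 1 < 2 * 2 + HLOOP) return;
      double target = Wat(i, j);
      if (target <= 0.0) return;
      bool advanced = false;
      // prefer the widest helix decomposition (outermost pairing first)
      for (int k = j; k >= i + 2 * 2 + HLOOP - 1; --k) {
        double hk = Hat(i, k);
        if (hk <= NEG_INF / 2) continue;
        double rest = (k + 1 <= j - 1 && j - k >= 2 * 2 + HLOOP)
                          ? Wat(k + 1, j) : 0.0;
        if (hk + rest >= target - 1e-9) {
          trace_H(i, k);
          i = k + 1;
          advanced = true;
          break;
        }
      }
      if (!advanced) ++i; // W(i+1,j) branch
    }
  }

  double structure_energy() const {
    double e = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      int j = pairs[i];
      if (j > i && pairs[i + 1] == j - 1 && j - 1 > i + 1)
        e -= stack_benefit(i, j);
    }
    if (mode != 0) {
      // hairpin-loop initiation penalty per loop closed with no inner pair
      for (int i = 0; i < n; ++i) {
        int j = pairs[i];
        if (j <= i) continue;
        bool empty = true;
        for (int k = i + 1; k < j; ++k)
          if (pairs[k] >= 0) { empty = false; break; }
        if (empty) e += HP_PENALTY;
      }
    }
    return e;
  }
};

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq, int mode) {
  int n = (int)seq.size();
  FoldDP dp(seq, mode);
  if (n >= 2 * 2 + HLOOP) {
    dp.run();
    dp.trace_W(0, n - 1);
  }
  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (dp.pairs[i] > i) { db[i] = '('; ++npairs; }
    else if (dp.pairs[i] >= 0 && dp.pairs[i] < i) db[i] = ')';
  }
  IntegerVector pr(n);
  for (int i = 0; i < n; ++i) pr[i] = dp.pairs[i] < 0 ? NA_INTEGER : dp.pairs[i] + 1;
  return List::create(_["dotbracket"] = db,
                      _["mfe"] = dp.structure_energy(),
                      _["n_bp"] = npairs,
                      _["pairs"] = pr,
                      _["objective"] = (n >= 2 * 2 + HLOOP) ? dp.Wat(0, n - 1) : 0.0);
}

// Mismatch counts of an ungapped full-length placement of `query` at every
// offset of `subject` (forward orientation only); used by the homology
// engine after seeding.  Returns an integer vector of length
// len(subject) - len(query) + 1.
// [[Rcpp::export(name = ".hamming_offsets")]]
IntegerVector hamming_offsets(std::string subject, std::string query) {
  int L = (int)subject.size(), m = (int)query.size();
  if (m > L) return IntegerVector(0);
  IntegerVector out(L - m + 1);
  for (int off = 0; off + m <= L; ++off) {
    int mm = 0;
    for (int k = 0; k < m; ++k)
      if (subject[off + k] != query[k]) ++mm;
    out[off] = mm;
  }
  return out;
}
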