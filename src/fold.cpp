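#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Built-in nearest-neighbor folding engine (surrogate for an external local
// folder such as RNALfold). It searches single fold-back hairpins only:
// helices of stacked pairs -- optionally interrupted by 1x1 mismatches,
// which barely destabilize a real helix -- separated by larger bulges or
// internal loops, closed by one terminal loop. No multibranch loops. A
// minimum helix length (3 pairs) suppresses 1-2 bp artifact helices, and
// candidate extraction keeps the energetically best "block" of helices
// connected by small (<= 2 nt per side) loops, so accidental background
// pairing across large loops is not absorbed into a genuine stem-loop.
//
// Energies are Turner-style nearest-neighbor approximations in kcal/mol.
// This is a documented surrogate, not a re-fit thermodynamic model.

static const double INF = 1e9;
static const int MIN_HELIX = 3;
static const double MISMATCH = 1.0;   // 1x1 internal loop inside a helix
static const int SMALL_LOOP = 2;      // max per-side loop length within a block

// base encoding: A=0 C=1 G=2 U/T=3 N=4 (N never pairs)
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 0;  // CG
  if (a == 2 && b == 1) return 1;  // GC
  if (a == 2 && b == 3) return 2;  // GU
  if (a == 3 && b == 2) return 3;  // UG
  if (a == 0 && b == 3) return 4;  // AU
  if (a == 3 && b == 0) return 5;  // UA
  return -1;
}

// stack[outer][inner], pair order CG GC GU UG AU UA
static const double STACK[6][6] = {
  {-3.3, -3.4, -2.1, -1.4, -2.1, -2.1},
  {-2.4, -3.3, -2.5, -1.5, -2.2, -2.1},
  {-1.4, -1.5, -0.5,  1.3, -0.6, -1.0},
  {-2.1, -2.5, -0.7, -0.5, -1.4, -1.3},
  {-2.1, -2.2, -1.4, -0.6, -0.9, -1.1},
  {-2.4, -2.1, -1.0, -1.3, -1.3, -0.9}
};

static inline double hairpin_energy(int l) {
  static const double H[] = {INF, INF, INF, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
  if (l < 3) return INF;
  if (l <= 9) return H[l];
  return 6.4 + 1.08 * std::log((double)l / 9.0);
}

static inline double bulge_energy(int l) {
  static const double B[] = {INF, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
  if (l <= 6) return B[l];
  return 4.4 + 1.08 * std::log((double)l / 6.0);
}

static inline double internal_energy(int n1, int n2) {
  int t = n1 + n2;
  double e;
  if (t <= 4) e = 1.7;
  else if (t == 5) e = 1.8;
  else if (t == 6) e = 2.0;
  else e = 2.0 + 1.08 * std::log((double)t / 6.0);
  double asym = 0.5 * std::abs(n1 - n2);
  return e + std::min(asym, 3.0);
}

static inline double loop_energy(int n1, int n2) {
  if (n1 == 0 || n2 == 0) return bulge_energy(n1 + n2);
  return internal_energy(n1, n2);
}

struct Fold {
  int n, maxloop;
  std::vector<int> s;
  // W[i,j]: min energy inward of helix-end pair (i,j): terminal loop or a
  //         bulge/internal loop to the next helix
  // D[i,j]: energy of a structure whose outermost helix starts at (i,j)
  //         (greedy helix walk, >= MIN_HELIX pairs, 1x1 mismatches allowed)
  std::vector<double> W, D;
  double &w(int i, int j) { return W[(size_t)i * n + j]; }
  double &d(int i, int j) { return D[(size_t)i * n + j]; }

  // walk the helix from (i,j) inward: stack when the adjacent pair exists,
  // otherwise bridge a single 1x1 mismatch; stop at the first position
  // where neither works. Returns the best end (minimum ssum + W).
  double helix_walk(int i, int j, int *end_a = NULL, int *end_b = NULL) {
    int a = i, b = j, npairs = 1;
    int pt = pair_type(s[a], s[b]);
    if (pt < 0) return INF;
    double ssum = 0.0, best = INF;
    int ba = -1, bb = -1;
    for (;;) {
      if (npairs >= MIN_HELIX && w(a, b) < INF && ssum + w(a, b) < best) {
        best = ssum + w(a, b); ba = a; bb = b;
      }
      int pt_stack = (a + 5 <= b - 1) ? pair_type(s[a + 1], s[b - 1]) : -1;
      if (pt_stack >= 0) {
        ssum += STACK[pt][pt_stack];
        a += 1; b -= 1; pt = pt_stack; ++npairs;
        continue;
      }
      int pt_mm = (a + 6 <= b - 2) ? pair_type(s[a + 2], s[b - 2]) : -1;
      if (pt_mm >= 0) {
        ssum += MISMATCH;
        a += 2; b -= 2; pt = pt_mm; ++npairs;
        continue;
      }
      break;
    }
    if (end_a) { *end_a = ba; *end_b = bb; }
    return best;
  }
};

static void fill(Fold &F) {
  int n = F.n;
  F.W.assign((size_t)n * n, INF);
  F.D.assign((size_t)n * n, INF);
  for (int span = 5; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      if (pair_type(F.s[i], F.s[j]) < 0) continue;
      // W: terminal loop or a bulge/internal loop into an inner helix
      double w = hairpin_energy(j - i - 1);
      int kmax = std::min(j - 4, i + 1 + F.maxloop);
      for (int k = i + 1; k <= kmax; ++k) {
        int n1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - (F.maxloop - n1));
        for (int l = j - 1; l >= lmin; --l) {
          int n2 = j - l - 1;
          if (n1 + n2 < 2) continue;  // stacks/1x1s live inside helices
          double inner = F.d(k, l);
          if (inner >= INF) continue;
          double e = inner + loop_energy(n1, n2);
          if (e < w) w = e;
        }
      }
      F.w(i, j) = w;
      F.d(i, j) = F.helix_walk(i, j);
    }
  }
}

struct Segment {
  std::vector<std::pair<int,int> > pairs;  // outermost first
  double stack_sum;   // stacking + mismatch penalties of the helix
  double loop_in;     // loop penalty to the next (inner) segment
  int loop_n1, loop_n2;
};

// trace the path realizing D(i,j)
static bool trace(Fold &F, int i, int j, std::vector<Segment> &segs,
                  double &hairpinE) {
  for (;;) {
    if (F.d(i, j) >= INF) return false;
    Segment seg; seg.loop_in = 0.0; seg.loop_n1 = seg.loop_n2 = 0;
    // replay the greedy walk, stopping at the best end found in fill()
    int ea = -1, eb = -1;
    F.helix_walk(i, j, &ea, &eb);
    if (ea < 0) return false;
    int a = i, b = j;
    double ssum = 0.0;
    seg.pairs.push_back(std::make_pair(a, b));
    while (!(a == ea && b == eb)) {
      int pt = pair_type(F.s[a], F.s[b]);
      int pt_stack = (a + 5 <= b - 1) ? pair_type(F.s[a + 1], F.s[b - 1]) : -1;
      if (pt_stack >= 0) {
        ssum += STACK[pt][pt_stack];
        a += 1; b -= 1;
      } else {
        ssum += MISMATCH;
        a += 2; b -= 2;
      }
      seg.pairs.push_back(std::make_pair(a, b));
    }
    seg.stack_sum = ssum;
    double w = F.w(ea, eb);
    if (std::fabs(w - hairpin_energy(eb - ea - 1)) < 1e-9) {
      segs.push_back(seg);
      hairpinE = hairpin_energy(eb - ea - 1);
      return true;
    }
    int kmax = std::min(eb - 4, ea + 1 + F.maxloop);
    bool found = false;
    for (int k = ea + 1; k <= kmax && !found; ++k) {
      int n1 = k - ea - 1;
      int lmin = std::max(k + 4, eb - 1 - (F.maxloop - n1));
      for (int l = eb - 1; l >= lmin; --l) {
        int n2 = eb - l - 1;
        if (n1 + n2 < 2) continue;
        if (F.d(k, l) >= INF) continue;
        if (std::fabs(F.d(k, l) + loop_energy(n1, n2) - w) < 1e-9) {
          seg.loop_in = loop_energy(n1, n2);
          seg.loop_n1 = n1; seg.loop_n2 = n2;
          segs.push_back(seg);
          i = k; j = l; found = true;
          break;
        }
      }
    }
    if (!found) return false;
  }
}

// pick the minimum-energy contiguous block of segments whose internal
// connecting loops are small on both sides (a canonical stem), closing the
// block's innermost pair with a hairpin loop
static bool best_block(const std::vector<Segment> &segs, double traceHairpinE,
                       int *bt0, int *bt1, double *benergy) {
  int q = (int)segs.size();
  // breakpoints after segment t when the loop to t+1 is large
  double best = INF;
  for (int t0 = 0; t0 < q; ++t0) {
    double e = 0.0;
    for (int t1 = t0; t1 < q; ++t1) {
      if (t1 > t0) {
        const Segment &prev = segs[t1 - 1];
        if (prev.loop_n1 > SMALL_LOOP || prev.loop_n2 > SMALL_LOOP) break;
        e += prev.loop_in;
      }
      e += segs[t1].stack_sum;
      std::pair<int,int> inner = segs[t1].pairs.back();
      double hpE = (t1 == q - 1) ? traceHairpinE
                                 : hairpin_energy(inner.second - inner.first - 1);
      if (hpE >= INF) continue;
      if (e + hpE < best) {
        best = e + hpE; *bt0 = t0; *bt1 = t1;
      }
    }
  }
  *benergy = best;
  return best < INF;
}

static std::string block_structure(const std::vector<Segment> &segs,
                                   int t0, int t1) {
  int lo = segs[t0].pairs.front().first;
  int hi = segs[t0].pairs.front().second;
  std::string db(hi - lo + 1, '.');
  for (int t = t0; t <= t1; ++t) {
    for (size_t x = 0; x < segs[t].pairs.size(); ++x) {
      db[segs[t].pairs[x].first - lo] = '(';
      db[segs[t].pairs[x].second - lo] = ')';
    }
  }
  return db;
}

static std::vector<int> encode(const std::string &seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': case 'a': s[i] = 0; break;
      case 'C': case 'c': s[i] = 1; break;
      case 'G': case 'g': s[i] = 2; break;
      case 'U': case 'u': case 'T': case 't': s[i] = 3; break;
      default: s[i] = 4;
    }
  }
  return s;
}

// [[Rcpp::export]]
List fold_window_cpp(std::string seq, int min_span, int max_span, int maxloop,
                     double e_cutoff, int max_candidates, double trim_delta) {
  Fold F;
  F.s = encode(seq);
  F.n = (int)F.s.size();
  F.maxloop = maxloop;
  int n = F.n;
  fill(F);

  std::vector<std::pair<double, std::pair<int,int> > > cands;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 8; j < n; ++j) {
      double e = F.d(i, j);
      if (e < e_cutoff) cands.push_back(std::make_pair(e, std::make_pair(i, j)));
    }
  }
  std::sort(cands.begin(), cands.end());

  std::vector<int> st, en;
  std::vector<double> energy;
  std::vector<std::string> structs;
  for (size_t c = 0; c < cands.size() && (int)st.size() < max_candidates; ++c) {
    std::vector<Segment> segs;
    double hpE = 0.0;
    if (!trace(F, cands[c].second.first, cands[c].second.second, segs, hpE)) {
      continue;
    }
    int t0 = 0, t1 = (int)segs.size() - 1;
    double e;
    if (!best_block(segs, hpE, &t0, &t1, &e)) continue;
    // drop weak outermost segments of the chosen block
    while (t0 < t1 &&
           segs[t0].stack_sum + segs[t0].loop_in > -trim_delta) {
      e -= segs[t0].stack_sum + segs[t0].loop_in;
      ++t0;
    }
    int ti = segs[t0].pairs.front().first;
    int tj = segs[t0].pairs.front().second;
    int span = tj - ti + 1;
    if (span < min_span || span > max_span || e >= e_cutoff) continue;
    bool clash = false;
    for (size_t u = 0; u < st.size(); ++u) {
      int ov = std::min(tj + 1, en[u]) - std::max(ti + 1, st[u]) + 1;
      if (ov > 0) { clash = true; break; }  // disjoint candidates per window
    }
    if (clash) continue;
    st.push_back(ti + 1); en.push_back(tj + 1);
    energy.push_back(e);
    structs.push_back(block_structure(segs, t0, t1));
  }
  return List::create(_["start"] = st, _["end"] = en,
                      _["energy"] = energy, _["structure"] = structs);
}

// Fold one full sequence: best single fold-back over any subinterval (full
// traced path, no block selection), as a full-length dot-bracket.
// [[Rcpp::export]]
List fold_one_cpp(std::string seq, int maxloop) {
  Fold F;
  F.s = encode(seq);
  F.n = (int)F.s.size();
  F.maxloop = maxloop;
  int n = F.n;
  fill(F);
  double best = INF; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 8; j < n; ++j)
      if (F.d(i, j) < best) { best = F.d(i, j); bi = i; bj = j; }
  std::string db(n, '.');
  double e = 0.0;
  if (bi >= 0) {
    std::vector<Segment> segs;
    double hpE = 0.0;
    if (trace(F, bi, bj, segs, hpE)) {
      for (size_t t = 0; t < segs.size(); ++t) {
        for (size_t x = 0; x < segs[t].pairs.size(); ++x) {
          db[segs[t].pairs[x].first] = '(';
          db[segs[t].pairs[x].second] = ')';
        }
      }
      e = best;
    }
  }
  return List::create(_["structure"] = db, _["energy"] = e,
                      _["start"] = bi + 1, _["end"] = bj + 1);
}
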