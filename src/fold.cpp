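// Minimum-free-energy secondary structure prediction for short RNAs
// (ITS2-sized), with bounded suboptimal enumeration.
//
// Energy model: simplified nearest-neighbour stacking (one value per
// stacked pair-type combination) + size-dependent hairpin/bulge/interior
// loop penalties (interior/bulge capped at `max_loop` unpaired bases) +
// affine multiloop cost a + b*branches + c*unpaired.  Energies are
// integers in units of 0.01 kcal/mol.  Pseudoknots excluded; G-U wobble
// allowed; min hairpin loop `min_loop`.
//
// Grammar (unambiguous, used for both the DP and the enumeration):
//   W(j)    = W(j-1) | W(i-1) + V(i,j)
//   V(i,j)  = bonus + [ hairpin | stack + V(i+1,j-1)
//                     | loopP(s1,s2) + V(k,l)
//                     | a + b + c*(h-i-1) + b + V(h,l) + ML(l+1,j-1) ]
//   ML(i,j) = c + ML(i+1,j)
//           | b + V(i,l) + ( c*(j-l)  |  ML(l+1,j) )
// ML regions contain >= 1 branch; the multiloop case of V therefore has
// >= 2 branches by construction.

#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

static const int INF = 1000000000;

struct FoldCtx {
  int n;
  std::vector<int> s;                  // 1-based nucleotide codes A0 C1 G2 U3
  std::vector<int> hairpin;            // penalty by loop size (index 0..n)
  std::vector<int> bulge;              // index 0..max_loop
  std::vector<int> interior;           // index 0..max_loop (total unpaired)
  int stack[6][6];
  int pair_bonus, ml_a, ml_b, ml_c, min_loop, max_loop;
  std::vector<int> V, ML, W;           // V, ML: (n+2)*(n+2); W: 0..n
  int pt[5][5];

  int idx(int i, int j) const { return i * (n + 2) + j; }
  int ptype(int i, int j) const { return pt[s[i]][s[j]]; }
};

static void fill_matrices(FoldCtx &C) {
  int n = C.n;
  C.V.assign((n + 2) * (n + 2), INF);
  C.ML.assign((n + 2) * (n + 2), INF);
  C.W.assign(n + 1, 0);

  for (int len = C.min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      // ---- V(i,j)
      int pt0 = C.ptype(i, j);
      if (pt0 >= 0) {
        int best = INF;
        int size = j - i - 1;
        if (size >= C.min_loop && size < (int)C.hairpin.size())
          best = std::min(best, C.hairpin[size]);
        // stack
        int pt1 = (i + 1 < j - 1) ? C.ptype(i + 1, j - 1) : -1;
        if (pt1 >= 0 && C.V[C.idx(i + 1, j - 1)] < INF)
          best = std::min(best, C.stack[pt0][pt1] + C.V[C.idx(i + 1, j - 1)]);
        // interior / bulge (total unpaired 1..max_loop)
        for (int s1 = 0; s1 <= C.max_loop; ++s1) {
          int k = i + 1 + s1;
          if (k >= j) break;
          for (int s2 = (s1 == 0 ? 1 : 0); s1 + s2 <= C.max_loop; ++s2) {
            int l = j - 1 - s2;
            if (l <= k) break;
            int vkl = C.V[C.idx(k, l)];
            if (vkl >= INF) continue;
            int pen = (s1 == 0 || s2 == 0) ? C.bulge[s1 + s2]
                                           : C.interior[s1 + s2];
            best = std::min(best, pen + vkl);
          }
        }
        // multiloop: first branch (h,l), then ML(l+1, j-1)
        for (int h = i + 1; h <= j - 2; ++h) {
          int lead = C.ml_c * (h - i - 1);
          for (int l = h + C.min_loop + 1; l <= j - 2; ++l) {
            int vhl = C.V[C.idx(h, l)];
            if (vhl >= INF) continue;
            int mlr = C.ML[C.idx(l + 1, j - 1)];
            if (mlr >= INF) continue;
            int e = C.ml_a + 2 * C.ml_b + lead + vhl + mlr;
            best = std::min(best, e);
          }
        }
        if (best < INF) C.V[C.idx(i, j)] = best + C.pair_bonus;
      }
      // ---- ML(i,j)  (>= 1 branch)
      {
        int best = INF;
        if (C.ML[C.idx(i + 1, j)] < INF)
          best = std::min(best, C.ml_c + C.ML[C.idx(i + 1, j)]);
        for (int l = i + C.min_loop + 1; l <= j; ++l) {
          int vil = C.V[C.idx(i, l)];
          if (vil >= INF) continue;
          int tail = C.ml_c * (j - l);
          if (l + 1 <= j && C.ML[C.idx(l + 1, j)] < INF)
            tail = std::min(tail, C.ML[C.idx(l + 1, j)]);
          best = std::min(best, C.ml_b + vil + tail);
        }
        if (best < INF) C.ML[C.idx(i, j)] = best;
      }
    }
  }
  for (int j = 1; j <= n; ++j) {
    int best = C.W[j - 1];
    for (int i = 1; i + C.min_loop + 1 <= j; ++i) {
      int vij = C.V[C.idx(i, j)];
      if (vij < INF) best = std::min(best, C.W[i - 1] + vij);
    }
    C.W[j] = best;
  }
}

// ---------------------------------------------------------------- traceback
// Deterministic preference: 5'-most pairing first, stacking before other
// loop closures (longest helices win ties).

static void traceback_V(FoldCtx &C, int i, int j, std::vector<int> &pair);

static void traceback_ML(FoldCtx &C, int i, int j, std::vector<int> &pair) {
  int target = C.ML[C.idx(i, j)];
  // branch starting at i?
  for (int l = i + C.min_loop + 1; l <= j; ++l) {
    int vil = C.V[C.idx(i, l)];
    if (vil >= INF) continue;
    if (C.ml_b + vil + C.ml_c * (j - l) == target) {
      traceback_V(C, i, l, pair);
      return;
    }
    if (l + 1 <= j && C.ML[C.idx(l + 1, j)] < INF &&
        C.ml_b + vil + C.ML[C.idx(l + 1, j)] == target) {
      traceback_V(C, i, l, pair);
      traceback_ML(C, l + 1, j, pair);
      return;
    }
  }
  // i unpaired
  traceback_ML(C, i + 1, j, pair);
}

static void traceback_V(FoldCtx &C, int i, int j, std::vector<int> &pair) {
  pair[i] = j; pair[j] = i;
  int target = C.V[C.idx(i, j)] - C.pair_bonus;
  int pt0 = C.ptype(i, j);
  // stack
  if (i + 1 < j - 1) {
    int pt1 = C.ptype(i + 1, j - 1);
    if (pt1 >= 0 && C.V[C.idx(i + 1, j - 1)] < INF &&
        C.stack[pt0][pt1] + C.V[C.idx(i + 1, j - 1)] == target) {
      traceback_V(C, i + 1, j - 1, pair);
      return;
    }
  }
  // interior / bulge
  for (int s1 = 0; s1 <= C.max_loop; ++s1) {
    int k = i + 1 + s1;
    if (k >= j) break;
    for (int s2 = (s1 == 0 ? 1 : 0); s1 + s2 <= C.max_loop; ++s2) {
      int l = j - 1 - s2;
      if (l <= k) break;
      int vkl = C.V[C.idx(k, l)];
      if (vkl >= INF) continue;
      int pen = (s1 == 0 || s2 == 0) ? C.bulge[s1 + s2] : C.interior[s1 + s2];
      if (pen + vkl == target) {
        traceback_V(C, k, l, pair);
        return;
      }
    }
  }
  // hairpin
  int size = j - i - 1;
  if (size >= C.min_loop && size < (int)C.hairpin.size() &&
      C.hairpin[size] == target)
    return;
  // multiloop
  for (int h = i + 1; h <= j - 2; ++h) {
    for (int l = h + C.min_loop + 1; l <= j - 2; ++l) {
      int vhl = C.V[C.idx(h, l)];
      if (vhl >= INF) continue;
      int mlr = C.ML[C.idx(l + 1, j - 1)];
      if (mlr >= INF) continue;
      if (C.ml_a + 2 * C.ml_b + C.ml_c * (h - i - 1) + vhl + mlr == target) {
        traceback_V(C, h, l, pair);
        traceback_ML(C, l + 1, j - 1, pair);
        return;
      }
    }
  }
  Rcpp::stop("internal folding error: traceback failed");
}

static std::vector<int> traceback_W(FoldCtx &C) {
  std::vector<int> pair(C.n + 1, 0);
  int j = C.n;
  while (j >= 1) {
    bool done = false;
    for (int i = 1; i + C.min_loop + 1 <= j; ++i) {
      int vij = C.V[C.idx(i, j)];
      if (vij < INF && C.W[i - 1] + vij == C.W[j]) {
        traceback_V(C, i, j, pair);
        j = i - 1;
        done = true;
        break;
      }
    }
    if (!done) {
      if (C.W[j] != C.W[j - 1]) Rcpp::stop("internal folding error");
      j -= 1;
    }
  }
  return pair;
}

// ------------------------------------------------------- suboptimal (Wuchty)

struct SubState {
  std::vector<std::array<int, 3>> iv;  // (tag 0=W,1=V,2=ML, i, j)
  std::vector<std::pair<int, int>> pairs;
  int acc;
  int rest;                            // sum of optimal energies of iv
};

struct SubCollector {
  std::vector<std::vector<std::pair<int, int>>> pairs;
  std::vector<int> energy;
  size_t cap;
  bool truncated = false;
};

static int opt_of(const FoldCtx &C, const std::array<int, 3> &t) {
  if (t[0] == 0) return C.W[t[2]];
  if (t[0] == 1) return C.V[C.idx(t[1], t[2])];
  return C.ML[C.idx(t[1], t[2])];
}

static void sub_enum(FoldCtx &C, SubState st, int thr, SubCollector &out) {
  if (out.truncated) return;
  if (st.iv.empty()) {
    if (out.pairs.size() >= out.cap) { out.truncated = true; return; }
    out.pairs.push_back(st.pairs);
    out.energy.push_back(st.acc);
    return;
  }
  std::array<int, 3> t = st.iv.back();
  st.iv.pop_back();
  st.rest -= opt_of(C, t);
  int tag = t[0], i = t[1], j = t[2];

  auto branch = [&](int cst, std::initializer_list<std::array<int, 3>> subs,
                    int pi = 0, int pj = 0) {
    int nb = st.acc + cst + st.rest;
    for (auto &s2 : subs) nb += opt_of(C, s2);
    if (nb > thr) return;
    SubState nx = st;
    nx.acc += cst;
    for (auto &s2 : subs) {
      nx.iv.push_back(s2);
      nx.rest += opt_of(C, s2);
    }
    if (pi > 0) nx.pairs.push_back(std::make_pair(pi, pj));
    sub_enum(C, nx, thr, out);
  };

  if (tag == 0) {  // W(1..j)
    if (j == 0) { sub_enum(C, st, thr, out); return; }
    for (int i2 = 1; i2 + C.min_loop + 1 <= j; ++i2)
      if (C.V[C.idx(i2, j)] < INF)
        branch(0, { {{0, 1, i2 - 1}}, {{1, i2, j}} });
    branch(0, { {{0, 1, j - 1}} });
  } else if (tag == 1) {  // V(i,j): record the pair, pay the bonus
    st.acc += C.pair_bonus;
    st.pairs.push_back(std::make_pair(i, j));
    SubState base = st;  // snapshot with pair recorded
    int pt0 = C.ptype(i, j);
    auto vbranch = [&](int cst, std::initializer_list<std::array<int, 3>> subs) {
      int nb = base.acc + cst + base.rest;
      for (auto &s2 : subs) nb += opt_of(C, s2);
      if (nb > thr) return;
      SubState nx = base;
      nx.acc += cst;
      for (auto &s2 : subs) { nx.iv.push_back(s2); nx.rest += opt_of(C, s2); }
      sub_enum(C, nx, thr, out);
    };
    if (i + 1 < j - 1) {
      int pt1 = C.ptype(i + 1, j - 1);
      if (pt1 >= 0 && C.V[C.idx(i + 1, j - 1)] < INF)
        vbranch(C.stack[pt0][pt1], { {{1, i + 1, j - 1}} });
    }
    for (int s1 = 0; s1 <= C.max_loop; ++s1) {
      int k = i + 1 + s1;
      if (k >= j) break;
      for (int s2 = (s1 == 0 ? 1 : 0); s1 + s2 <= C.max_loop; ++s2) {
        int l = j - 1 - s2;
        if (l <= k) break;
        if (C.V[C.idx(k, l)] >= INF) continue;
        int pen = (s1 == 0 || s2 == 0) ? C.bulge[s1 + s2] : C.interior[s1 + s2];
        vbranch(pen, { {{1, k, l}} });
      }
    }
    int size = j - i - 1;
    if (size >= C.min_loop && size < (int)C.hairpin.size())
      vbranch(C.hairpin[size], {});
    for (int h = i + 1; h <= j - 2; ++h)
      for (int l = h + C.min_loop + 1; l <= j - 2; ++l) {
        if (C.V[C.idx(h, l)] >= INF) continue;
        if (C.ML[C.idx(l + 1, j - 1)] >= INF) continue;
        vbranch(C.ml_a + 2 * C.ml_b + C.ml_c * (h - i - 1),
                { {{1, h, l}}, {{2, l + 1, j - 1}} });
      }
  } else {  // ML(i,j)
    for (int l = i + C.min_loop + 1; l <= j; ++l) {
      if (C.V[C.idx(i, l)] >= INF) continue;
      branch(C.ml_b + C.ml_c * (j - l), { {{1, i, l}} });
      if (l + 1 <= j && C.ML[C.idx(l + 1, j)] < INF)
        branch(C.ml_b, { {{1, i, l}}, {{2, l + 1, j}} });
    }
    if (C.ML[C.idx(i + 1, j)] < INF)
      branch(C.ml_c, { {{2, i + 1, j}} });
  }
}

// ----------------------------------------------------------------- wrappers

static FoldCtx make_ctx(const IntegerVector &seq, const List &par) {
  FoldCtx C;
  C.n = seq.size();
  C.s.assign(C.n + 1, 0);
  for (int i = 0; i < C.n; ++i) C.s[i + 1] = seq[i];
  IntegerVector hp = par["hairpin"], bu = par["bulge"], in = par["interior"];
  C.hairpin.assign(hp.begin(), hp.end());
  C.bulge.assign(bu.begin(), bu.end());
  C.interior.assign(in.begin(), in.end());
  IntegerMatrix st = par["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) C.stack[a][b] = st(a, b);
  C.pair_bonus = as<int>(par["pair_bonus"]);
  C.ml_a = as<int>(par["ml_a"]);
  C.ml_b = as<int>(par["ml_b"]);
  C.ml_c = as<int>(par["ml_c"]);
  C.min_loop = as<int>(par["min_loop"]);
  C.max_loop = as<int>(par["max_loop"]);
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) C.pt[a][b] = -1;
  C.pt[0][3] = 0; C.pt[1][2] = 1; C.pt[2][1] = 2;
  C.pt[3][0] = 3; C.pt[2][3] = 4; C.pt[3][2] = 5;
  return C;
}

// [[Rcpp::export]]
List c_fold(IntegerVector seq, List par) {
  FoldCtx C = make_ctx(seq, par);
  fill_matrices(C);
  std::vector<int> pair = traceback_W(C);
  IntegerVector p(C.n);
  for (int i = 1; i <= C.n; ++i) p[i - 1] = pair[i];
  return List::create(_["pair"] = p, _["energy"] = C.W[C.n]);
}

// [[Rcpp::export]]
List c_subopt(IntegerVector seq, List par, int delta, int max_emit) {
  FoldCtx C = make_ctx(seq, par);
  fill_matrices(C);
  int thr = C.W[C.n] + delta;
  SubCollector out;
  out.cap = (size_t)max_emit;
  SubState st;
  st.iv.push_back({{0, 1, C.n}});
  st.acc = 0;
  st.rest = C.W[C.n];
  sub_enum(C, st, thr, out);
  int m = out.pairs.size();
  List res(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector p(C.n);
    for (auto &pr : out.pairs[k]) { p[pr.first - 1] = pr.second; p[pr.second - 1] = pr.first; }
    res[k] = List::create(_["pair"] = p, _["energy"] = out.energy[k]);
  }
  return List::create(_["structures"] = res, _["mfe"] = C.W[C.n],
                      _["truncated"] = out.truncated);
}
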