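#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Anchored intermolecular duplex optimization.
//
// Bases are coded A=0, C=1, G=2, U=3.  A structure is an ordered list of
// pairs (mi_pos increasing, t_pos decreasing); its 5'-most pair sits on the
// anchor (the last window position).  Admissibility: every pair WC or G:U,
// every maximal stacked run (helix) has length >= 2, per-strand unpaired
// runs between pairs capped at max_loop_side, no G:U among the first 8
// pairs, fewer than 5 G:U pairs overall.
//
// DP state: (i, j) last pair, h in {0 = helix still length 1, 1 = helix
// closed}, and a 12-value G:U bookkeeping state s:
//   g == 0 : s = pc - 1 for pair count pc capped at 8  (s in 0..7)
//   g >= 1 : s = 7 + g, only reachable once pc >= 8    (s in 8..11)

static const double INF = 1e30;
static const double EPS = 1e-9;

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;  // A:U
  if (a == 3 && b == 0) return 1;  // U:A
  if (a == 2 && b == 1) return 2;  // G:C
  if (a == 1 && b == 2) return 3;  // C:G
  if (a == 2 && b == 3) return 4;  // G:U
  if (a == 3 && b == 2) return 5;  // U:G
  return -1;
}
static inline bool is_gu(int pt) { return pt >= 4; }
static inline bool term_pen(int pt) { return pt != 2 && pt != 3; }
static inline int gs_pc(int s) { return s <= 7 ? s + 1 : 8; }
static inline int gs_g(int s) { return s <= 7 ? 0 : s - 7; }
// state after adding one more pair (wobble = the new pair is G:U)
static inline int gs_next(int s, bool wobble) {
  int pc = gs_pc(s), g = gs_g(s);
  if (wobble) {
    if (pc < 8 || g >= 4) return -1;   // inadmissible
    return 7 + (g + 1);
  }
  if (g == 0) return std::min(pc + 1, 8) - 1;
  return s;
}

struct DuplexDP {
  int M, maxW, L;
  std::vector<double> stack;     // 36
  std::vector<double> bulge;     // L
  std::vector<double> interior;  // 2L-1 (total length 2..2L)
  double init, terminal;
  std::vector<double> E;
  std::vector<int> NP;
  std::vector<int> PAR;

  DuplexDP(int M_, int maxW_, List params) : M(M_), maxW(maxW_) {
    NumericMatrix st = params["stack"];
    stack.assign(36, 0.0);
    for (int a = 0; a < 6; ++a)
      for (int b = 0; b < 6; ++b) stack[a * 6 + b] = st(a, b);
    bulge = as<std::vector<double> >(params["bulge"]);
    interior = as<std::vector<double> >(params["interior"]);
    init = as<double>(params["init"]);
    terminal = as<double>(params["terminal"]);
    L = as<int>(params["max_loop_side"]);
    size_t n = (size_t)M * maxW * 2 * 12;
    E.assign(n, INF); NP.assign(n, 0); PAR.assign(n, -1);
  }

  inline size_t idx(int i, int j, int h, int s) const {
    return (((size_t)i * maxW + j) * 2 + h) * 12 + s;
  }

  inline void relax(size_t dst, double e, int np, int par) {
    if (e < E[dst] - EPS || (e <= E[dst] + EPS && np < NP[dst])) {
      E[dst] = e; NP[dst] = np; PAR[dst] = par;
    }
  }

  // run on window mi[0..M-1] vs win[0..W-1]; anchor = window position W-1.
  // seed_forced: restrict to structures starting with the perfect 7-pair
  // 5'-end helix (positions 1..7 on the anchor diagonal, WC only).
  // Returns true if any admissible structure exists; fills out_*.
  bool run(const int* mi, int W, const int* win, bool seed_forced,
           double& out_energy, std::vector<std::pair<int,int> >& out_pairs) {
    std::fill(E.begin(), E.end(), INF);  // indices are strided by maxW
    // -1: ordinary start; -2: seed prefix sentinel
    if (!seed_forced) {
      for (int i0 = 0; i0 < M; ++i0) {
        int pt = pair_type(mi[i0], win[W - 1]);
        if (pt < 0 || is_gu(pt)) continue;  // G:U forbidden among first 8 pairs
        size_t c = idx(i0, W - 1, 0, 0);
        double e = init + (term_pen(pt) ? terminal : 0.0);
        relax(c, e, 1, -1);
      }
    } else {
      if (W < 7 || M < 7) return false;
      double e = init;
      int prev_pt = -1;
      bool ok = true;
      for (int q = 0; q < 7; ++q) {
        int pt = pair_type(mi[q], win[W - 1 - q]);
        if (pt < 0 || is_gu(pt)) { ok = false; break; }
        if (q == 0) e += term_pen(pt) ? terminal : 0.0;
        else e += stack[prev_pt * 6 + pt];
        prev_pt = pt;
      }
      if (!ok) return false;
      relax(idx(6, W - 7, 1, 6), e, 7, -2);
    }

    for (int i = 1; i < M; ++i) {
      for (int j = W - 2; j >= 0; --j) {
        int pt2 = pair_type(mi[i], win[j]);
        if (pt2 < 0) continue;
        bool wob2 = is_gu(pt2);
        // stacked extension from (i-1, j+1)
        {
          int pt1 = pair_type(mi[i - 1], win[j + 1]);
          if (pt1 >= 0) {
            double cost = stack[pt1 * 6 + pt2];
            for (int h = 0; h < 2; ++h) {
              for (int s = 0; s < 12; ++s) {
                size_t src = idx(i - 1, j + 1, h, s);
                if (E[src] >= INF) continue;
                int s2 = gs_next(s, wob2);
                if (s2 < 0) continue;
                relax(idx(i, j, 1, s2), E[src] + cost, NP[src] + 1, (int)src);
              }
            }
          }
        }
        // loop-separated extension (bulge / interior); source helix closed
        int gimax = std::min(L, i - 1);
        for (int gi = 0; gi <= gimax; ++gi) {
          int ip = i - 1 - gi;
          int gjmax = std::min(L, W - 2 - j);
          for (int gj = (gi == 0 ? 1 : 0); gj <= gjmax; ++gj) {
            int jp = j + 1 + gj;
            int pt1 = pair_type(mi[ip], win[jp]);
            if (pt1 < 0) continue;
            double pen = (gi == 0) ? bulge[gj - 1]
                       : (gj == 0) ? bulge[gi - 1]
                       : interior[gi + gj - 2];
            for (int s = 0; s < 12; ++s) {
              size_t src = idx(ip, jp, 1, s);
              if (E[src] >= INF) continue;
              int s2 = gs_next(s, wob2);
              if (s2 < 0) continue;
              relax(idx(i, j, 0, s2), E[src] + pen, NP[src] + 1, (int)src);
            }
          }
        }
      }
    }

    // finalize: last helix closed, charge terminal penalty at the last pair
    double best = INF; int bnp = 0; long bcell = -1;
    for (int i = 0; i < M; ++i) {
      for (int j = 0; j < W; ++j) {
        int pt = pair_type(mi[i], win[j]);
        if (pt < 0) continue;
        double tp = term_pen(pt) ? terminal : 0.0;
        for (int s = 0; s < 12; ++s) {
          size_t c = idx(i, j, 1, s);
          if (E[c] >= INF) continue;
          double e = E[c] + tp;
          if (e < best - EPS || (e <= best + EPS && NP[c] < bnp)) {
            best = e; bnp = NP[c]; bcell = (long)c;
          }
        }
      }
    }
    if (bcell < 0) return false;
    out_energy = best;
    out_pairs.clear();
    long cur = bcell;
    while (cur >= 0) {
      size_t c = (size_t)cur;
      int i = (int)(c / ((size_t)maxW * 24));
      // careful: idx uses window-local maxW? we filled with this->maxW
      int rem = (int)(c % ((size_t)maxW * 24));
      int j = rem / 24;
      out_pairs.push_back(std::make_pair(i + 1, j + 1));
      int par = PAR[c];
      if (par == -1) { cur = -1; }
      else if (par == -2) {
        // seed prefix: pairs (q+1, W-q) for q = 0..5 precede the cell (7, W-6)
        for (int q = 5; q >= 0; --q)
          out_pairs.push_back(std::make_pair(q + 1, W - q));
        cur = -1;
      } else cur = par;
    }
    std::reverse(out_pairs.begin(), out_pairs.end());
    return true;
  }
};

static IntegerMatrix pairs_to_matrix(const std::vector<std::pair<int,int> >& pr) {
  IntegerMatrix m(pr.size(), 2);
  for (size_t k = 0; k < pr.size(); ++k) { m(k, 0) = pr[k].first; m(k, 1) = pr[k].second; }
  colnames(m) = CharacterVector::create("mi_pos", "t_pos");
  return m;
}

// [[Rcpp::export]]
List cpp_dp_anchor(IntegerVector mi, IntegerVector win, List params, bool seed_forced) {
  int M = mi.size(), W = win.size();
  DuplexDP dp(M, W, params);
  double e; std::vector<std::pair<int,int> > pr;
  bool found = dp.run(&mi[0], W, &win[0], seed_forced, e, pr);
  if (!found) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["energy"] = e,
                      _["pairs"] = pairs_to_matrix(pr));
}

// Full attraction profile: for every anchor p in 1..|utr| run the anchored
// optimization on the window [p - span, p].  With prune_seed, anchors where
// a perfect 5'-end >= 7-pair helix exists keep only seed structures.
// [[Rcpp::export]]
List cpp_profile(IntegerVector mi, IntegerVector utr, List params,
                 bool prune_seed, int span) {
  int M = mi.size(), N = utr.size();
  int maxW = std::min(span + 1, N);
  DuplexDP dp(M, std::max(maxW, 8), params);
  NumericVector energy(N, NA_REAL);
  LogicalVector seed(N);
  IntegerVector first_mi(N, NA_INTEGER);
  List pairs(N);
  std::vector<std::pair<int,int> > pr;
  for (int p = 1; p <= N; ++p) {
    int lo = std::max(1, p - span);
    int W = p - lo + 1;
    const int* win = &utr[lo - 1];
    double e;
    bool found = false, sflag = false;
    if (prune_seed) {
      found = dp.run(&mi[0], W, win, true, e, pr);
      sflag = found;
    }
    if (!found) {
      found = dp.run(&mi[0], W, win, false, e, pr);
      sflag = false;
      if (found && M >= 7) {
        // the general optimum may itself begin with a perfect 7-pair 5' helix
        if (pr.size() >= 7) {
          sflag = true;
          for (int q = 0; q < 7; ++q) {
            if (pr[q].first != q + 1 || pr[q].second != W - q) { sflag = false; break; }
          }
        }
      }
    }
    if (found) {
      energy[p - 1] = e;
      seed[p - 1] = sflag;
      first_mi[p - 1] = pr[0].first;
      IntegerMatrix m = pairs_to_matrix(pr);
      for (int k = 0; k < m.nrow(); ++k) m(k, 1) += lo - 1;  // UTR coordinates
      pairs[p - 1] = m;
    }
  }
  return List::create(_["energy"] = energy, _["seed"] = seed,
                      _["first_mi"] = first_mi, _["pairs"] = pairs);
}
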