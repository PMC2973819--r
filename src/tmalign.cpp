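// TM-score structural alignment kernels.
//
// The alignment search follows the TM-align recipe in simplified form:
// several families of initial residue-pair alignments (gapless threading,
// dynamic programming on secondary-structure strings, best-fragment
// superposition) are each refined by iterating {superpose on current pairs,
// rebuild the TM-weighted score matrix, realign by semi-global dynamic
// programming}.  The TM-score of a fixed alignment is maximised over
// superpositions by an iterative subset search (Kabsch on a distance-trimmed
// subset of pairs, as in the original TM-score program).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Superpose {
  arma::mat33 R;
  arma::rowvec3 muP, muQ;
  double rmsd;
};

// Optimal proper rotation mapping (P - muP) onto (Q - muQ).
static Superpose kabsch_core(const arma::mat& P, const arma::mat& Q) {
  Superpose sp;
  sp.muP = arma::mean(P, 0);
  sp.muQ = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - sp.muP, Qc = Q.each_row() - sp.muQ;
  arma::mat H = Pc.t() * Qc, U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in Kabsch superposition");
  double d = (arma::det(U) * arma::det(V) < 0) ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  sp.R = U * D * V.t();
  arma::mat diff = Pc * sp.R - Qc;
  sp.rmsd = std::sqrt(arma::accu(arma::square(diff)) / P.n_rows);
  return sp;
}

// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& P, const arma::mat& Q) {
  Superpose sp = kabsch_core(P, Q);
  return List::create(_["rotation"] = arma::mat(sp.R),
                      _["center_P"] = arma::rowvec(sp.muP),
                      _["center_Q"] = arma::rowvec(sp.muQ),
                      _["rmsd"] = sp.rmsd);
}

// Apply a superposition to the full coordinate set A.
static arma::mat apply_sp(const arma::mat& A, const Superpose& sp) {
  arma::mat Ac = A.each_row() - sp.muP;
  Ac = Ac * sp.R;
  return Ac.each_row() + sp.muQ;
}

// Squared distances between transformed A rows and B rows for given pairs
// (0-based index columns ia, ib).
static arma::vec pair_d2(const arma::mat& At, const arma::mat& B,
                         const arma::uvec& ia, const arma::uvec& ib) {
  arma::mat d = At.rows(ia) - B.rows(ib);
  return arma::sum(arma::square(d), 1);
}

struct TMResult {
  double tm = 0.0;
  double rmsd = NA_REAL;
  Superpose sp;
  bool ok = false;
};

// Maximise the TM-score of a fixed alignment over rigid superpositions.
// Seeds: the full pair set plus (optionally) contiguous windows; each seed
// iterates Kabsch-on-subset with a distance cutoff until the subset is
// stable.  `deep` switches between the thorough (final scoring) and light
// (inner refinement loop) schedules.
static TMResult tm_search_core(const arma::mat& A, const arma::mat& B,
                               const arma::uvec& ia, const arma::uvec& ib,
                               double d0, int Lt, bool deep) {
  TMResult best;
  const arma::uword n = ia.n_elem;
  if (n == 0) { best.tm = 0.0; best.ok = false; return best; }
  if (n < 3) {
    // too few pairs to define a superposition; score as unsuperposable zero
    best.tm = 0.0; best.ok = false; return best;
  }
  const double d02 = d0 * d0;
  std::vector<arma::uvec> seeds;
  seeds.push_back(arma::regspace<arma::uvec>(0, n - 1));
  if (deep && n >= 6) {
    const arma::uword h = n / 2;
    seeds.push_back(arma::regspace<arma::uvec>(0, h - 1));
    seeds.push_back(arma::regspace<arma::uvec>(n - h, n - 1));
    seeds.push_back(arma::regspace<arma::uvec>(n / 4, n / 4 + h - 1));
  }
  const int max_iter = deep ? 20 : 4;
  const double d_keep = std::max(4.5, d0);
  for (const arma::uvec& seed : seeds) {
    arma::uvec sub = seed;
    for (int it = 0; it < max_iter; ++it) {
      Superpose sp = kabsch_core(A.rows(ia.elem(sub)), B.rows(ib.elem(sub)));
      arma::mat At = apply_sp(A, sp);
      arma::vec d2 = pair_d2(At, B, ia, ib);
      const double tm = arma::accu(1.0 / (1.0 + d2 / d02)) / Lt;
      if (tm > best.tm || !best.ok) {
        best.tm = tm;
        best.sp = sp;
        best.rmsd = std::sqrt(arma::mean(d2));
        best.ok = true;
      }
      double dc = d_keep;
      arma::uvec nsub = arma::find(d2 < dc * dc);
      while (nsub.n_elem < 3) {
        dc += 0.5;
        nsub = arma::find(d2 < dc * dc);
      }
      if (nsub.n_elem == sub.n_elem && arma::all(nsub == sub)) break;
      sub = nsub;
    }
  }
  return best;
}

// [[Rcpp::export]]
List tm_eval_cpp(const arma::mat& A, const arma::mat& B,
                 const arma::umat& pairs, double d0, int Lt,
                 bool deep = true) {
  if (pairs.n_rows == 0)
    return List::create(_["tm"] = 0.0, _["rmsd"] = NA_REAL);
  arma::uvec ia = pairs.col(0) - 1, ib = pairs.col(1) - 1;
  TMResult r = tm_search_core(A, B, ia, ib, d0, Lt, deep);
  return List::create(_["tm"] = r.tm, _["rmsd"] = r.rmsd,
                      _["rotation"] = arma::mat(r.sp.R),
                      _["center_A"] = arma::rowvec(r.sp.muP),
                      _["center_B"] = arma::rowvec(r.sp.muQ));
}

// Semi-global Needleman-Wunsch with linear gap penalty and free end gaps.
// Deterministic tie-breaking: diagonal > up > left.  Returns matched pairs
// (0-based), strictly increasing in both indices.
static arma::umat nw_core(const arma::mat& S, double gap) {
  const int n1 = S.n_rows, n2 = S.n_cols;
  arma::mat H(n1 + 1, n2 + 1, arma::fill::zeros);
  arma::Mat<unsigned char> ptr(n1 + 1, n2 + 1, arma::fill::zeros);
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      const double sd = H(i - 1, j - 1) + S(i - 1, j - 1);
      const double su = H(i - 1, j) + gap;
      const double sl = H(i, j - 1) + gap;
      double m = sd;
      unsigned char p = 1;
      if (su > m) { m = su; p = 2; }
      if (sl > m) { m = sl; p = 3; }
      H(i, j) = m;
      ptr(i, j) = p;
    }
  }
  // best cell on the last row or column (free end gaps)
  int bi = n1, bj = n2;
  double bs = H(n1, n2);
  for (int j = 0; j <= n2; ++j)
    if (H(n1, j) > bs) { bs = H(n1, j); bi = n1; bj = j; }
  for (int i = 0; i <= n1; ++i)
    if (H(i, n2) > bs) { bs = H(i, n2); bi = i; bj = n2; }
  std::vector<std::pair<int, int>> rev;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const unsigned char p = ptr(i, j);
    if (p == 1) {
      rev.push_back({i - 1, j - 1});
      --i; --j;
    } else if (p == 2) {
      --i;
    } else {
      --j;
    }
  }
  arma::umat out(rev.size(), 2);
  for (size_t k = 0; k < rev.size(); ++k) {
    out(rev.size() - 1 - k, 0) = rev[k].first;
    out(rev.size() - 1 - k, 1) = rev[k].second;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix nw_align_cpp(const arma::mat& S, double gap) {
  arma::umat p = nw_core(S, gap);
  IntegerMatrix out(p.n_rows, 2);
  for (arma::uword k = 0; k < p.n_rows; ++k) {
    out(k, 0) = p(k, 0) + 1;
    out(k, 1) = p(k, 1) + 1;
  }
  return out;
}


// Fill S(i, j) = 1 / (1 + d2(At_i, B_j) / d0^2) with raw loops (hot path).
static void fill_score(const arma::mat& At, const arma::mat& B, double d02,
                       arma::mat& S) {
  const int LA = At.n_rows, LB = B.n_rows;
  for (int i = 0; i < LA; ++i) {
    const double ax = At.at(i, 0), ay = At.at(i, 1), az = At.at(i, 2);
    for (int j = 0; j < LB; ++j) {
      const double dx = ax - B.at(j, 0), dy = ay - B.at(j, 1),
                   dz = az - B.at(j, 2);
      S.at(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
    }
  }
}

// Quick TM for candidate ranking: one Kabsch on all pairs, no subset search.
static double tm_quick(const arma::mat& A, const arma::mat& B,
                       const arma::uvec& ia, const arma::uvec& ib, double d0,
                       int Lt) {
  if (ia.n_elem < 3) return 0.0;
  Superpose sp = kabsch_core(A.rows(ia), B.rows(ib));
  arma::vec d2 = pair_d2(apply_sp(A, sp), B, ia, ib);
  return arma::accu(1.0 / (1.0 + d2 / (d0 * d0))) / Lt;
}

static void push_candidate(std::vector<arma::umat>& cands,
                           const arma::umat& p) {
  if (p.n_rows >= 3) cands.push_back(p);
}

struct AlignOut {
  arma::umat pairs;
  double tm = 0.0;
  double rmsd = NA_REAL;
};

// Full alignment search between CA traces A (LA x 3) and B (LB x 3).
// ssA/ssB are integer secondary-structure codes (0 coil, 1 helix, 2 strand).
// Lt is the normalisation (target) length; gap the DP gap penalty.
static AlignOut align_search_core(const arma::mat& A, const arma::mat& B,
                      const arma::ivec& ssA, const arma::ivec& ssB, double d0,
                      int Lt, double gap, int thread_step,
                      int frag_step, int frag_len, int n_refine,
                      int max_iter, double stop_above,
                      double give_up_below) {
  const int LA = A.n_rows, LB = B.n_rows;
  const double d02 = d0 * d0;
  std::vector<arma::umat> cands;

  // (a) gapless threading at all offsets (overlap >= 10), offset 0 always in
  const int minov = std::min(10, std::min(LA, LB));
  for (int off = -(LA - minov); off <= LB - minov; ++off) {
    if (off != 0 && (off % thread_step) != 0) continue;
    const int i0 = std::max(0, -off), i1 = std::min(LA - 1, LB - 1 - off);
    const int len = i1 - i0 + 1;
    if (len < minov) continue;
    arma::umat p(len, 2);
    for (int k = 0; k < len; ++k) {
      p(k, 0) = i0 + k;
      p(k, 1) = i0 + k + off;
    }
    push_candidate(cands, p);
  }

  // (b) DP on secondary-structure string match scores
  {
    arma::mat S(LA, LB);
    for (int i = 0; i < LA; ++i)
      for (int j = 0; j < LB; ++j)
        S(i, j) = (ssA[i] == ssB[j]) ? 1.0 : -1.0;
    push_candidate(cands, nw_core(S, -1.0));
  }

  // (c) best short-fragment superposition, extended by distance DP
  if (LA >= frag_len && LB >= frag_len) {
    double best_r = std::numeric_limits<double>::infinity();
    int bi = 0, bj = 0;
    for (int i = 0; i + frag_len <= LA; i += frag_step) {
      for (int j = 0; j + frag_len <= LB; j += frag_step) {
        Superpose sp =
            kabsch_core(A.rows(i, i + frag_len - 1), B.rows(j, j + frag_len - 1));
        if (sp.rmsd < best_r) { best_r = sp.rmsd; bi = i; bj = j; }
      }
    }
    Superpose sp =
        kabsch_core(A.rows(bi, bi + frag_len - 1), B.rows(bj, bj + frag_len - 1));
    arma::mat At = apply_sp(A, sp);
    arma::mat S(LA, LB);
    fill_score(At, B, d02, S);
    push_candidate(cands, nw_core(S, gap));
  }

  if (cands.empty()) return AlignOut();

  // rank candidates cheaply, keep the best few for refinement
  arma::vec quick(cands.size());
  for (size_t c = 0; c < cands.size(); ++c)
    quick[c] = tm_quick(A, B, cands[c].col(0), cands[c].col(1), d0, Lt);
  arma::uvec ord = arma::sort_index(quick, "descend");
  const size_t keep = std::min<size_t>(n_refine, cands.size());

  arma::umat best_pairs;
  double best_tm = -1.0;
  bool gave_up = false;
  for (size_t c = 0; c < keep; ++c) {
    arma::umat cur = cands[ord[c]];
    double prev_tm = -1.0;
    for (int it = 0; it < max_iter; ++it) {
      TMResult r =
          tm_search_core(A, B, cur.col(0), cur.col(1), d0, Lt, false);
      if (!r.ok) break;
      if (r.tm > best_tm) { best_tm = r.tm; best_pairs = cur; }
      if (r.tm - prev_tm < 1e-6 && it > 0) break;
      prev_tm = r.tm;
      arma::mat At = apply_sp(A, r.sp);
      arma::mat S(LA, LB);
      fill_score(At, B, d02, S);
      cur = nw_core(S, gap);
      if (cur.n_rows < 3) break;
    }
    // bounded-effort modes used for neighbour-graph construction: once the
    // decision threshold is crossed the (lower-bound) score settles it, and
    // a first refined candidate far below it will not be rescued by the
    // remaining seeds
    if (best_tm > stop_above) break;
    if (c == 0 && best_tm < give_up_below) { gave_up = true; break; }
  }

  // final thorough scoring of the winning alignment (skipped for pairs
  // abandoned far below the decision threshold)
  TMResult fin = tm_search_core(A, B, best_pairs.col(0), best_pairs.col(1),
                                d0, Lt, !gave_up);
  AlignOut out;
  out.pairs = best_pairs;
  out.tm = fin.tm;
  out.rmsd = fin.rmsd;
  return out;
}

// [[Rcpp::export]]
List align_search_cpp(const arma::mat& A, const arma::mat& B,
                      const arma::ivec& ssA, const arma::ivec& ssB, double d0,
                      int Lt, double gap = -0.6, int thread_step = 3,
                      int frag_step = 3, int frag_len = 8, int n_refine = 3,
                      int max_iter = 8, double stop_above = 2.0,
                      double give_up_below = -1.0) {
  AlignOut r = align_search_core(A, B, ssA, ssB, d0, Lt, gap, thread_step,
                                 frag_step, frag_len, n_refine, max_iter,
                                 stop_above, give_up_below);
  IntegerMatrix pr(r.pairs.n_rows, 2);
  for (arma::uword k = 0; k < r.pairs.n_rows; ++k) {
    pr(k, 0) = r.pairs(k, 0) + 1;
    pr(k, 1) = r.pairs(k, 1) + 1;
  }
  return List::create(_["pairs"] = pr, _["tm"] = r.tm, _["rmsd"] = r.rmsd);
}

// d0 for a given target length (duplicated from the R helper).
static double d0_of(int Lt) {
  double v = Lt - 15.0;
  double c = (v < 0) ? -std::cbrt(-v) : std::cbrt(v);
  return std::max(1.24 * c - 1.8, 0.5);
}

// Thresholded all-vs-all TM neighbour matrix for a set of chains.  Entries
// are exact TM lower bounds adequate for neighbour decisions at
// `threshold`: equal-length pairs first try the cheap identity alignment,
// and the full search runs with bounded effort (early exit once the
// threshold is crossed, abandonment more than `margin` below it).
// [[Rcpp::export]]
NumericMatrix tm_graph_cpp(const List& cas, const List& scs,
                           double threshold, double margin,
                           double gap = -0.6) {
  const int n = cas.size();
  std::vector<arma::mat> X(n);
  std::vector<arma::ivec> S(n);
  for (int i = 0; i < n; ++i) {
    X[i] = as<arma::mat>(cas[i]);
    S[i] = as<arma::ivec>(scs[i]);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) out(i, i) = 1.0;
  for (int i = 0; i + 1 < n; ++i) {
    const int Li = X[i].n_rows;
    for (int j = i + 1; j < n; ++j) {
      const int Lj = X[j].n_rows;
      const int Lt = std::min(Li, Lj);
      const double d0 = d0_of(Lt);
      double val = -1.0;
      if (Li == Lj) {
        arma::uvec idx = arma::regspace<arma::uvec>(0, Li - 1);
        TMResult lb = tm_search_core(X[i], X[j], idx, idx, d0, Lt, false);
        if (lb.ok && lb.tm > threshold) val = lb.tm;
      }
      if (val < 0) {
        AlignOut r = align_search_core(X[i], X[j], S[i], S[j], d0, Lt, gap,
                                       5, 5, 8, 3, 5, threshold,
                                       threshold - margin);
        val = r.tm;
      }
      out(i, j) = out(j, i) = val;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
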