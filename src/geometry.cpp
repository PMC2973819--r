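// Backbone construction and fast geometric checks.
//
// Chains are grown in internal coordinates (NeRF): each atom is placed from
// the three preceding reference atoms given a bond length, bond angle and
// torsion.  Standard peptide geometry: N-CA 1.458, CA-C 1.525, C-N 1.329,
// C=O 1.231, CA-CB 1.521 A; angles CA-C-N 116.2, C-N-CA 121.7,
// N-CA-C 111.2, CA-C-O 120.5, C-CA-CB 110.1 deg; omega fixed trans (180).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Place atom D bonded to C, with bond angle theta at C (B-C-D) and torsion
// chi about the B-C axis (A-B-C-D).  Lengths in Angstrom, angles in degrees.
static arma::vec3 nerf(const arma::vec3& A, const arma::vec3& B,
                       const arma::vec3& C, double r, double theta,
                       double chi) {
  const double th = theta * DEG, ph = chi * DEG;
  arma::vec3 bc = arma::normalise(C - B);
  arma::vec3 n = arma::normalise(arma::cross(B - A, bc));
  arma::vec3 m = arma::cross(n, bc);
  arma::vec3 d;
  d[0] = -r * std::cos(th);
  d[1] = r * std::sin(th) * std::cos(ph);
  d[2] = -r * std::sin(th) * std::sin(ph);
  return C + bc * d[0] + m * d[1] + n * d[2];
}

// Core backbone builder shared by the exported functions.
static void build_bb_core(const NumericVector& phi, const NumericVector& psi,
                          double cb_chi, arma::mat& N, arma::mat& CA,
                          arma::mat& C, arma::mat& O, arma::mat& CB) {
  const int L = phi.size();
  N.set_size(L, 3); CA.set_size(L, 3); C.set_size(L, 3);
  O.set_size(L, 3); CB.set_size(L, 3);
  arma::vec3 n0 = {0.0, 0.0, 0.0};
  arma::vec3 ca0 = {1.458, 0.0, 0.0};
  arma::vec3 c0 = ca0 + 1.525 * arma::vec3({-std::cos(111.2 * DEG),
                                            std::sin(111.2 * DEG), 0.0});
  N.row(0) = n0.t(); CA.row(0) = ca0.t(); C.row(0) = c0.t();
  for (int i = 1; i < L; ++i) {
    arma::vec3 pn = N.row(i - 1).t(), pca = CA.row(i - 1).t(),
               pc = C.row(i - 1).t();
    arma::vec3 ni = nerf(pn, pca, pc, 1.329, 116.2, psi[i - 1]);
    arma::vec3 cai = nerf(pca, pc, ni, 1.458, 121.7, 180.0);
    arma::vec3 ci = nerf(pc, ni, cai, 1.525, 111.2, phi[i]);
    N.row(i) = ni.t(); CA.row(i) = cai.t(); C.row(i) = ci.t();
  }
  for (int i = 0; i < L; ++i) {
    arma::vec3 ni = N.row(i).t(), cai = CA.row(i).t(), ci = C.row(i).t();
    O.row(i) = nerf(ni, cai, ci, 1.231, 120.5, psi[i] + 180.0).t();
    CB.row(i) = nerf(ci, ni, cai, 1.521, 110.1, cb_chi).t();
  }
}

// Build an L-residue backbone from per-residue (phi, psi) in degrees.
// phi[0] is ignored (undefined); psi[L-1] is still used to orient the
// terminal carbonyl.  Returns L x 3 matrices for N, CA, C, O, CB.
// CB chirality: torsion N-C-CA-CB = cb_chi (default +122.5 deg, L-amino).
// [[Rcpp::export]]
List build_backbone_cpp(NumericVector phi, NumericVector psi,
                        double cb_chi = 122.5) {
  const int L = phi.size();
  if (psi.size() != L) stop("phi and psi must have equal length");
  if (L < 1) stop("need at least one residue");
  arma::mat N, CA, C, O, CB;
  build_bb_core(phi, psi, cb_chi, N, CA, C, O, CB);
  return List::create(_["N"] = N, _["CA"] = CA, _["C"] = C, _["O"] = O,
                      _["CB"] = CB);
}

// Build the heavy-atom chain from dihedrals and report its radius of
// gyration and clash statistics in one call (hot path of the compact-chain
// sampler).
// [[Rcpp::export]]
List chain_metrics_cpp(NumericVector phi, NumericVector psi,
                       double clash_cut = 2.5, int min_res_sep = 2) {
  const int L = phi.size();
  if (psi.size() != L) stop("phi and psi must have equal length");
  arma::mat N, CA, C, O, CB;
  build_bb_core(phi, psi, 122.5, N, CA, C, O, CB);
  const int n = 5 * L;
  arma::mat X(n, 3);
  X.rows(0, L - 1) = N;
  X.rows(L, 2 * L - 1) = CA;
  X.rows(2 * L, 3 * L - 1) = C;
  X.rows(3 * L, 4 * L - 1) = O;
  X.rows(4 * L, 5 * L - 1) = CB;
  const double c2 = clash_cut * clash_cut;
  double mind2 = std::numeric_limits<double>::infinity();
  int n_clash = 0;
  for (int i = 0; i + 1 < n; ++i) {
    const int ri = i % L;
    const double xi = X.at(i, 0), yi = X.at(i, 1), zi = X.at(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (std::abs((j % L) - ri) < min_res_sep) continue;
      const double dx = xi - X.at(j, 0), dy = yi - X.at(j, 1),
                   dz = zi - X.at(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind2) mind2 = d2;
      if (d2 < c2) ++n_clash;
    }
  }
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  const double rg = std::sqrt(arma::accu(arma::square(Xc)) / n);
  return List::create(_["min_dist"] = std::sqrt(mind2),
                      _["n_clash"] = n_clash, _["rg"] = rg);
}

// Energy of the compact-chain sampler: squared excess of |Rg - target|
// beyond 40% of the tolerance band, plus 2 per clashing pair.
// Evaluation stops early (returning HUGE_VAL) once the clash term alone
// exceeds `e_cap`, since such proposals are rejected anyway.
static double sampler_energy(const NumericVector& phi,
                             const NumericVector& psi, double rg_target,
                             double band, double e_cap = HUGE_VAL) {
  const int L = phi.size();
  arma::mat N, CA, C, O, CB;
  build_bb_core(phi, psi, 122.5, N, CA, C, O, CB);
  const int n = 5 * L;
  arma::mat X(n, 3);
  X.rows(0, L - 1) = N;
  X.rows(L, 2 * L - 1) = CA;
  X.rows(2 * L, 3 * L - 1) = C;
  X.rows(3 * L, 4 * L - 1) = O;
  X.rows(4 * L, 5 * L - 1) = CB;
  int n_clash = 0;
  for (int i = 0; i + 1 < n; ++i) {
    const int ri = i % L;
    const double xi = X.at(i, 0), yi = X.at(i, 1), zi = X.at(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (std::abs((j % L) - ri) < 2) continue;
      const double dx = xi - X.at(j, 0), dy = yi - X.at(j, 1),
                   dz = zi - X.at(j, 2);
      if (dx * dx + dy * dy + dz * dz < 6.25) {
        if (2.0 * (++n_clash) > e_cap) return HUGE_VAL;
      }
    }
  }
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  const double rg = std::sqrt(arma::accu(arma::square(Xc)) / n);
  const double ex = std::max(0.0, std::abs(rg - rg_target) - 0.8 * band);
  return ex * ex + 2.0 * n_clash;
}

// Greedy pivot annealing of a dihedral chain towards a self-avoiding
// conformation with Rg inside the target band.  Movable positions are
// 1-based; after `stall_limit` consecutive non-improving moves all
// positions become movable.  Uses R's RNG (seed controlled by the caller).
// [[Rcpp::export]]
List anneal_chain_cpp(NumericVector phi0, NumericVector psi0,
                      IntegerVector movable, NumericMatrix basins,
                      double rg_target, double band, int max_moves,
                      int stall_limit = 250) {
  const int L = phi0.size();
  NumericVector phi = clone(phi0), psi = clone(psi0);
  std::vector<int> mov(movable.begin(), movable.end());
  double e = sampler_energy(phi, psi, rg_target, band);
  int stall = 0;
  bool widened = false;
  for (int mv = 0; mv < max_moves && e > 0; ++mv) {
    if (!widened && stall >= stall_limit) {
      mov.resize(L);
      for (int k = 0; k < L; ++k) mov[k] = k + 1;
      widened = true;
    }
    const int i = mov[(int)(unif_rand() * mov.size())] - 1;
    const int b = (int)(unif_rand() * basins.nrow());
    const double old_phi = phi[i], old_psi = psi[i];
    phi[i] = basins(b, 0) + norm_rand() * 15.0;
    psi[i] = basins(b, 1) + norm_rand() * 15.0;
    const double en = sampler_energy(phi, psi, rg_target, band, e);
    if (en <= e) {
      stall = (en < e) ? 0 : stall + 1;
      e = en;
    } else {
      phi[i] = old_phi;
      psi[i] = old_psi;
      ++stall;
    }
  }
  return List::create(_["phi"] = phi, _["psi"] = psi, _["energy"] = e,
                      _["converged"] = (e == 0.0));
}

// Minimum distance and number of clashing pairs (< clash_cut) over atom
// pairs at residue separation >= min_res_sep, plus the radius of gyration of
// the atom set.  Used by the self-avoiding chain samplers; O(n^2) is fine at
// the chain lengths handled here.
// [[Rcpp::export]]
List clash_rg_cpp(const arma::mat& X, const arma::ivec& resid,
                  int min_res_sep = 2, double clash_cut = 2.5) {
  const arma::uword n = X.n_rows;
  if (resid.n_elem != n) stop("resid length mismatch");
  const double c2 = clash_cut * clash_cut;
  double mind2 = std::numeric_limits<double>::infinity();
  int n_clash = 0;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      if (std::abs(resid[j] - resid[i]) < min_res_sep) continue;
      const double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
                   dz = X(i, 2) - X(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind2) mind2 = d2;
      if (d2 < c2) ++n_clash;
    }
  }
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  const double rg = std::sqrt(arma::accu(arma::square(Xc)) / n);
  return List::create(_["min_dist"] = std::sqrt(mind2),
                      _["n_clash"] = n_clash, _["rg"] = rg);
}

// Residue-level contact map: residues i, j (1-based, |j - i| >= min_sep) are
// in contact when any two of their heavy atoms lie closer than d_cut.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(const arma::mat& X, const arma::ivec& resid,
                                double d_cut, int min_sep) {
  const arma::uword n = X.n_rows;
  const double c2 = d_cut * d_cut;
  std::set<std::pair<int, int>> hits;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      const int ri = resid[i], rj = resid[j];
      const int lo = std::min(ri, rj), hi = std::max(ri, rj);
      if (hi - lo < min_sep) continue;
      if (hits.count({lo, hi})) continue;
      const double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
                   dz = X(i, 2) - X(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) hits.insert({lo, hi});
    }
  }
  IntegerMatrix out(hits.size(), 2);
  int k = 0;
  for (const auto& p : hits) {
    out(k, 0) = p.first; out(k, 1) = p.second; ++k;
  }
  return out;
}

// Least-squares RMSD between two equal-size point sets after optimal proper
// rotation (no reflection).  Shared with tmalign.cpp via a local copy.
static double kabsch_rmsd_only(const arma::mat& P, const arma::mat& Q) {
  arma::rowvec muP = arma::mean(P, 0), muQ = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - muP, Qc = Q.each_row() - muQ;
  arma::mat H = Pc.t() * Qc, U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = (arma::det(U) * arma::det(V) < 0) ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat diff = Pc * (U * D * V.t()) - Qc;
  return std::sqrt(arma::accu(arma::square(diff)) / P.n_rows);
}

// For every fragment in `query`, the minimum superposition RMSD over all
// fragments in `reference`.  Each list element is an m x 3 coordinate matrix
// (same m throughout).
// [[Rcpp::export]]
NumericVector frag_min_rmsd_cpp(const List& query, const List& reference) {
  const int nq = query.size(), nr = reference.size();
  std::vector<arma::mat> R(nr);
  for (int j = 0; j < nr; ++j) R[j] = as<arma::mat>(reference[j]);
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    arma::mat Qi = as<arma::mat>(query[i]);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nr; ++j) {
      const double r = kabsch_rmsd_only(Qi, R[j]);
      if (r < best) best = r;
    }
    out[i] = best;
  }
  return out;
}
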