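// Geometric-simulation core: uniform-grid neighbour search, ghost-template
// relaxation (iterative rigid refitting of cluster templates plus pairwise
// steric projection) and the biased mode-following loop.  Kept in C++ so a
// full 5000-step trajectory set runs in seconds.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <unordered_set>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long long cellkey(int cx, int cy, int cz) {
  return (static_cast<long long>(cx + 512) << 40) |
         (static_cast<long long>(cy + 512) << 20) |
         static_cast<long long>(cz + 512);
}

// all unordered pairs (i, j), i < j, with |xi - xj| <= cutoff (1-based)
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix X, double cutoff) {
  const int n = X.nrow();
  const double c = cutoff > 0 ? cutoff : 1.0;
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int>(std::floor(X(i, 0) / c));
    cy[i] = static_cast<int>(std::floor(X(i, 1) / c));
    cz[i] = static_cast<int>(std::floor(X(i, 2) / c));
    grid[cellkey(cx[i], cy[i], cz[i])].push_back(i);
  }
  const double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cellkey(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = X(i, 0) - X(j, 0), ddy = X(i, 1) - X(j, 1),
                   ddz = X(i, 2) - X(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
              ii.push_back(i + 1);
              jj.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

struct Ghost {
  arma::uvec idx;      // 0-based atom indices
  arma::mat templ_c;   // centered template (m x 3)
};

struct RelaxProblem {
  std::vector<Ghost> ghosts;
  std::vector<std::vector<int>> atom_ghosts;  // ghosts touching each atom
  std::unordered_set<long long> excluded;     // pair keys i*n+j (i < j)
  std::vector<int> cluster;                   // rigid-cluster label per atom
  arma::vec radii;
  double clash_margin;     // subtracted from vdW sum
  double template_tol;
  int max_iter;
  int n;
};

static inline long long pairkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return static_cast<long long>(i) * n + j;
}

// rotate centered template onto current positions, Kabsch
static arma::mat fit_template(const arma::mat& templ_c, const arma::mat& P) {
  arma::rowvec cp = arma::mean(P, 0);
  arma::mat Pc = P.each_row() - cp;
  arma::mat C = templ_c.t() * Pc;  // 3x3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, C)) return P;  // degenerate: leave as is
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  arma::mat R = V * D * U.t();
  arma::mat fitted = templ_c * R.t();
  fitted.each_row() += cp;
  return fitted;
}

struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> limit;
};

static NeighborList build_nlist(const arma::mat& X, const RelaxProblem& pr,
                                double skin) {
  NeighborList nl;
  const int n = pr.n;
  double maxr = pr.radii.max();
  double cutoff = 2.0 * maxr - pr.clash_margin + skin;
  NumericMatrix Xr(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Xr(i, k) = X(i, k);
  IntegerMatrix pairs = cpp_neighbor_pairs(Xr, cutoff);
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    if (pr.cluster[i] == pr.cluster[j]) continue;  // held by the template
    if (pr.excluded.count(pairkey(i, j, n))) continue;
    double lim = pr.radii(i) + pr.radii(j) - pr.clash_margin;
    nl.pi.push_back(i);
    nl.pj.push_back(j);
    nl.limit.push_back(lim);
  }
  return nl;
}

// one full relaxation; returns iterations used, final max template deviation
// and worst clash overlap; X modified in place
static void relax_inplace(arma::mat& X, const RelaxProblem& pr,
                          const NeighborList& nl, int& iters, double& maxdev,
                          double& worst, bool& converged) {
  converged = false;
  maxdev = 0.0;
  worst = 0.0;
  for (iters = 1; iters <= pr.max_iter; ++iters) {
    // ghost refit and averaged targets
    arma::mat target(pr.n, 3, arma::fill::zeros);
    arma::vec wt(pr.n, arma::fill::zeros);
    maxdev = 0.0;
    for (const Ghost& g : pr.ghosts) {
      arma::mat P = X.rows(g.idx);
      arma::mat F = fit_template(g.templ_c, P);
      for (arma::uword r = 0; r < g.idx.n_elem; ++r) {
        target.row(g.idx(r)) += F.row(r);
        wt(g.idx(r)) += 1.0;
        double dev = arma::norm(F.row(r) - P.row(r), 2);
        if (dev > maxdev) maxdev = dev;
      }
    }
    for (int i = 0; i < pr.n; ++i)
      if (wt(i) > 0) X.row(i) = target.row(i) / wt(i);
    // steric projection
    worst = 0.0;
    for (size_t k = 0; k < nl.pi.size(); ++k) {
      int i = nl.pi[k], j = nl.pj[k];
      arma::rowvec dv = X.row(i) - X.row(j);
      double d = arma::norm(dv, 2);
      double lim = nl.limit[k];
      if (d < lim && d > 1e-9) {
        double push = 0.5 * (lim - d);
        arma::rowvec u = dv / d;
        X.row(i) += push * u;
        X.row(j) -= push * u;
        if (lim - d > worst) worst = lim - d;
      }
    }
    if (maxdev < pr.template_tol && worst < 0.5 * pr.template_tol) {
      converged = true;
      return;
    }
  }
  iters = pr.max_iter;
}

static RelaxProblem make_problem(int n, List ghost_idx, List ghost_templ,
                                 IntegerMatrix excl_pairs, IntegerVector cluster,
                                 NumericVector radii, double clash_margin,
                                 double template_tol, int max_iter) {
  RelaxProblem pr;
  pr.n = n;
  pr.cluster.assign(cluster.begin(), cluster.end());
  pr.clash_margin = clash_margin;
  pr.template_tol = template_tol;
  pr.max_iter = max_iter;
  pr.radii = arma::vec(radii.begin(), n);
  pr.atom_ghosts.resize(n);
  for (int g = 0; g < ghost_idx.size(); ++g) {
    IntegerVector iv = ghost_idx[g];
    NumericMatrix tm = ghost_templ[g];
    Ghost gh;
    gh.idx.set_size(iv.size());
    arma::mat T(iv.size(), 3);
    for (int r = 0; r < iv.size(); ++r) {
      gh.idx(r) = iv[r] - 1;
      pr.atom_ghosts[iv[r] - 1].push_back(g);
      for (int k = 0; k < 3; ++k) T(r, k) = tm(r, k);
    }
    arma::rowvec ct = arma::mean(T, 0);
    gh.templ_c = T.each_row() - ct;
    pr.ghosts.push_back(gh);
  }
  for (int k = 0; k < excl_pairs.nrow(); ++k)
    pr.excluded.insert(pairkey(excl_pairs(k, 0) - 1, excl_pairs(k, 1) - 1, n));
  return pr;
}

// [[Rcpp::export]]
List cpp_relax(NumericMatrix X0, List ghost_idx, List ghost_templ,
               IntegerMatrix excl_pairs, IntegerVector cluster,
               NumericVector radii, double clash_margin, double template_tol,
               int max_iter) {
  const int n = X0.nrow();
  RelaxProblem pr = make_problem(n, ghost_idx, ghost_templ, excl_pairs,
                                 cluster, radii, clash_margin, template_tol,
                                 max_iter);
  arma::mat X(X0.begin(), n, 3);
  NeighborList nl = build_nlist(X, pr, 1.4);
  int iters;
  double maxdev, worst;
  bool conv;
  relax_inplace(X, pr, nl, iters, maxdev, worst, conv);
  return List::create(_["coords"] = wrap(X), _["iterations"] = iters,
                      _["max_template_dev"] = maxdev,
                      _["worst_clash"] = worst, _["converged"] = conv);
}

// Biased mode following: n_steps iterations of (displace along V, relax);
// conformer recorded at step 0 and every save_every steps.  Stall when the
// C-alpha RMSD from the start gains less than stall_gain per 100 steps.
// [[Rcpp::export]]
List cpp_mode_follow(NumericMatrix X0, NumericMatrix V, double step_size,
                     int n_steps, int save_every, IntegerVector ca_idx,
                     List ghost_idx, List ghost_templ, IntegerMatrix excl_pairs,
                     IntegerVector cluster, NumericVector radii,
                     double clash_margin, double template_tol, int max_iter,
                     double stall_gain) {
  const int n = X0.nrow();
  RelaxProblem pr = make_problem(n, ghost_idx, ghost_templ, excl_pairs,
                                 cluster, radii, clash_margin, template_tol,
                                 max_iter);
  arma::mat X(X0.begin(), n, 3);
  arma::mat Xstart = X;
  arma::mat Vm(V.begin(), n, 3);
  arma::uvec ca(ca_idx.size());
  for (int k = 0; k < ca_idx.size(); ++k) ca(k) = ca_idx[k] - 1;

  std::vector<NumericMatrix> saved;
  std::vector<int> steps;
  saved.push_back(wrap(X));
  steps.push_back(0);

  NeighborList nl = build_nlist(X, pr, 1.4);
  bool stalled = false;
  std::string status = "completed";
  double last_rmsd = 0.0;
  int done = 0;
  for (int s = 1; s <= n_steps; ++s) {
    X += step_size * Vm;
    if (s % 20 == 0) nl = build_nlist(X, pr, 1.4);
    int iters;
    double maxdev, worst;
    bool conv;
    relax_inplace(X, pr, nl, iters, maxdev, worst, conv);
    if (!conv && maxdev > 5.0 * pr.template_tol) {
      status = "relax_failure";
      break;
    }
    done = s;
    if (s % save_every == 0) {
      saved.push_back(wrap(X));
      steps.push_back(s);
    }
    if (s % 100 == 0) {
      arma::mat D = X.rows(ca) - Xstart.rows(ca);
      double rmsd = std::sqrt(arma::accu(D % D) / ca.n_elem);
      if (rmsd - last_rmsd < stall_gain) stalled = true;
      last_rmsd = rmsd;
    }
  }
  List sv(saved.size());
  for (size_t k = 0; k < saved.size(); ++k) sv[k] = saved[k];
  return List::create(_["coords"] = sv, _["steps"] = wrap(steps),
                      _["stalled"] = stalled, _["status"] = status,
                      _["steps_done"] = done);
}
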