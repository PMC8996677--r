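// Sparse inverse covariance estimation (graphical lasso) and the hot loops
// built on it: density-targeted penalty search with warm starts, binary
// graph metrics, and group-label permutation of network statistics.
//
// The solver is the block coordinate descent of the penalized Gaussian
// log-likelihood  max_Theta  log det Theta - tr(S Theta) - lambda ||Theta||_1,off
// (one lasso regression per column of the working covariance W).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static const double ZERO_TOL = 1e-8;  // numerical floor for edge presence

static inline double soft_threshold(double x, double l) {
  if (x > l) return x - l;
  if (x < -l) return x + l;
  return 0.0;
}

// Core BCD solver. W and B are used as warm starts when warm = true and
// are overwritten with the solution. B holds the per-column lasso
// coefficients (B(j,j) == 0).
static void glasso_core(const mat& S, double lambda, double tol, int maxit,
                        mat& W, mat& B, bool warm, int& iter, bool& converged) {
  // Only off-diagonal entries are penalized, so the working covariance
  // keeps the empirical diagonal (W_ii = S_ii at stationarity).
  const uword p = S.n_rows;
  if (!warm) {
    W = S;
    B.zeros(p, p);
  } else {
    W.diag() = S.diag();
  }
  // convergence scale: average |off-diagonal S|
  double s_off = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) s_off += std::fabs(S(i, j));
  double denom = (p > 1) ? s_off / (p * (p - 1) / 2.0) : 1.0;
  if (denom < 1e-12) denom = 1e-12;
  const double thr = tol * denom;
  const double inner_thr = 0.1 * thr;

  converged = false;
  iter = 0;
  vec beta(p), u(p);
  for (int it = 0; it < maxit; ++it) {
    double max_dw = 0.0;
    for (uword j = 0; j < p; ++j) {
      beta = B.col(j);
      beta(j) = 0.0;
      // inner coordinate descent on the lasso subproblem: full passes to
      // fix the active set, cheap active-set-only passes in between
      for (int full = 0; full < 10; ++full) {
        double max_db = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j) - arma::dot(W.col(k), beta) + W(k, k) * beta(k);
          double bnew = soft_threshold(grad, lambda) / W(k, k);
          double db = std::fabs(bnew - beta(k));
          if (db > max_db) max_db = db;
          beta(k) = bnew;
        }
        if (max_db < inner_thr) break;
        for (int in_it = 0; in_it < 100; ++in_it) {
          double mdb = 0.0;
          for (uword k = 0; k < p; ++k) {
            if (k == j || beta(k) == 0.0) continue;
            double grad = S(k, j) - arma::dot(W.col(k), beta) + W(k, k) * beta(k);
            double bnew = soft_threshold(grad, lambda) / W(k, k);
            double db = std::fabs(bnew - beta(k));
            if (db > mdb) mdb = db;
            beta(k) = bnew;
          }
          if (mdb < inner_thr) break;
        }
      }
      B.col(j) = beta;
      B(j, j) = 0.0;
      u = W * beta;  // u(k) = (W11 beta)(k) for k != j since beta(j) = 0
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double dw = std::fabs(u(k) - W(k, j));
        if (dw > max_dw) max_dw = dw;
        W(k, j) = u(k);
        W(j, k) = u(k);
      }
    }
    iter = it + 1;
    if (max_dw < thr) { converged = true; break; }
  }
}

// Recover Theta from (W, B); symmetrize and floor tiny entries to exact 0.
static mat theta_from_wb(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat theta(p, p, arma::fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j) - arma::dot(W.col(j), B.col(j));
    double tjj = 1.0 / denom;
    theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      theta(k, j) = -B(k, j) * tjj;
    }
  }
  // symmetric support by the max rule, then average
  mat out(p, p, arma::fill::zeros);
  out.diag() = theta.diag();
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) {
      double a = theta(i, j), b = theta(j, i);
      double v = (std::max(std::fabs(a), std::fabs(b)) > ZERO_TOL) ? 0.5 * (a + b) : 0.0;
      out(i, j) = v;
      out(j, i) = v;
    }
  return out;
}

static double kkt_residual(const mat& S, const mat& W, const mat& theta,
                           double lambda) {
  const uword p = S.n_rows;
  double r = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j) {
      if (i == j) continue;
      double d = W(i, j) - S(i, j);
      double ri = (theta(i, j) != 0.0)
        ? std::fabs(d - lambda * ((theta(i, j) > 0) - (theta(i, j) < 0)))
        : std::max(0.0, std::fabs(d) - lambda);
      if (ri > r) r = ri;
    }
  return r;
}

static double edge_density(const mat& theta) {
  const uword p = theta.n_rows;
  if (p < 2) return 0.0;
  uword m = 0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (std::fabs(theta(i, j)) > ZERO_TOL) ++m;
  return (double)m / (p * (p - 1) / 2.0);
}

static double penalized_objective(const mat& S, const mat& theta, double lambda) {
  double ld, sign;
  if (!arma::log_det(ld, sign, theta) || sign <= 0) return R_NegInf;
  double pen = 0.0;
  const uword p = theta.n_rows;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) pen += std::fabs(theta(i, j));
  return ld - arma::trace(S * theta) - lambda * pen;
}

// [[Rcpp::export]]
List cpp_glasso(const arma::mat& S, double lambda, double tol, int maxit) {
  const uword p = S.n_rows;
  if (lambda <= 1e-12) {
    mat theta;
    bool ok = arma::inv_sympd(theta, S);
    if (!ok) stop("lambda = 0 requires an invertible (positive definite) covariance");
    theta = 0.5 * (theta + theta.t());
    return List::create(_["theta"] = theta, _["w"] = S, _["n_iter"] = 0,
                        _["converged"] = true, _["kkt"] = 0.0,
                        _["objective"] = penalized_objective(S, theta, 0.0),
                        _["density"] = edge_density(theta));
  }
  mat W, B;
  int iter;
  bool conv;
  glasso_core(S, lambda, tol, maxit, W, B, false, iter, conv);
  mat theta = theta_from_wb(W, B);
  return List::create(_["theta"] = theta, _["w"] = W, _["n_iter"] = iter,
                      _["converged"] = conv,
                      _["kkt"] = kkt_residual(S, W, theta, lambda),
                      _["objective"] = penalized_objective(S, theta, lambda),
                      _["density"] = edge_density(theta));
}

// Bisection on lambda for a target edge density, warm-starting each solve
// from the previous one. Density is non-increasing in lambda.
// [[Rcpp::export]]
List cpp_lambda_for_density(const arma::mat& S, double target, double tol_density,
                            double tol, int maxit, double lambda_min_frac,
                            int max_bisect) {
  const uword p = S.n_rows;
  double lmax = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      lmax = std::max(lmax, std::fabs(S(i, j)));
  if (lmax < 1e-12) lmax = 1e-12;

  mat W, B;
  int iter;
  bool conv, warm = false;
  mat best_theta;
  double best_lambda = NA_REAL, best_density = -1.0, best_gap = R_PosInf;
  bool best_conv = false;
  bool plateau = false;

  auto solve_at = [&](double lam) -> double {
    glasso_core(S, lam, tol, maxit, W, B, warm, iter, conv);
    warm = true;
    mat theta = theta_from_wb(W, B);
    double d = edge_density(theta);
    double gap = std::fabs(d - target);
    if (gap < best_gap) {
      best_gap = gap;
      best_theta = theta;
      best_lambda = lam;
      best_density = d;
      best_conv = conv;
    }
    return d;
  };

  if (target <= 0.0) {
    double lam = lmax * (1.0 + 1e-6);
    solve_at(lam);
    return List::create(_["lambda"] = best_lambda, _["theta"] = best_theta,
                        _["density"] = best_density, _["converged"] = best_conv,
                        _["plateau"] = false);
  }

  // plain midpoint bisection; the cheap large-lambda half of the bracket
  // is explored first, so a near-zero-penalty solve (slow on
  // rank-deficient S) happens only when the target genuinely needs it
  double lo = lmax * lambda_min_frac;
  double hi = lmax * (1.0 + 1e-6);
  for (int b = 0; b < max_bisect && best_gap > tol_density; ++b) {
    double mid = 0.5 * (lo + hi);
    double d = solve_at(mid);
    if (d > target) lo = mid; else hi = mid;
    if ((hi - lo) < 1e-10 * lmax) break;
  }
  if (best_gap > tol_density) plateau = true;
  return List::create(_["lambda"] = best_lambda, _["theta"] = best_theta,
                      _["density"] = best_density, _["converged"] = best_conv,
                      _["plateau"] = plateau);
}

// ---- binary graph metrics (adjacency as 0/1 matrix, zero diagonal) ----

static void bfs_dists(const std::vector<std::vector<int>>& nb, int src,
                      std::vector<int>& dist) {
  const int n = (int)nb.size();
  std::fill(dist.begin(), dist.end(), -1);
  std::vector<int> queue;
  queue.reserve(n);
  queue.push_back(src);
  dist[src] = 0;
  size_t head = 0;
  while (head < queue.size()) {
    int v = queue[head++];
    for (int w : nb[v])
      if (dist[w] < 0) { dist[w] = dist[v] + 1; queue.push_back(w); }
  }
}

static std::vector<std::vector<int>> adj_list(const mat& A) {
  const int n = (int)A.n_rows;
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0.0) nb[i].push_back(j);
  return nb;
}

// metric_id: 1 = global efficiency, 2 = mean clustering coefficient,
//            3 = characteristic path length (reachable pairs only)
static double bin_metric(const mat& A, int metric_id) {
  const int n = (int)A.n_rows;
  if (metric_id == 2) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int j = 0; j < n; ++j) if (j != i && A(i, j) != 0.0) ++k;
      if (k < 2) continue;
      int tri = 0;
      for (int a = 0; a < n; ++a) {
        if (a == i || A(i, a) == 0.0) continue;
        for (int b = a + 1; b < n; ++b)
          if (b != i && A(i, b) != 0.0 && A(a, b) != 0.0) ++tri;
      }
      tot += 2.0 * tri / ((double)k * (k - 1));
    }
    return tot / n;
  }
  auto nb = adj_list(A);
  std::vector<int> dist(n);
  double acc = 0.0;
  long n_pairs = 0;
  for (int i = 0; i < n; ++i) {
    bfs_dists(nb, i, dist);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (metric_id == 1) {
        acc += (dist[j] > 0) ? 1.0 / dist[j] : 0.0;
        ++n_pairs;
      } else {
        if (dist[j] > 0) { acc += dist[j]; ++n_pairs; }
      }
    }
  }
  if (n_pairs == 0) return (metric_id == 1) ? 0.0 : R_PosInf;
  return acc / n_pairs;
}

// [[Rcpp::export]]
double cpp_bin_metric(const arma::mat& A, int metric_id) {
  return bin_metric(A, metric_id);
}

// [[Rcpp::export]]
arma::mat cpp_shortest_paths(const arma::mat& A) {
  const int n = (int)A.n_rows;
  auto nb = adj_list(A);
  std::vector<int> dist(n);
  mat D(n, n);
  for (int i = 0; i < n; ++i) {
    bfs_dists(nb, i, dist);
    for (int j = 0; j < n; ++j)
      D(i, j) = (dist[j] < 0) ? R_PosInf : (double)dist[j];
  }
  return D;
}

// ---- permutation loop for density-matched network statistics ----

static mat correlation_of(const mat& X) {
  mat C = arma::cor(X);
  C.diag().ones();
  return C;
}

static double net_stat(const mat& Xg, double density, int metric_id,
                       double tol_density, double tol, int maxit,
                       double lambda_min_frac, int max_bisect) {
  mat S = correlation_of(Xg);
  const uword p = S.n_rows;
  double lmax = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      lmax = std::max(lmax, std::fabs(S(i, j)));
  if (lmax < 1e-12) lmax = 1e-12;
  mat W, B;
  int iter;
  bool conv, warm = false;
  double lo = lmax * lambda_min_frac, hi = lmax * (1.0 + 1e-6);
  mat best_theta;
  double best_gap = R_PosInf;
  for (int b = 0; b < max_bisect; ++b) {
    double lam = 0.5 * (lo + hi);
    glasso_core(S, lam, tol, maxit, W, B, warm, iter, conv);
    warm = true;
    mat theta = theta_from_wb(W, B);
    double d = edge_density(theta);
    double gap = std::fabs(d - density);
    if (gap < best_gap) { best_gap = gap; best_theta = theta; }
    if (gap <= tol_density) break;
    if (d > density) lo = lam; else hi = lam;
  }
  const uword pp = best_theta.n_rows;
  mat A(pp, pp, arma::fill::zeros);
  for (uword i = 0; i < pp; ++i)
    for (uword j = 0; j < pp; ++j)
      if (i != j && std::fabs(best_theta(i, j)) > ZERO_TOL) A(i, j) = 1.0;
  return bin_metric(A, metric_id);
}

// Observed group difference (A - B) of a density-matched binary network
// statistic, plus its distribution under n_perm random relabelings.
// Uses R's RNG so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
List cpp_perm_netstat(const arma::mat& Xa, const arma::mat& Xb, double density,
                      int metric_id, int n_perm, double tol_density,
                      double tol, int maxit, double lambda_min_frac,
                      int max_bisect) {
  const uword na = Xa.n_rows, nb_ = Xb.n_rows, p = Xa.n_cols;
  mat X(na + nb_, p);
  X.rows(0, na - 1) = Xa;
  X.rows(na, na + nb_ - 1) = Xb;
  double obs = net_stat(Xa, density, metric_id, tol_density, tol, maxit,
                        lambda_min_frac, max_bisect)
             - net_stat(Xb, density, metric_id, tol_density, tol, maxit,
                        lambda_min_frac, max_bisect);
  NumericVector perms(n_perm);
  const uword n = na + nb_;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG
    for (uword i = n - 1; i > 0; --i) {
      uword j = (uword)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    arma::uvec ia(na), ib(nb_);
    for (uword i = 0; i < na; ++i) ia(i) = idx[i];
    for (uword i = 0; i < nb_; ++i) ib(i) = idx[na + i];
    perms[b] = net_stat(X.rows(ia), density, metric_id, tol_density, tol,
                        maxit, lambda_min_frac, max_bisect)
             - net_stat(X.rows(ib), density, metric_id, tol_density, tol,
                        maxit, lambda_min_frac, max_bisect);
  }
  return List::create(_["observed"] = obs, _["perms"] = perms);
}
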