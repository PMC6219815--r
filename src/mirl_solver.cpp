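// Convex inner solver and discount-factor grid search for sparse modular
// IRL.  The likelihood is parameterized through per-module feature sums
// phi_n(t, a) = sum_m gamma_n^d(t, a, m) over live objects; for fixed
// gammas the L1-penalized log-likelihood is concave in the rewards and is
// maximized by proximal gradient (FISTA with backtracking and monotone
// restarts), with exact zeros from soft thresholding.  The grid search
// enumerates gamma combinations, caching phi per (module, gamma) and warm
// starting each node at the previous node's rewards.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// phi vector (length T*K) for one module at one gamma. dist: (T*K) x M
// column-major; negative distance marks a dead/absent object.
std::vector<double> make_phi(const NumericMatrix& dist, double gamma,
                             int TK) {
  std::vector<double> phi(TK, 0.0);
  const int M = dist.ncol();
  for (int m = 0; m < M; ++m) {
    const double* col = &dist(0, m);
    for (int i = 0; i < TK; ++i) {
      double d = col[i];
      if (d >= 0.0) phi[i] += std::pow(gamma, d);
    }
  }
  return phi;
}

struct Problem {
  std::vector<const double*> phi;  // N pointers, each length T*K
  const int* obs;                  // T row indices into flattened (t,a)
  int T, K, N;
  double eta, lambda;
};

// Smooth part f(r) = sum_t [eta*q(t, a_t) - lse_a eta*q(t, a)], its
// gradient, and optionally its (negative semidefinite) Hessian
// -eta^2 * sum_t Cov_p(phi).  grad/hess may be null.
double smooth_eval(const Problem& pb, const double* r, double* grad,
                   double* hess = nullptr) {
  const int K = pb.K, N = pb.N;
  double f = 0.0;
  if (grad) for (int j = 0; j < N; ++j) grad[j] = 0.0;
  if (hess) for (int j = 0; j < N * N; ++j) hess[j] = 0.0;
  std::vector<double> z(K), p(K), ex(N);
  for (int t = 0; t < pb.T; ++t) {
    const int base = t * K;
    double mx = -1e300;
    for (int a = 0; a < K; ++a) {
      double q = 0.0;
      for (int j = 0; j < N; ++j) q += r[j] * pb.phi[j][base + a];
      z[a] = pb.eta * q;
      if (z[a] > mx) mx = z[a];
    }
    double sum = 0.0;
    for (int a = 0; a < K; ++a) { p[a] = std::exp(z[a] - mx); sum += p[a]; }
    double lse = mx + std::log(sum);
    f += z[pb.obs[t] - base] - lse;
    if (grad) {
      for (int a = 0; a < K; ++a) p[a] /= sum;
      for (int j = 0; j < N; ++j) {
        const double* ph = pb.phi[j] + base;
        double e = 0.0;
        for (int a = 0; a < K; ++a) e += p[a] * ph[a];
        ex[j] = e;
        grad[j] += pb.eta * (ph[pb.obs[t] - base] - e);
      }
      if (hess) {
        for (int j = 0; j < N; ++j) {
          const double* phj = pb.phi[j] + base;
          for (int k = j; k < N; ++k) {
            const double* phk = pb.phi[k] + base;
            double m2 = 0.0;
            for (int a = 0; a < K; ++a) m2 += p[a] * phj[a] * phk[a];
            double h = -pb.eta * pb.eta * (m2 - ex[j] * ex[k]);
            hess[j * N + k] += h;
            if (k != j) hess[k * N + j] += h;
          }
        }
      }
    }
  }
  return f;
}

// Solve (-H) x = g for the Newton ascent direction; -H is positive
// semidefinite, regularized on the diagonal.  Gaussian elimination with
// partial pivoting (N is tiny).
static bool solve_spd(int N, const double* H, const double* g, double* x) {
  std::vector<double> A(N * N);
  std::vector<double> b(g, g + N);
  double dmax = 1e-12;
  for (int j = 0; j < N; ++j) dmax = std::max(dmax, -H[j * N + j]);
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < N; ++k)
      A[j * N + k] = -H[j * N + k] + (j == k ? 1e-9 * dmax : 0.0);
  for (int c = 0; c < N; ++c) {
    int piv = c;
    for (int rI = c + 1; rI < N; ++rI)
      if (std::fabs(A[rI * N + c]) > std::fabs(A[piv * N + c])) piv = rI;
    if (std::fabs(A[piv * N + c]) < 1e-300) return false;
    if (piv != c) {
      for (int k = 0; k < N; ++k) std::swap(A[c * N + k], A[piv * N + k]);
      std::swap(b[c], b[piv]);
    }
    for (int rI = c + 1; rI < N; ++rI) {
      double m = A[rI * N + c] / A[c * N + c];
      for (int k = c; k < N; ++k) A[rI * N + k] -= m * A[c * N + k];
      b[rI] -= m * b[c];
    }
  }
  for (int c = N - 1; c >= 0; --c) {
    double s = b[c];
    for (int k = c + 1; k < N; ++k) s -= A[c * N + k] * x[k];
    x[c] = s / A[c * N + c];
  }
  return true;
}

// Damped Newton maximization of the smooth objective (lambda = 0 path).
double newton(const Problem& pb, std::vector<double>& r, double tol,
              int maxit) {
  const int N = pb.N;
  std::vector<double> grad(N), hess(N * N), dir(N), rn(N);
  double obj = smooth_eval(pb, r.data(), nullptr);
  for (int it = 0; it < maxit; ++it) {
    double f = smooth_eval(pb, r.data(), grad.data(), hess.data());
    double gn = 0.0;
    for (int j = 0; j < N; ++j) gn += grad[j] * grad[j];
    if (std::sqrt(gn) < 1e-10 * (1.0 + std::fabs(f))) { obj = f; break; }
    if (!solve_spd(N, hess.data(), grad.data(), dir.data())) break;
    // cap the step to stay in a sane region even under near-separation
    double dn = 0.0;
    for (int j = 0; j < N; ++j) dn += dir[j] * dir[j];
    dn = std::sqrt(dn);
    double cap = 100.0;
    double scale = dn > cap ? cap / dn : 1.0;
    double step = scale, fn = f;
    for (int h = 0; h < 30; ++h) {
      for (int j = 0; j < N; ++j) rn[j] = r[j] + step * dir[j];
      fn = smooth_eval(pb, rn.data(), nullptr);
      if (fn >= f) break;
      step *= 0.5;
    }
    if (fn < f) { obj = f; break; }
    r = rn;
    bool done = std::fabs(fn - f) < tol * (1.0 + std::fabs(f));
    obj = fn;
    if (done) break;
  }
  return obj;
}

inline double soft(double x, double thr) {
  if (x > thr) return x - thr;
  if (x < -thr) return x + thr;
  return 0.0;
}

// FISTA maximization of f(r) - lambda*||r||_1 over the free coordinates.
// r is modified in place; returns the penalized objective.
double fista(const Problem& pb, std::vector<double>& r,
             const std::vector<bool>& free_r, double tol, int maxit,
             double& Lstep) {
  const int N = pb.N;
  std::vector<double> y(r), rn(N), grad(N), r_prev(r);
  double theta = 1.0;
  double obj = smooth_eval(pb, r.data(), nullptr);
  for (int j = 0; j < N; ++j) obj -= pb.lambda * std::fabs(r[j]);
  if (maxit <= 0) return obj;
  double L = Lstep > 0 ? Lstep : 1.0;
  for (int it = 0; it < maxit; ++it) {
    double fy = smooth_eval(pb, y.data(), grad.data());
    double fn = 0.0;
    for (;;) {
      for (int j = 0; j < N; ++j) {
        rn[j] = free_r[j] ? soft(y[j] + grad[j] / L, pb.lambda / L) : y[j];
      }
      fn = smooth_eval(pb, rn.data(), nullptr);
      double quad = fy;
      for (int j = 0; j < N; ++j) {
        double dj = rn[j] - y[j];
        quad += grad[j] * dj - 0.5 * L * dj * dj;
      }
      if (fn >= quad - 1e-12 * (1.0 + std::fabs(fy))) break;
      L *= 2.0;
      if (L > 1e14) break;
    }
    double objn = fn;
    for (int j = 0; j < N; ++j) objn -= pb.lambda * std::fabs(rn[j]);
    if (objn < obj) {           // monotone restart
      y = r; theta = 1.0;
      if (std::fabs(objn - obj) < tol * (1.0 + std::fabs(obj))) break;
      continue;
    }
    bool done = std::fabs(objn - obj) < tol * (1.0 + std::fabs(obj));
    double theta_n = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * theta * theta));
    for (int j = 0; j < N; ++j) {
      y[j] = rn[j] + ((theta - 1.0) / theta_n) * (rn[j] - r[j]);
    }
    r = rn; theta = theta_n; obj = objn;
    if (done) break;
    L *= 0.7;
  }
  Lstep = L;
  return obj;
}

// Route to the appropriate inner solver: evaluation only (maxit = 0 /
// all rewards clamped), damped Newton (smooth, all free), or proximal
// FISTA (L1 and/or clamped coordinates).
double solve_node(const Problem& pb, std::vector<double>& r,
                  const std::vector<bool>& free_r, double tol, int maxit,
                  double& Lstep) {
  bool all_free = true, any_free = false;
  for (bool fj : free_r) { all_free = all_free && fj; any_free = any_free || fj; }
  if (maxit <= 0 || !any_free) {
    double obj = smooth_eval(pb, r.data(), nullptr);
    for (size_t j = 0; j < r.size(); ++j) obj -= pb.lambda * std::fabs(r[j]);
    return obj;
  }
  if (pb.lambda == 0.0 && all_free) return newton(pb, r, tol, maxit);
  return fista(pb, r, free_r, tol, maxit, Lstep);
}

} // namespace

// Fit rewards at fixed gammas.  dist: list of (T*K) x M_j matrices;
// obs: 0-based flattened (t, a_t) indices; r_init/r_fixed control warm
// start and clamped (non-estimated) rewards.
// [[Rcpp::export]]
List cpp_fit_rewards(List dist, IntegerVector obs, int T, int K,
                     NumericVector gammas, double eta, double lambda,
                     NumericVector r_init, LogicalVector r_free,
                     double tol, int maxit) {
  const int N = dist.size(), TK = T * K;
  std::vector<NumericMatrix> dm(N);
  std::vector<std::vector<double>> phis(N);
  Problem pb;
  pb.phi.resize(N);
  for (int j = 0; j < N; ++j) {
    dm[j] = as<NumericMatrix>(dist[j]);
    phis[j] = make_phi(dm[j], gammas[j], TK);
    pb.phi[j] = phis[j].data();
  }
  pb.obs = INTEGER(obs); pb.T = T; pb.K = K; pb.N = N;
  pb.eta = eta; pb.lambda = lambda;
  std::vector<double> r(r_init.begin(), r_init.end());
  std::vector<bool> fr(r_free.begin(), r_free.end());
  double L = 1.0;
  double obj = solve_node(pb, r, fr, tol, maxit, L);
  double ll = smooth_eval(pb, r.data(), nullptr);
  if (!std::isfinite(obj))
    stop("non-finite objective in reward fit (eta=%g, lambda=%g)", eta, lambda);
  return List::create(_["rewards"] = NumericVector(r.begin(), r.end()),
                      _["objective"] = obj, _["loglik"] = ll);
}

// Grid search over gamma combinations.  cand: list of N numeric vectors of
// candidate gammas; nodes: n x N matrix of 0-based indices into cand.
// Returns per-node objectives and the best node's fit.
// [[Rcpp::export]]
List cpp_grid_search(List dist, IntegerVector obs, int T, int K,
                     List cand, IntegerMatrix nodes, double eta,
                     double lambda, NumericVector r_init,
                     LogicalVector r_free, double tol, int maxit) {
  const int N = dist.size(), TK = T * K, n_nodes = nodes.nrow();
  std::vector<NumericMatrix> dm(N);
  std::vector<NumericVector> cv(N);
  std::vector<std::vector<std::vector<double>>> cache(N);
  for (int j = 0; j < N; ++j) {
    dm[j] = as<NumericMatrix>(dist[j]);
    cv[j] = as<NumericVector>(cand[j]);
    cache[j].resize(cv[j].size());
  }
  Problem pb;
  pb.phi.resize(N);
  pb.obs = INTEGER(obs); pb.T = T; pb.K = K; pb.N = N;
  pb.eta = eta; pb.lambda = lambda;
  std::vector<bool> fr(r_free.begin(), r_free.end());
  std::vector<double> r(r_init.begin(), r_init.end());
  NumericVector objs(n_nodes);
  NumericMatrix fit_r(n_nodes, N);
  double best = -1e300;
  int best_node = 0;
  std::vector<double> best_r(r);
  double L = 1.0;
  for (int i = 0; i < n_nodes; ++i) {
    for (int j = 0; j < N; ++j) {
      int gi = nodes(i, j);
      if (cache[j][gi].empty() && dm[j].ncol() > 0)
        cache[j][gi] = make_phi(dm[j], cv[j][gi], TK);
      if (dm[j].ncol() == 0 && cache[j][gi].empty())
        cache[j][gi].assign(TK, 0.0);
      pb.phi[j] = cache[j][gi].data();
    }
    double obj = solve_node(pb, r, fr, tol, maxit, L);
    objs[i] = obj;
    for (int j = 0; j < N; ++j) fit_r(i, j) = r[j];
    if (obj > best) { best = obj; best_node = i; best_r = r; }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["objectives"] = objs,
                      _["best_node"] = best_node + 1,
                      _["best_rewards"] = NumericVector(best_r.begin(),
                                                        best_r.end()),
                      _["best_objective"] = best,
                      _["rewards"] = fit_r);
}
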