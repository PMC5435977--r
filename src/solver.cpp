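// Coordinate-descent path solver for per-feature-weighted L1 penalized
// regression (gaussian / binomial / Cox with Breslow ties), and a blockwise
// proximal-gradient solver for the sparse group lasso.
//
// Conventions: X arrives standardized (column mean 0, variance 1 with
// divisor n); for gaussian, y is centered. Losses are scaled by 1/n
// (1/(2n) RSS for gaussian), so the per-coordinate update with unit-variance
// columns is a plain soft-threshold step.
//
// Each lambda is solved on a working set assembled by the sequential strong
// rule from the previous lambda's gradient, then certified by one full
// gradient pass; violators are added and the solve repeated, so returned
// solutions satisfy the full KKT conditions regardless of the screen.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent cycle over the columns in idx for the weighted
// least-squares model (1/(2n)) sum_i w_i (r_i)^2 + lam sum pw_j |b_j|,
// where r is kept equal to z - b0 - X b. Returns max |delta beta|.
static double cd_cycle(const NumericMatrix& X, const NumericVector& w,
                       std::vector<double>& r, std::vector<double>& beta,
                       const NumericVector& pw, double lam,
                       const std::vector<double>& xv,
                       const std::vector<int>& idx, int n) {
  double dmax = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    int j = idx[k];
    if (xv[j] <= 0.0) continue;
    const double* xj = &X(0, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += w[i] * xj[i] * r[i];
    g /= n;
    double u = g + xv[j] * beta[j];
    double bnew = soft(u, lam * pw[j]) / xv[j];
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bnew;
      double ad = std::fabs(d);
      if (ad > dmax) dmax = ad;
    }
  }
  return dmax;
}

static void update_intercept(const NumericVector& w, std::vector<double>& r,
                             double& b0, double wsum, int n) {
  if (wsum <= 0.0) return;
  double g = 0.0;
  for (int i = 0; i < n; ++i) g += w[i] * r[i];
  double d = g / wsum;
  if (d != 0.0) { b0 += d; for (int i = 0; i < n; ++i) r[i] -= d; }
}

// Weighted lasso restricted to the columns in sub: sweep over sub, iterate
// on its nonzero subset, re-sweep until stable.
static int cd_solve(const NumericMatrix& X, const NumericVector& w,
                    std::vector<double>& r, std::vector<double>& beta,
                    double& b0, bool intercept,
                    const NumericVector& pw, double lam,
                    const std::vector<double>& xv,
                    const std::vector<int>& sub,
                    double tol, int maxit, int n) {
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];
  int iters = 0;
  for (;;) {
    if (intercept) update_intercept(w, r, b0, wsum, n);
    double dmax = cd_cycle(X, w, r, beta, pw, lam, xv, sub, n);
    ++iters;
    if (dmax < tol || iters >= maxit) return iters;
    std::vector<int> act;
    for (size_t k = 0; k < sub.size(); ++k)
      if (beta[sub[k]] != 0.0) act.push_back(sub[k]);
    for (;;) {
      if (intercept) update_intercept(w, r, b0, wsum, n);
      double dm = cd_cycle(X, w, r, beta, pw, lam, xv, act, n);
      ++iters;
      if (dm < tol || iters >= maxit) break;
    }
    if (iters >= maxit) return iters;
  }
}

// strong-rule working set: previous-solution nonzeros plus columns whose
// gradient at the previous lambda exceeds pw_j * (2 lam - lam_prev)
static void build_working_set(const std::vector<double>& g,
                              const NumericVector& pw,
                              const std::vector<double>& beta,
                              double lam, double lam_prev, int p,
                              std::vector<char>& in_set,
                              std::vector<int>& sub) {
  sub.clear();
  double mult = 2.0 * lam - lam_prev;
  for (int j = 0; j < p; ++j) {
    in_set[j] = (beta[j] != 0.0) ||
      (std::fabs(g[j]) >= pw[j] * mult * (1.0 - 1e-12));
    if (in_set[j]) sub.push_back(j);
  }
}

// add KKT violators (|g_j| > lam pw_j among excluded zero columns);
// returns the number added
static int add_violations(const std::vector<double>& g,
                          const NumericVector& pw, double lam, int p,
                          std::vector<char>& in_set,
                          std::vector<int>& sub) {
  int added = 0;
  for (int j = 0; j < p; ++j) {
    if (in_set[j]) continue;
    if (std::fabs(g[j]) > lam * pw[j] * (1.0 + 1e-10) + 1e-14) {
      in_set[j] = 1;
      sub.push_back(j);
      ++added;
    }
  }
  return added;
}

// full gradient pass: g = (1/n) X^T res for a plain residual-style vector
static void full_gradient(const NumericMatrix& X,
                          const std::vector<double>& res,
                          std::vector<double>& g, int n, int p) {
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * res[i];
    g[j] = s / n;
  }
}

// [[Rcpp::export]]
List cd_gaussian_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& pw, const NumericVector& lambda,
                      double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix betas(p, nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  NumericVector w(n, 1.0);
  std::vector<double> xv(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xv[j] = s / n;
  }
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end()), g(p);
  std::vector<char> in_set(p);
  std::vector<int> sub;
  full_gradient(X, r, g, n, p);
  double b0 = 0.0, lam_prev = lambda[0];
  for (int l = 0; l < nlam; ++l) {
    double lam = lambda[l];
    build_working_set(g, pw, beta, lam, lam_prev, p, in_set, sub);
    int it = 0;
    for (;;) {
      it += cd_solve(X, w, r, beta, b0, false, pw, lam, xv, sub,
                     tol, maxit, n);
      full_gradient(X, r, g, n, p);
      if (add_violations(g, pw, lam, p, in_set, sub) == 0) break;
      if (it >= maxit) break;
    }
    iters[l] = it;
    conv[l] = it < maxit;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    lam_prev = lam;
  }
  return List::create(_["beta"] = betas, _["a0"] = NumericVector(nlam, 0.0),
                      _["iters"] = iters, _["converged"] = conv);
}

static void eta_from_beta(const NumericMatrix& X,
                          const std::vector<double>& beta, double b0,
                          std::vector<double>& eta, int n, int p) {
  std::fill(eta.begin(), eta.end(), b0);
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
  }
}

// [[Rcpp::export]]
List cd_binomial_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& pw, const NumericVector& lambda,
                      double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix betas(p, nlam);
  NumericVector a0(nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  std::vector<double> beta(p, 0.0), eta(n), res(n), g(p), xv(p, 0.0), r(n);
  std::vector<char> in_set(p);
  std::vector<int> sub;
  NumericVector w(n);
  const double pmin = 1e-5;
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));
  // gradient at the null model
  for (int i = 0; i < n; ++i) res[i] = y[i] - ybar;
  full_gradient(X, res, g, n, p);
  double lam_prev = lambda[0];
  for (int l = 0; l < nlam; ++l) {
    double lam = lambda[l];
    build_working_set(g, pw, beta, lam, lam_prev, p, in_set, sub);
    bool ok = false;
    int total_it = 0;
    for (;;) {  // screening loop
      ok = false;
      for (int outer = 0; outer < 100; ++outer) {
        eta_from_beta(X, beta, b0, eta, n, p);
        for (int i = 0; i < n; ++i) {
          double mu = 1.0 / (1.0 + std::exp(-eta[i]));
          if (mu < pmin) mu = pmin;
          if (mu > 1.0 - pmin) mu = 1.0 - pmin;
          double wi = mu * (1.0 - mu);
          w[i] = wi;
          r[i] = (y[i] - mu) / wi;
        }
        for (size_t k = 0; k < sub.size(); ++k) {
          int j = sub[k];
          const double* xj = &X(0, j);
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
          xv[j] = s / n;
        }
        std::vector<double> bold(beta);
        double b0old = b0;
        total_it += cd_solve(X, w, r, beta, b0, true, pw, lam, xv, sub,
                             tol, maxit, n);
        double dmax = std::fabs(b0 - b0old);
        for (size_t k = 0; k < sub.size(); ++k) {
          double d = std::fabs(beta[sub[k]] - bold[sub[k]]);
          if (d > dmax) dmax = d;
        }
        if (dmax < tol * 10.0) { ok = true; break; }
        if (total_it >= maxit) break;
      }
      // certify against the true gradient over all columns
      eta_from_beta(X, beta, b0, eta, n, p);
      for (int i = 0; i < n; ++i)
        res[i] = y[i] - 1.0 / (1.0 + std::exp(-eta[i]));
      full_gradient(X, res, g, n, p);
      if (add_violations(g, pw, lam, p, in_set, sub) == 0) break;
      if (total_it >= maxit) break;
    }
    iters[l] = total_it;
    conv[l] = ok;
    a0[l] = b0;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    lam_prev = lam;
  }
  return List::create(_["beta"] = betas, _["a0"] = a0,
                      _["iters"] = iters, _["converged"] = conv);
}

// Cox partial-likelihood machinery (Breslow ties). Subjects are ordered by
// increasing time; rstart[k] is the first subject index of the risk set of
// the k-th distinct event time, devents[k] its event count. Computes the
// per-subject gradient and diagonal Hessian of -(1/n) log PL.
static void cox_derivs(const std::vector<double>& eta,
                       const IntegerVector& status,
                       const IntegerVector& rstart,
                       const IntegerVector& devents,
                       int n, std::vector<double>& grad,
                       std::vector<double>& w) {
  int K = rstart.size();
  std::vector<double> ee(n), s0(K);
  double emax = eta[0];
  for (int i = 0; i < n; ++i) if (eta[i] > emax) emax = eta[i];
  for (int i = 0; i < n; ++i) ee[i] = std::exp(eta[i] - emax);
  std::vector<double> suff(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suff[i] = suff[i + 1] + ee[i];
  for (int k = 0; k < K; ++k) s0[k] = suff[rstart[k]];
  double ch = 0.0, ch2 = 0.0;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k < K && rstart[k] <= i) {
      ch += devents[k] / s0[k];
      ch2 += devents[k] / (s0[k] * s0[k]);
      ++k;
    }
    // ee carries exp(-emax); ch carries exp(+emax): the scales cancel
    double mu = ee[i] * ch;
    double mu2 = ee[i] * ee[i] * ch2;
    grad[i] = (status[i] ? 1.0 : 0.0) - mu;
    double wi = mu - mu2;
    if (wi < 1e-5) wi = 1e-5;
    w[i] = wi;
  }
}

// -(1/n) Breslow log partial likelihood at eta
static double cox_negll(const std::vector<double>& eta,
                        const IntegerVector& status,
                        const IntegerVector& rstart,
                        const IntegerVector& devents, int n) {
  int K = rstart.size();
  double emax = eta[0];
  for (int i = 0; i < n; ++i) if (eta[i] > emax) emax = eta[i];
  std::vector<double> suff(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i)
    suff[i] = suff[i + 1] + std::exp(eta[i] - emax);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) if (status[i]) ll += eta[i];
  for (int k = 0; k < K; ++k)
    ll -= devents[k] * (emax + std::log(suff[rstart[k]]));
  return -ll / n;
}

// [[Rcpp::export]]
List cd_cox_path(const NumericMatrix& X, const IntegerVector& status,
                 const IntegerVector& rstart, const IntegerVector& devents,
                 const NumericVector& pw, const NumericVector& lambda,
                 double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix betas(p, nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  std::vector<double> beta(p, 0.0), eta(n, 0.0), grad(n), wv(n), r(n),
      xv(p, 0.0), g(p), eta_new(n);
  std::vector<char> in_set(p);
  std::vector<int> sub;
  NumericVector w(n);
  double b0 = 0.0;
  cox_derivs(eta, status, rstart, devents, n, grad, wv);
  full_gradient(X, grad, g, n, p);
  double lam_prev = lambda[0];
  for (int l = 0; l < nlam; ++l) {
    double lam = lambda[l];
    build_working_set(g, pw, beta, lam, lam_prev, p, in_set, sub);
    bool ok = false;
    int total_it = 0;
    auto pen = [&](const std::vector<double>& b) {
      double s = 0.0;
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0) s += pw[j] * std::fabs(b[j]);
      return lam * s;
    };
    for (;;) {  // screening loop
      ok = false;
      // the diagonal-Hessian outer iteration contracts slowly near
      // degenerate small-lambda fits; allow many cheap outer passes
      for (int outer = 0; outer < 20000; ++outer) {
        eta_from_beta(X, beta, 0.0, eta, n, p);
        cox_derivs(eta, status, rstart, devents, n, grad, wv);
        for (int i = 0; i < n; ++i) {
          w[i] = wv[i];
          r[i] = grad[i] / wv[i];
        }
        for (size_t k = 0; k < sub.size(); ++k) {
          int j = sub[k];
          const double* xj = &X(0, j);
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
          xv[j] = s / n;
        }
        std::vector<double> bold(beta);
        double obj_old = cox_negll(eta, status, rstart, devents, n) +
          pen(bold);
        total_it += cd_solve(X, w, r, beta, b0, false, pw, lam, xv, sub,
                             tol, maxit, n);
        // the quadratic is not a majorizer: damp until the true
        // penalized objective does not increase
        for (int halv = 0; halv < 30; ++halv) {
          eta_from_beta(X, beta, 0.0, eta_new, n, p);
          double obj_new = cox_negll(eta_new, status, rstart, devents, n) +
            pen(beta);
          if (obj_new <= obj_old + 1e-13) break;
          for (int j = 0; j < p; ++j)
            beta[j] = 0.5 * (beta[j] + bold[j]);
        }
        double dmax = 0.0;
        for (size_t k = 0; k < sub.size(); ++k) {
          double d = std::fabs(beta[sub[k]] - bold[sub[k]]);
          if (d > dmax) dmax = d;
        }
        if (dmax < tol * 10.0) { ok = true; break; }
        if (total_it >= maxit) break;
      }
      eta_from_beta(X, beta, 0.0, eta, n, p);
      cox_derivs(eta, status, rstart, devents, n, grad, wv);
      full_gradient(X, grad, g, n, p);
      if (add_violations(g, pw, lam, p, in_set, sub) == 0) break;
      if (total_it >= maxit) break;
    }
    iters[l] = total_it;
    conv[l] = ok;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    lam_prev = lam;
  }
  return List::create(_["beta"] = betas, _["iters"] = iters,
                      _["converged"] = conv);
}

// ---------------- sparse group lasso ----------------
// Penalty: (1-alpha)*lam * sum_m sqrt(p_m) ||beta_m||_2 + alpha*lam ||beta||_1
// Solved by proximal gradient (FISTA with backtracking). The prox of the
// composite penalty is elementwise soft-thresholding followed by blockwise
// group shrinkage.

static double sgl_loss(const NumericMatrix& X, const NumericVector& y,
                       int family, const std::vector<double>& beta, double b0,
                       std::vector<double>& eta) {
  int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) eta[i] = b0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
  }
  double f = 0.0;
  if (family == 0) {  // gaussian, (1/(2n)) RSS
    for (int i = 0; i < n; ++i) {
      double d = y[i] - eta[i];
      f += d * d;
    }
    f /= (2.0 * n);
  } else {  // binomial, (1/n) neg log lik
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      double l = (e > 30.0) ? e : std::log1p(std::exp(e));
      f += l - y[i] * e;
    }
    f /= n;
  }
  return f;
}

static void sgl_grad(const NumericMatrix& X, const NumericVector& y,
                     int family, const std::vector<double>& eta,
                     std::vector<double>& g, double& g0) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> r(n);
  if (family == 0) {
    for (int i = 0; i < n; ++i) r[i] = eta[i] - y[i];
  } else {
    for (int i = 0; i < n; ++i)
      r[i] = 1.0 / (1.0 + std::exp(-eta[i])) - y[i];
  }
  g0 = 0.0;
  for (int i = 0; i < n; ++i) g0 += r[i];
  g0 /= n;
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * r[i];
    g[j] = s / n;
  }
}

// [[Rcpp::export]]
List sgl_path(const NumericMatrix& X, const NumericVector& y, int family,
              const IntegerVector& gstart, const IntegerVector& gsize,
              double alpha, const NumericVector& lambda, bool intercept,
              double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), nlam = lambda.size(), M = gstart.size();
  NumericMatrix betas(p, nlam);
  NumericVector a0(nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  std::vector<double> beta(p, 0.0), v(p), g(p), cand(p), eta(n), sq(M);
  for (int m = 0; m < M; ++m) sq[m] = std::sqrt((double)gsize[m]);
  double b0 = 0.0, v0 = 0.0;
  if (family == 1 && intercept) {
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    b0 = std::log(ybar / (1.0 - ybar));
  }
  double step = 1.0;
  for (int l = 0; l < nlam; ++l) {
    double lam = lambda[l];
    double t_fista = 1.0;
    std::copy(beta.begin(), beta.end(), v.begin());
    v0 = b0;
    bool ok = false;
    int it = 0;
    for (; it < maxit; ++it) {
      double fv = sgl_loss(X, y, family, v, v0, eta);
      double g0;
      sgl_grad(X, y, family, eta, g, g0);
      double b0new = v0;
      for (int bt = 0; bt < 60; ++bt) {
        double thr1 = step * alpha * lam;
        for (int m = 0; m < M; ++m) {
          int s0i = gstart[m], sz = gsize[m];
          double nrm = 0.0;
          for (int j = s0i; j < s0i + sz; ++j) {
            double u = soft(v[j] - step * g[j], thr1);
            cand[j] = u;
            nrm += u * u;
          }
          nrm = std::sqrt(nrm);
          double thr2 = step * (1.0 - alpha) * lam * sq[m];
          if (nrm <= thr2) {
            for (int j = s0i; j < s0i + sz; ++j) cand[j] = 0.0;
          } else {
            double sc = 1.0 - thr2 / nrm;
            for (int j = s0i; j < s0i + sz; ++j) cand[j] *= sc;
          }
        }
        b0new = intercept ? (v0 - step * g0) : v0;
        double fnew = sgl_loss(X, y, family, cand, b0new, eta);
        double q = fv, sq2 = 0.0;
        for (int j = 0; j < p; ++j) {
          double d = cand[j] - v[j];
          q += g[j] * d;
          sq2 += d * d;
        }
        double d0 = b0new - v0;
        q += g0 * d0;
        sq2 += d0 * d0;
        q += sq2 / (2.0 * step);
        if (fnew <= q + 1e-12) break;
        step *= 0.5;
      }
      double tnew = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_fista * t_fista));
      double mom = (t_fista - 1.0) / tnew;
      double dmax = 0.0, bmax = 0.0;
      for (int j = 0; j < p; ++j) {
        double d = cand[j] - beta[j];
        double ad = std::fabs(d);
        if (ad > dmax) dmax = ad;
        double ab = std::fabs(cand[j]);
        if (ab > bmax) bmax = ab;
        v[j] = cand[j] + mom * (cand[j] - beta[j]);
        beta[j] = cand[j];
      }
      double d0 = b0new - b0;
      if (std::fabs(d0) > dmax) dmax = std::fabs(d0);
      v0 = b0new + mom * d0;
      b0 = b0new;
      t_fista = tnew;
      if (dmax < tol * std::max(1.0, bmax)) { ok = true; break; }
      // occasional step-size recovery after backtracking shrinkage
      if ((it & 31) == 31) step *= 1.5;
    }
    iters[l] = it + 1;
    conv[l] = ok;
    a0[l] = b0;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
  }
  return List::create(_["beta"] = betas, _["a0"] = a0,
                      _["iters"] = iters, _["converged"] = conv);
}
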