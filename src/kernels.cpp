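#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Minimum of perm[x] over each set, sets given flattened (0-based values).
// perm[x] is the image of element x under one permutation of [0, M).
// [[Rcpp::export]]
IntegerVector cpp_min_permuted(IntegerVector flat, IntegerVector lens,
                               IntegerVector perm) {
  const int n = lens.size();
  IntegerVector out(n);
  int pos = 0;
  for (int s = 0; s < n; ++s) {
    int len = lens[s];
    if (len == 0) stop("empty set at position %d", s + 1);
    int best = perm[flat[pos]];
    for (int j = 1; j < len; ++j) {
      int v = perm[flat[pos + j]];
      if (v < best) best = v;
    }
    out[s] = best;
    pos += len;
  }
  return out;
}

// Same, with the permutation approximated by x -> (a*x + b) mod p.
// [[Rcpp::export]]
IntegerVector cpp_min_affine(IntegerVector flat, IntegerVector lens,
                             double a, double b, double p) {
  const uint64_t ua = (uint64_t)a, ub = (uint64_t)b, up = (uint64_t)p;
  const int n = lens.size();
  IntegerVector out(n);
  int pos = 0;
  for (int s = 0; s < n; ++s) {
    int len = lens[s];
    if (len == 0) stop("empty set at position %d", s + 1);
    uint64_t best = (ua * (uint64_t)flat[pos] + ub) % up;
    for (int j = 1; j < len; ++j) {
      uint64_t v = (ua * (uint64_t)flat[pos + j] + ub) % up;
      if (v < best) best = v;
    }
    out[s] = (int)best;
    pos += len;
  }
  return out;
}

// Vectorized (a*x + b) mod p in exact 64-bit arithmetic.
// [[Rcpp::export]]
NumericVector cpp_affine_hash(NumericVector x, double a, double b, double p) {
  const uint64_t ua = (uint64_t)a, ub = (uint64_t)b, up = (uint64_t)p;
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = (double)((ua * (uint64_t)x[i] + ub) % up);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hinge-loss linear models over sparse binary designs.
// Primal objective: R(w) + C * sum_i max(1 - y_i (w.x_i [+ b]), 0),
// R = ||w||_1 (L1) or 0.5 ||w||_2^2 (L2). Both solvers track the best primal
// iterate seen, so the reported per-sweep trace is non-increasing.

static double primal_objective(const std::vector<double>& w, double bias_pen,
                               const std::vector<double>& s,
                               const NumericVector& y, double C, int reg) {
  double obj = bias_pen;
  if (reg == 1) {
    for (double v : w) obj += std::fabs(v);
  } else {
    for (double v : w) obj += 0.5 * v * v;
  }
  for (size_t i = 0; i < s.size(); ++i) {
    double m = 1.0 - y[i] * s[i];
    if (m > 0) obj += C * m;
  }
  return obj;
}

// L2-regularized hinge loss by dual coordinate descent (one box-constrained
// dual variable per example, cyclic order). xtp/xti give row-wise access:
// the nonzero feature indices of example i. With fit_bias the intercept is
// an implicit constant feature, regularized like the rest.
// Stops when the duality gap of the best iterate falls below tol (relative).
// [[Rcpp::export]]
List cpp_train_l2_dual(IntegerVector xtp, IntegerVector xti, int n, int d,
                       NumericVector y, double C, bool fit_bias,
                       double tol, int max_sweeps) {
  std::vector<double> w(d, 0.0), alpha(n, 0.0), s(n, 0.0);
  double bias = 0.0;
  std::vector<double> w_best(d, 0.0);
  double bias_best = 0.0, best_obj = R_PosInf;
  NumericVector trace(max_sweeps);
  bool converged = false;
  int sweeps = 0;

  for (int sweep = 1; sweep <= max_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int from = xtp[i], to = xtp[i + 1];
      double wx = fit_bias ? bias : 0.0;
      for (int t = from; t < to; ++t) wx += w[xti[t]];
      double G = y[i] * wx - 1.0;
      double a = alpha[i];
      if ((a <= 0.0 && G >= 0.0) || (a >= C && G <= 0.0)) continue;
      double qii = (to - from) + (fit_bias ? 1.0 : 0.0);
      if (qii <= 0.0) continue;
      double an = std::min(std::max(a - G / qii, 0.0), C);
      double delta = (an - a) * y[i];
      if (delta != 0.0) {
        for (int t = from; t < to; ++t) w[xti[t]] += delta;
        if (fit_bias) bias += delta;
        alpha[i] = an;
      }
    }
    // primal objective at the current iterate
    std::fill(s.begin(), s.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double wx = fit_bias ? bias : 0.0;
      for (int t = xtp[i]; t < xtp[i + 1]; ++t) wx += w[xti[t]];
      s[i] = wx;
    }
    double obj = primal_objective(w, fit_bias ? 0.5 * bias * bias : 0.0,
                                  s, y, C, 2);
    if (obj < best_obj) {
      best_obj = obj; w_best = w; bias_best = bias;
    }
    trace[sweep - 1] = best_obj;
    sweeps = sweep;
    double wsq = 0.0;
    for (double v : w) wsq += v * v;
    if (fit_bias) wsq += bias * bias;
    double dual = std::accumulate(alpha.begin(), alpha.end(), 0.0) - 0.5 * wsq;
    if (best_obj - dual <= tol * std::max(1.0, std::fabs(best_obj))) {
      converged = true;
      break;
    }
  }

  NumericVector tr(sweeps);
  for (int i = 0; i < sweeps; ++i) tr[i] = trace[i];
  return List::create(_["weights"] = NumericVector(w_best.begin(), w_best.end()),
                      _["bias"] = bias_best, _["objective"] = best_obj,
                      _["trace"] = tr, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}

// L1-regularized hinge loss by ADMM: split z = diag(y) X w, alternate a
// lasso w-update (cyclic coordinate descent with soft-thresholding, exact
// zeros), the closed-form hinge prox for z, and a dual ascent on u.
// xp/xi give column-wise access. An unpenalized intercept, when requested,
// is an extra coordinate skipped by the threshold.
// [[Rcpp::export]]
List cpp_train_l1_admm(IntegerVector xp, IntegerVector xi, int n, int d,
                       NumericVector y, double C, bool fit_bias,
                       double rho, double tol, int max_iters) {
  std::vector<double> w(d, 0.0), s(n, 0.0), z(n, 0.0), u(n, 0.0);
  double bias = 0.0;
  std::vector<double> w_best(d, 0.0);
  double bias_best = 0.0, best_obj = R_PosInf;
  NumericVector trace(max_iters);
  bool converged = false;
  int iters = 0;
  const double kappa = C / rho;
  double best_prev_window = R_PosInf;

  for (int iter = 1; iter <= max_iters; ++iter) {
    // w-update: a few lasso sweeps on |w|_1 + rho/2 sum (y_i s_i - v_i)^2
    for (int pass = 0; pass < 3; ++pass) {
      for (int j = 0; j < d; ++j) {
        int from = xp[j], to = xp[j + 1];
        int nj = to - from;
        if (nj == 0) continue;
        double grad = 0.0;
        for (int t = from; t < to; ++t) {
          int i = xi[t];
          grad += (y[i] * s[i] - (z[i] - u[i])) * y[i];
        }
        grad *= rho;
        double a = rho * nj;
        double cand = w[j] - grad / a;
        double thr = 1.0 / a;
        double wn = (cand > thr) ? cand - thr : ((cand < -thr) ? cand + thr : 0.0);
        double delta = wn - w[j];
        if (delta != 0.0) {
          for (int t = from; t < to; ++t) s[xi[t]] += delta;
          w[j] = wn;
        }
      }
      if (fit_bias) {
        double grad = 0.0;
        for (int i = 0; i < n; ++i) grad += (y[i] * s[i] - (z[i] - u[i])) * y[i];
        double bn = bias - grad / n;   // rho cancels, no threshold
        double delta = bn - bias;
        if (delta != 0.0) {
          for (int i = 0; i < n; ++i) s[i] += delta;
          bias = bn;
        }
      }
    }
    // z-update: prox of (C/rho) * hinge at q = y s + u
    double pri_res = 0.0;
    for (int i = 0; i < n; ++i) {
      double q = y[i] * s[i] + u[i];
      if (q > 1.0) z[i] = q;
      else if (q < 1.0 - kappa) z[i] = q + kappa;
      else z[i] = 1.0;
      double r = y[i] * s[i] - z[i];
      u[i] += r;
      pri_res = std::max(pri_res, std::fabs(r));
    }

    double obj = primal_objective(w, 0.0, s, y, C, 1);
    if (obj < best_obj) {
      best_obj = obj; w_best = w; bias_best = bias;
    }
    trace[iter - 1] = best_obj;
    iters = iter;
    if (iter % 10 == 0) {
      bool obj_settled = (best_prev_window - best_obj) <=
        tol * std::max(1.0, std::fabs(best_obj));
      if (obj_settled && pri_res <= 1e-3) {
        converged = true;
        break;
      }
      best_prev_window = best_obj;
    }
  }

  NumericVector tr(iters);
  for (int i = 0; i < iters; ++i) tr[i] = trace[i];
  return List::create(_["weights"] = NumericVector(w_best.begin(), w_best.end()),
                      _["bias"] = bias_best, _["objective"] = best_obj,
                      _["trace"] = tr, _["sweeps"] = iters,
                      _["converged"] = converged);
}
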