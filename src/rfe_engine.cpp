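#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>
using namespace Rcpp;

// C-SVC dual solver (SMO with maximal-violating-pair working-set selection)
// on a precomputed kernel matrix. Labels must be +1/-1. Convention:
// decision f(x) = sum_t alpha_t y_t K(x_t, x) + b, predict +1 iff f > 0.

struct SvmFit {
  std::vector<double> alpha;
  double b;
  int iters;
};

static SvmFit smo_solve(const std::vector<double>& K, int n,
                        const std::vector<int>& y, double C,
                        double tol, int max_iter) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient of 1/2 a'Qa - e'a, Q_st = y_s y_t K_st
  int it = 0;
  for (; it < max_iter; ++it) {
    int i = -1, j = -1;
    double Gmax = -DBL_MAX, Gmin = DBL_MAX;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double a = Kii + Kjj - 2.0 * Kij;
    if (a <= 0) a = 1e-12;
    double delta = (Gmax - Gmin) / a;

    double old_ai = alpha[i], old_aj = alpha[j];
    double zeta = y[i] * old_ai + y[j] * old_aj;
    alpha[i] += y[i] * delta;
    // box projection preserving y_i a_i + y_j a_j = zeta
    if (alpha[i] > C) alpha[i] = C;
    if (alpha[i] < 0) alpha[i] = 0;
    alpha[j] = y[j] * (zeta - y[i] * alpha[i]);
    if (alpha[j] > C) alpha[j] = C;
    if (alpha[j] < 0) alpha[j] = 0;
    alpha[i] = y[i] * (zeta - y[j] * alpha[j]);
    if (alpha[i] > C) alpha[i] = C;
    if (alpha[i] < 0) alpha[i] = 0;

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * y[i] * K[(size_t)t * n + i] * dai +
              y[t] * y[j] * K[(size_t)t * n + j] * daj;
    }
  }
  // rho as in LIBSVM; b = -rho
  double ub = DBL_MAX, lb = -DBL_MAX, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nr_free; sum_free += yG;
    }
  }
  double rho = (nr_free > 0) ? sum_free / nr_free : (ub + lb) / 2.0;
  SvmFit fit;
  fit.alpha = alpha;
  fit.b = -rho;
  fit.iters = it;
  return fit;
}

// [[Rcpp::export(name = ".svm_rbf_train_cpp", rng = false)]]
List svm_rbf_train_cpp(NumericMatrix X, IntegerVector y, double cost,
                       double gamma, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = X(i, f) - X(j, f);
        d2 += d * d;
      }
      double k = std::exp(-gamma * d2);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
  std::vector<int> yy(y.begin(), y.end());
  SvmFit fit = smo_solve(K, n, yy, cost, tol, max_iter);
  NumericVector coefs(n);
  for (int t = 0; t < n; ++t) coefs[t] = fit.alpha[t] * yy[t];
  return List::create(_["coefs"] = coefs, _["b"] = fit.b,
                      _["iters"] = fit.iters);
}

// [[Rcpp::export(name = ".svm_rbf_decision_cpp", rng = false)]]
NumericVector svm_rbf_decision_cpp(NumericMatrix X, NumericVector coefs,
                                   double b, double gamma, NumericMatrix Xnew) {
  int n = X.nrow(), p = X.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = b;
    for (int t = 0; t < n; ++t) {
      if (coefs[t] == 0.0) continue;
      double d2 = 0.0;
      for (int ff = 0; ff < p; ++ff) {
        double d = X(t, ff) - Xnew(q, ff);
        d2 += d * d;
      }
      f += coefs[t] * std::exp(-gamma * d2);
    }
    out[q] = f;
  }
  return out;
}

// Full single-fold engine: RFE with correlation-bias reduction on training
// data, then an RBF-SVM on the surviving features, with decision values for
// test rows. Kernel matrices are maintained incrementally through the
// per-feature squared-difference matrices, so each elimination step costs
// O(p * nSV^2) rather than a full refit from raw data.
//
// Ranking criterion per feature group g (alpha held fixed):
//   dJ(g) = 1/2 a'Ha - 1/2 a'H^{(-g)}a = sum_{j<k in SV} M_jk (1 - exp(gamma * D_g(j,k)))
// with M = (c c') .* K restricted to support vectors, c_t = alpha_t y_t,
// and D_g the summed squared differences over the group's features.
//
// Groups: greedy cliques over |r| >= corr_threshold in ascending feature
// order (CBR); every member receives the group score. The lowest-scored
// feature is eliminated; ties keep the lower feature index (the larger
// index is eliminated).
// [[Rcpp::export(name = ".rfe_svm_engine_cpp", rng = false)]]
List rfe_svm_engine_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                        double cost, int target_k, double corr_threshold,
                        bool use_cbr, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), m = Xtest.nrow();
  std::vector<int> yy(y.begin(), y.end());

  // per-feature squared-difference matrices and running sum
  std::vector< std::vector<double> > D(p, std::vector<double>((size_t)n * n, 0.0));
  std::vector<double> Dsum((size_t)n * n, 0.0);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d = X(i, f) - X(j, f);
        double d2 = d * d;
        D[f][(size_t)i * n + j] = d2;
        D[f][(size_t)j * n + i] = d2;
        Dsum[(size_t)i * n + j] += d2;
        Dsum[(size_t)j * n + i] += d2;
      }
    }
  }

  // per-feature sample variances (training data fixed within the fold)
  std::vector<double> varf(p, 0.0);
  for (int f = 0; f < p; ++f) {
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += X(i, f);
    mu /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = X(i, f) - mu;
      ss += d * d;
    }
    varf[f] = ss / (n - 1);
  }

  // feature correlation matrix, computed once (|r| used for CBR grouping)
  std::vector<double> corr;
  if (use_cbr) {
    corr.assign((size_t)p * p, 0.0);
    std::vector<double> mu(p, 0.0);
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) mu[f] += X(i, f);
      mu[f] /= n;
    }
    for (int f = 0; f < p; ++f) {
      corr[(size_t)f * p + f] = 1.0;
      for (int g = f + 1; g < p; ++g) {
        double s = 0.0;
        for (int i = 0; i < n; ++i)
          s += (X(i, f) - mu[f]) * (X(i, g) - mu[g]);
        double denom = std::sqrt(varf[f] * varf[g]) * (n - 1);
        double r = (denom > 0) ? s / denom : 0.0;
        corr[(size_t)f * p + g] = std::fabs(r);
        corr[(size_t)g * p + f] = std::fabs(r);
      }
    }
  }

  std::vector<bool> active(p, true);
  int n_active = p;
  std::vector<int> elim_order;
  std::vector<double> K((size_t)n * n);
  std::vector<int> sv;
  std::vector<double> csv;
  if (target_k < 1) target_k = 1;

  while (n_active > target_k) {
    // pooled variance over active features
    double pooled = 0.0;
    for (int f = 0; f < p; ++f) if (active[f]) pooled += varf[f];
    pooled /= n_active;
    if (pooled <= 0) stop("all active features have zero variance");
    double gamma = 1.0 / (n_active * pooled);

    for (size_t idx = 0; idx < (size_t)n * n; ++idx)
      K[idx] = std::exp(-gamma * Dsum[idx]);
    SvmFit fit = smo_solve(K, n, yy, cost, tol, max_iter);

    sv.clear(); csv.clear();
    for (int t = 0; t < n; ++t) {
      if (fit.alpha[t] > 1e-12) {
        sv.push_back(t);
        csv.push_back(fit.alpha[t] * yy[t]);
      }
    }
    int nsv = (int)sv.size();

    // grouping of active features
    std::vector< std::vector<int> > groups;
    if (use_cbr) {
      for (int f = 0; f < p; ++f) {
        if (!active[f]) continue;
        bool placed = false;
        for (size_t g = 0; g < groups.size() && !placed; ++g) {
          bool ok = true;
          for (size_t mI = 0; mI < groups[g].size(); ++mI) {
            if (corr[(size_t)f * p + groups[g][mI]] < corr_threshold) {
              ok = false; break;
            }
          }
          if (ok) { groups[g].push_back(f); placed = true; }
        }
        if (!placed) groups.push_back(std::vector<int>(1, f));
      }
    } else {
      for (int f = 0; f < p; ++f)
        if (active[f]) groups.push_back(std::vector<int>(1, f));
    }

    // score each group by whole-group removal; assign to members
    std::vector<double> score(p, 0.0);
    for (size_t g = 0; g < groups.size(); ++g) {
      double s = 0.0;
      const std::vector<int>& mem = groups[g];
      for (int a = 0; a < nsv; ++a) {
        int ja = sv[a];
        for (int bI = a + 1; bI < nsv; ++bI) {
          int jb = sv[bI];
          size_t idx = (size_t)ja * n + jb;
          double dg = 0.0;
          for (size_t mi = 0; mi < mem.size(); ++mi) dg += D[mem[mi]][idx];
          s += csv[a] * csv[bI] * K[idx] * (1.0 - std::exp(gamma * dg));
        }
      }
      for (size_t mi = 0; mi < mem.size(); ++mi) score[mem[mi]] = s;
    }

    // eliminate the lowest-scored feature; ties keep the lower index
    double smin = DBL_MAX;
    for (int f = 0; f < p; ++f)
      if (active[f] && score[f] < smin) smin = score[f];
    double tie_eps = 1e-9 * std::max(1.0, std::fabs(smin));
    int elim = -1;
    for (int f = 0; f < p; ++f)
      if (active[f] && score[f] <= smin + tie_eps) elim = f; // largest index
    if (elim < 0) stop("internal error: no feature to eliminate");

    for (size_t idx = 0; idx < (size_t)n * n; ++idx) Dsum[idx] -= D[elim][idx];
    active[elim] = false;
    --n_active;
    elim_order.push_back(elim + 1); // 1-based
  }

  // final model on surviving features
  double pooled = 0.0;
  for (int f = 0; f < p; ++f) if (active[f]) pooled += varf[f];
  pooled /= n_active;
  if (pooled <= 0) stop("all selected features have zero variance");
  double gamma = 1.0 / (n_active * pooled);
  for (size_t idx = 0; idx < (size_t)n * n; ++idx)
    K[idx] = std::exp(-gamma * Dsum[idx]);
  SvmFit fit = smo_solve(K, n, yy, cost, tol, max_iter);
  NumericVector coefs(n);
  for (int t = 0; t < n; ++t) coefs[t] = fit.alpha[t] * yy[t];

  IntegerVector selected(n_active);
  {
    int k = 0;
    for (int f = 0; f < p; ++f) if (active[f]) selected[k++] = f + 1;
  }

  NumericVector dec(m);
  for (int q = 0; q < m; ++q) {
    double fx = fit.b;
    for (int t = 0; t < n; ++t) {
      if (coefs[t] == 0.0) continue;
      double d2 = 0.0;
      for (int f = 0; f < p; ++f) {
        if (!active[f]) continue;
        double d = X(t, f) - Xtest(q, f);
        d2 += d * d;
      }
      fx += coefs[t] * std::exp(-gamma * d2);
    }
    dec[q] = fx;
  }

  return List::create(_["selected"] = selected,
                      _["elim_order"] = wrap(elim_order),
                      _["decision"] = dec,
                      _["coefs"] = coefs,
                      _["b"] = fit.b,
                      _["gamma"] = gamma);
}
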