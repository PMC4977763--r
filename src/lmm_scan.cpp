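#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Univariate linear mixed model, profiled maximum likelihood.
//
// Model (after rotation into the kinship eigenbasis):
//   y* = w* a + x* b + e*,  Var(e*_i) = tau^{-1} (lambda d_i + 1)
// with d the kinship eigenvalues, w the intercept, x the SNP dosage.
// For fixed lambda the fixed effects and tau are profiled out in closed
// form; lambda is maximized on log10 scale over [-5, 5] by a coarse grid
// followed by golden-section refinement of every local grid optimum.
// ML (not REML) throughout, so likelihood-ratio tests between nested
// models are valid.

static const double LOG10_LO = -5.0, LOG10_HI = 5.0;

// Profile log-likelihood at fixed lambda. ux may be NULL (null model).
// On singular design (SNP collinear with the intercept) returns NA.
static double eval_logL(double lambda, int n, const double* d,
                        const double* uy, const double* uw, const double* ux,
                        double* beta_out, double* se_out) {
  double sldet = 0, sww = 0, swy = 0, syy = 0, swx = 0, sxy = 0, sxx = 0;
  for (int i = 0; i < n; i++) {
    double h = lambda * d[i] + 1.0;
    sldet += std::log(h);
    double v = 1.0 / h;
    double w = uw[i], y = uy[i];
    sww += v * w * w; swy += v * w * y; syy += v * y * y;
    if (ux) {
      double x = ux[i];
      swx += v * w * x; sxy += v * x * y; sxx += v * x * x;
    }
  }
  double rss;
  if (ux) {
    double det = sww * sxx - swx * swx;
    if (!(det > 1e-12 * std::max(1.0, sww * sxx))) return NA_REAL;
    double a = (sxx * swy - swx * sxy) / det;
    double b = (sww * sxy - swx * swy) / det;
    rss = syy - a * swy - b * sxy;
    if (beta_out) {
      if (rss < 1e-300) rss = 1e-300;
      *beta_out = b;
      *se_out = std::sqrt((sww / det) * rss / n);
    }
  } else {
    rss = syy - swy * swy / sww;
  }
  if (rss < 1e-300) rss = 1e-300;
  return -0.5 * n * std::log(2.0 * M_PI) - 0.5 * sldet
         - 0.5 * n * std::log(rss / n) - 0.5 * n;
}

struct OptResult { double log10_lambda; double logL; };

// Golden-section maximization of the profile logL over log10(lambda).
static double golden(double lo, double hi, int n, const double* d,
                     const double* uy, const double* uw, const double* ux,
                     double* best_f) {
  const double gr = 0.61803398874989484821;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = eval_logL(std::pow(10.0, c1), n, d, uy, uw, ux, 0, 0);
  double f2 = eval_logL(std::pow(10.0, c2), n, d, uy, uw, ux, 0, 0);
  for (int it = 0; it < 60 && (b - a) > 1e-7; it++) {
    if (f1 >= f2) { b = c2; c2 = c1; f2 = f1;
      c1 = b - gr * (b - a);
      f1 = eval_logL(std::pow(10.0, c1), n, d, uy, uw, ux, 0, 0);
    } else { a = c1; c1 = c2; f1 = f2;
      c2 = a + gr * (b - a);
      f2 = eval_logL(std::pow(10.0, c2), n, d, uy, uw, ux, 0, 0);
    }
  }
  double t = (f1 >= f2) ? c1 : c2;  // ties toward smaller lambda
  *best_f = (f1 >= f2) ? f1 : f2;
  return t;
}

// Multi-start optimum: refine around every local maximum of a coarse grid.
static OptResult optimize_lambda(int n, const double* d, const double* uy,
                                 const double* uw, const double* ux) {
  const int ng = 41;  // step 0.25 over [-5, 5]
  double fs[ng];
  for (int k = 0; k < ng; k++) {
    double t = LOG10_LO + k * (LOG10_HI - LOG10_LO) / (ng - 1);
    fs[k] = eval_logL(std::pow(10.0, t), n, d, uy, uw, ux, 0, 0);
    if (ISNAN(fs[k])) { OptResult r = {NA_REAL, NA_REAL}; return r; }
  }
  OptResult best = {NA_REAL, -HUGE_VAL};
  double step = (LOG10_HI - LOG10_LO) / (ng - 1);
  for (int k = 0; k < ng; k++) {
    bool is_local = (k == 0 || fs[k] >= fs[k - 1]) &&
                    (k == ng - 1 || fs[k] >= fs[k + 1]);
    if (!is_local) continue;
    double lo = std::max(LOG10_LO, LOG10_LO + (k - 1) * step);
    double hi = std::min(LOG10_HI, LOG10_LO + (k + 1) * step);
    double f, t = golden(lo, hi, n, d, uy, uw, ux, &f);
    if (f > best.logL + 1e-12 ||
        (std::fabs(f - best.logL) <= 1e-12 && t < best.log10_lambda)) {
      best.logL = f; best.log10_lambda = t;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_lmm_null(NumericVector d, NumericVector uy,
                           NumericVector uw) {
  int n = d.size();
  OptResult r = optimize_lambda(n, d.begin(), uy.begin(), uw.begin(), 0);
  double lambda = std::pow(10.0, r.log10_lambda);
  double logL = eval_logL(lambda, n, d.begin(), uy.begin(), uw.begin(),
                          0, 0, 0);
  return NumericVector::create(_["lambda"] = lambda, _["logL"] = logL);
}

// [[Rcpp::export]]
NumericMatrix cpp_lmm_scan(NumericVector d, NumericVector uy,
                           NumericVector uw, NumericMatrix UX) {
  int n = d.size(), m = UX.ncol();
  NumericMatrix out(m, 4);
  colnames(out) = CharacterVector::create("beta", "se_beta", "lambda", "logL");
  for (int j = 0; j < m; j++) {
    const double* ux = &UX(0, j);
    OptResult r = optimize_lambda(n, d.begin(), uy.begin(), uw.begin(), ux);
    if (ISNAN(r.log10_lambda)) {
      out(j, 0) = NA_REAL; out(j, 1) = NA_REAL;
      out(j, 2) = NA_REAL; out(j, 3) = NA_REAL;
      continue;
    }
    double lambda = std::pow(10.0, r.log10_lambda);
    double beta = NA_REAL, se = NA_REAL;
    double logL = eval_logL(lambda, n, d.begin(), uy.begin(), uw.begin(),
                            ux, &beta, &se);
    out(j, 0) = beta; out(j, 1) = se; out(j, 2) = lambda; out(j, 3) = logL;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_profile_logL(double lambda, NumericVector d, NumericVector uy,
                        NumericVector uw, Nullable<NumericVector> ux) {
  int n = d.size();
  if (ux.isNotNull()) {
    NumericVector x(ux);
    return eval_logL(lambda, n, d.begin(), uy.begin(), uw.begin(),
                     x.begin(), 0, 0);
  }
  return eval_logL(lambda, n, d.begin(), uy.begin(), uw.begin(), 0, 0, 0);
}
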