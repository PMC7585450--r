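// Self-consistency residuals for the reduced mean-field systems and the
// root-counting loops behind phase diagrams and the bistability-onset search.
//
// Conventions: rule 0 = collective, 1 = individual; wiring 0 = degree-
// correlated, 1 = uncorrelated; sgn +1 = triangle contagion, -1 = triangle
// healing.  The per-class equilibrium is x_k = n_k/(gamma + n_k) for net
// infection pressure n_k > 0 and x_k = 0 otherwise (boundary equilibrium of
// the clamped per-class dynamics; relevant only when the triangle term heals).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double xk_of(double n, double gamma) {
  return (n > 0.0) ? n / (gamma + n) : 0.0;
}

// degree-correlated case: dynamics closed in V alone
static double h_corr(double V, const double* k, const double* p, int nk,
                     double M1, double gamma, double beta2, double beta3,
                     int rule, int sgn) {
  double s2 = (rule == 0)
    ? beta2 * V + sgn * beta3 * V * V
    : (beta2 + 2.0 * sgn * beta3) * V - sgn * beta3 * V * V;
  double acc = 0.0;
  for (int i = 0; i < nk; ++i)
    acc += p[i] * k[i] * xk_of(k[i] * s2, gamma);
  return acc / M1 - V;
}

static double U_corr(double V, const double* k, const double* p, int nk,
                     double gamma, double beta2, double beta3,
                     int rule, int sgn) {
  double s2 = (rule == 0)
    ? beta2 * V + sgn * beta3 * V * V
    : (beta2 + 2.0 * sgn * beta3) * V - sgn * beta3 * V * V;
  double acc = 0.0;
  for (int i = 0; i < nk; ++i)
    acc += p[i] * xk_of(k[i] * s2, gamma);
  return acc;
}

// uncorrelated case: eliminate U at fixed V by fixed-point iteration,
// warm-started from the caller-supplied U.  Returns the V-residual and
// updates U in place; NaN on non-convergence.
static double h_unc(double V, double& U, const double* k, const double* p,
                    int nk, double M1, double gamma, double beta2,
                    double beta3, int rule, int sgn) {
  const double tol = 1e-13;
  double omega = 1.0;
  int it = 0, max_it = 400;
  for (int round = 0; round < 3; ++round) {
    for (; it < max_it; ++it) {
      double c = (rule == 0)
        ? sgn * beta3 * M1 * U * U
        : sgn * beta3 * M1 * (2.0 * U - U * U);
      double Un = 0.0;
      for (int i = 0; i < nk; ++i)
        Un += p[i] * xk_of(beta2 * k[i] * V + c, gamma);
      double Unew = (1.0 - omega) * U + omega * Un;
      double d = std::fabs(Unew - U);
      U = Unew;
      if (d < tol) {
        double c2 = (rule == 0)
          ? sgn * beta3 * M1 * U * U
          : sgn * beta3 * M1 * (2.0 * U - U * U);
        double acc = 0.0;
        for (int i = 0; i < nk; ++i)
          acc += p[i] * k[i] * xk_of(beta2 * k[i] * V + c2, gamma);
        return acc / M1 - V;
      }
    }
    omega *= 0.4;          // damp and retry if plain iteration cycles
    max_it += 2000;
  }
  return R_NaReal;
}

static double h_any(double V, double& U, const double* k, const double* p,
                    int nk, double M1, double gamma, double beta2,
                    double beta3, int rule, int wiring, int sgn) {
  if (wiring == 0) {
    double h = h_corr(V, k, p, nk, M1, gamma, beta2, beta3, rule, sgn);
    U = U_corr(V, k, p, nk, gamma, beta2, beta3, rule, sgn);
    return h;
  }
  return h_unc(V, U, k, p, nk, M1, gamma, beta2, beta3, rule, sgn);
}

// [[Rcpp::export]]
List cpp_residual_curve(NumericVector V, NumericVector k, NumericVector p,
                        double gamma, double beta2, double beta3,
                        int rule, int wiring, int sgn) {
  int nV = V.size(), nk = k.size();
  double M1 = 0.0;
  for (int i = 0; i < nk; ++i) M1 += p[i] * k[i];
  NumericVector h(nV), U(nV);
  double Uw = 0.0;
  for (int j = 0; j < nV; ++j) {
    h[j] = h_any(V[j], Uw, k.begin(), p.begin(), nk, M1, gamma, beta2, beta3,
                 rule, wiring, sgn);
    U[j] = Uw;
  }
  return List::create(_["h"] = h, _["U"] = U);
}

// count sign changes of h over the grid; total root count = 1 (V = 0) + that
static int count_on_grid(const double* V, int nV, const double* k,
                         const double* p, int nk, double M1, double gamma,
                         double beta2, double beta3, int rule, int wiring,
                         int sgn) {
  int count = 0, last_sign = 0;
  double Uw = 0.0;
  for (int j = 0; j < nV; ++j) {
    double h = h_any(V[j], Uw, k, p, nk, M1, gamma, beta2, beta3,
                     rule, wiring, sgn);
    if (ISNAN(h)) { last_sign = 0; continue; }
    int s = (h > 0.0) - (h < 0.0);
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) ++count;
      last_sign = s;
    }
  }
  return 1 + count;
}

// [[Rcpp::export]]
IntegerVector cpp_count_roots_grid(NumericVector beta2s, NumericVector beta3s,
                                   NumericVector V, NumericVector k,
                                   NumericVector p, double gamma,
                                   int rule, int wiring, int sgn) {
  int n = beta2s.size(), nk = k.size();
  double M1 = 0.0;
  for (int i = 0; i < nk; ++i) M1 += p[i] * k[i];
  IntegerVector out(n);
  for (int q = 0; q < n; ++q) {
    out[q] = count_on_grid(V.begin(), V.size(), k.begin(), p.begin(), nk, M1,
                           gamma, beta2s[q], beta3s[q], rule, wiring, sgn);
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// bisection polish of a bracketed sign change; returns root, U there, and a
// central-difference slope of the residual
// [[Rcpp::export]]
List cpp_polish_root(double lo, double hi, double U0, NumericVector k,
                     NumericVector p, double gamma, double beta2, double beta3,
                     int rule, int wiring, int sgn, double tol) {
  int nk = k.size();
  double M1 = 0.0;
  for (int i = 0; i < nk; ++i) M1 += p[i] * k[i];
  double Uw = U0;
  double hlo = h_any(lo, Uw, k.begin(), p.begin(), nk, M1, gamma, beta2, beta3,
                     rule, wiring, sgn);
  for (int it = 0; it < 200 && (hi - lo) > tol; ++it) {
    double mid = 0.5 * (lo + hi);
    double hm = h_any(mid, Uw, k.begin(), p.begin(), nk, M1, gamma, beta2,
                      beta3, rule, wiring, sgn);
    if (ISNAN(hm)) break;
    if ((hm > 0) == (hlo > 0)) { lo = mid; hlo = hm; } else hi = mid;
  }
  double V = 0.5 * (lo + hi);
  double h = h_any(V, Uw, k.begin(), p.begin(), nk, M1, gamma, beta2, beta3,
                   rule, wiring, sgn);
  double eps = std::max(1e-9, 1e-6 * V);
  double Ua = Uw, Ub = Uw;
  double hp = h_any(V + eps, Ua, k.begin(), p.begin(), nk, M1, gamma, beta2,
                    beta3, rule, wiring, sgn);
  double hm2 = h_any(std::max(0.0, V - eps), Ub, k.begin(), p.begin(), nk, M1,
                     gamma, beta2, beta3, rule, wiring, sgn);
  double slope = (hp - hm2) / (V + eps - std::max(0.0, V - eps));
  return List::create(_["V"] = V, _["U"] = Uw, _["h"] = h,
                      _["slope"] = slope);
}
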