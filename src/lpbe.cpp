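// Red-black SOR kernel for the finite-difference linearized
// Poisson-Boltzmann equation on a uniform grid.
//
// Node equation (volume-integrated over a cell of side h):
//   sum_f eps_f (u_f - u_0) - kbar_0 h^2 u_0 + src_0 = 0
// with eps_f the harmonic mean of node dielectrics across each of the six
// faces, kbar = eps_ext * kappa^2 * ion_accessibility, and
// src = 4 pi C q_node / h (charge trilinearly spread to nodes).
// Boundary nodes hold Dirichlet values and are never updated.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double harm(double a, double b) {
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
List sor_lpbe_cpp(NumericVector eps, NumericVector kbar, NumericVector src,
                  NumericVector u0, double h, double omega, double tol,
                  int max_iter, int check_every) {
  IntegerVector dims = eps.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (u0.size() != n || kbar.size() != n || src.size() != n)
    stop("array size mismatch");

  std::vector<double> u(u0.begin(), u0.end());
  const double *e = eps.begin();
  const double *k2 = kbar.begin();
  const double *b = src.begin();
  const double h2 = h * h;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // relative-residual denominator: source norm, falling back to the
  // boundary-value norm for charge-free problems
  double bnorm2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) bnorm2 += b[i] * b[i];
  double denom = std::sqrt(bnorm2);
  if (denom == 0.0) {
    double bc2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) bc2 += u0[i] * u0[i];
    denom = std::sqrt(bc2);
  }
  if (denom == 0.0) denom = 1.0;  // homogeneous problem: u stays 0

  double res = R_PosInf;
  int iter = 0;
  bool converged = false, diverged = false;
  std::vector<double> trace;
  double prev_res = R_PosInf;
  int grow = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((k + j + 1 + colour) & 1);
          R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
          for (int i = istart; i < nx - 1; i += 2) {
            R_xlen_t p = base + i;
            double exm = harm(e[p], e[p - sx]), exp_ = harm(e[p], e[p + sx]);
            double eym = harm(e[p], e[p - sy]), eyp = harm(e[p], e[p + sy]);
            double ezm = harm(e[p], e[p - sz]), ezp = harm(e[p], e[p + sz]);
            double S = exm * u[p - sx] + exp_ * u[p + sx] +
                       eym * u[p - sy] + eyp * u[p + sy] +
                       ezm * u[p - sz] + ezp * u[p + sz];
            double diag = exm + exp_ + eym + eyp + ezm + ezp + k2[p] * h2;
            double unew = (S + b[p]) / diag;
            u[p] += omega * (unew - u[p]);
          }
        }
      }
    }

    if (iter % check_every == 0 || iter == max_iter) {
      double r2 = 0.0;
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t p = base + i;
            double exm = harm(e[p], e[p - sx]), exp_ = harm(e[p], e[p + sx]);
            double eym = harm(e[p], e[p - sy]), eyp = harm(e[p], e[p + sy]);
            double ezm = harm(e[p], e[p - sz]), ezp = harm(e[p], e[p + sz]);
            double S = exm * u[p - sx] + exp_ * u[p + sx] +
                       eym * u[p - sy] + eyp * u[p + sy] +
                       ezm * u[p - sz] + ezp * u[p + sz];
            double diag = exm + exp_ + eym + eyp + ezm + ezp + k2[p] * h2;
            double r = S + b[p] - diag * u[p];
            r2 += r * r;
          }
        }
      }
      res = std::sqrt(r2) / denom;
      trace.push_back(res);
      if (!std::isfinite(res)) { diverged = true; break; }
      if (res <= tol) { converged = true; break; }
      if (res > prev_res * 1.0000001) {
        if (++grow >= 5) { diverged = true; break; }
      } else {
        grow = 0;
      }
      prev_res = res;
    }
  }
  if (iter > max_iter) iter = max_iter;

  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return List::create(_["u"] = out, _["iterations"] = iter,
                      _["residual"] = res, _["converged"] = converged,
                      _["diverged"] = diverged,
                      _["residual_trace"] = NumericVector(trace.begin(), trace.end()));
}
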