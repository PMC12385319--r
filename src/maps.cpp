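#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled identical logistic maps:
//   x[t+1] = (1-eps) f(x[t]) + eps f(y[t]),  f(z) = r z (1-z)
// with the symmetric equation for y. States must stay in [0,1]; a small
// tolerance absorbs rounding at the r = 4 boundary.
// [[Rcpp::export]]
List cpp_logistic_pair(double r, double eps, double x0, double y0,
                       int n, int transient) {
  NumericVector x(n), y(n);
  double xx = x0, yy = y0;
  const double tol = 1e-12;
  for (int t = 0; t < transient + n; ++t) {
    double fx = r * xx * (1.0 - xx);
    double fy = r * yy * (1.0 - yy);
    double nx = (1.0 - eps) * fx + eps * fy;
    double ny = (1.0 - eps) * fy + eps * fx;
    if (nx < -tol || nx > 1.0 + tol || ny < -tol || ny > 1.0 + tol ||
        !std::isfinite(nx) || !std::isfinite(ny))
      stop("logistic map state left [0,1] at iteration %d (r = %g may be invalid)",
           t + 1, r);
    xx = nx; yy = ny;
    if (t >= transient) { x[t - transient] = xx; y[t - transient] = yy; }
  }
  return List::create(_["x"] = x, _["y"] = y);
}

// Henon map: x[t+1] = 1 - a x[t]^2 + y[t], y[t+1] = b x[t].
// [[Rcpp::export]]
List cpp_henon_pair(double a, double b, double x0, double y0,
                    int n, int transient) {
  NumericVector x(n), y(n);
  double xx = x0, yy = y0;
  for (int t = 0; t < transient + n; ++t) {
    double nx = 1.0 - a * xx * xx + yy;
    double ny = b * xx;
    if (!std::isfinite(nx) || std::fabs(nx) > 1e6)
      stop("Henon trajectory diverged at iteration %d (|x| > 1e6)", t + 1);
    xx = nx; yy = ny;
    if (t >= transient) { x[t - transient] = xx; y[t - transient] = yy; }
  }
  return List::create(_["x"] = x, _["y"] = y);
}

// Benettin iteration: propagate a unit tangent vector through the analytic
// 2x2 Jacobian, renormalising every step; the MLE is the mean log growth
// (natural log, per iteration).
static double benettin(int map, double p1, double p2,
                       double x0, double y0, int n, int transient) {
  double xx = x0, yy = y0;
  double v1 = M_SQRT1_2, v2 = M_SQRT1_2;
  double sum = 0.0;
  for (int t = 0; t < transient + n; ++t) {
    double w1, w2, nx, ny;
    if (map == 0) { // coupled logistic, p1 = r, p2 = eps
      double fpx = p1 * (1.0 - 2.0 * xx);
      double fpy = p1 * (1.0 - 2.0 * yy);
      w1 = (1.0 - p2) * fpx * v1 + p2 * fpy * v2;
      w2 = p2 * fpx * v1 + (1.0 - p2) * fpy * v2;
      double fx = p1 * xx * (1.0 - xx);
      double fy = p1 * yy * (1.0 - yy);
      nx = (1.0 - p2) * fx + p2 * fy;
      ny = (1.0 - p2) * fy + p2 * fx;
    } else {        // Henon, p1 = a, p2 = b
      w1 = -2.0 * p1 * xx * v1 + v2;
      w2 = p2 * v1;
      nx = 1.0 - p1 * xx * xx + yy;
      ny = p2 * xx;
    }
    double nrm = std::sqrt(w1 * w1 + w2 * w2);
    if (nrm <= 0.0 || !std::isfinite(nrm))
      stop("tangent vector degenerated at iteration %d", t + 1);
    v1 = w1 / nrm; v2 = w2 / nrm;
    xx = nx; yy = ny;
    if (!std::isfinite(xx) || std::fabs(xx) > 1e6)
      stop("trajectory diverged at iteration %d", t + 1);
    if (t >= transient) sum += std::log(nrm);
  }
  return sum / n;
}

// [[Rcpp::export]]
double cpp_benettin_logistic(double r, double eps, double x0, double y0,
                             int n, int transient) {
  return benettin(0, r, eps, x0, y0, n, transient);
}

// [[Rcpp::export]]
double cpp_benettin_henon(double a, double b, double x0, double y0,
                          int n, int transient) {
  return benettin(1, a, b, x0, y0, n, transient);
}
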