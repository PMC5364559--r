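#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gram matrix between rows of X and rows of Z for the four kernels.
// kind: 0 linear, 1 polynomial, 2 rbf, 3 sigmoid.
// linear:     x'z
// polynomial: (gamma * x'z + coef0)^degree
// rbf:        exp(-gamma * ||x - z||^2)
// sigmoid:    tanh(gamma * x'z + coef0)
// [[Rcpp::export]]
NumericMatrix kernel_matrix_cpp(const NumericMatrix& X, const NumericMatrix& Z,
                                int kind, double gamma, double coef0,
                                int degree) {
  const int n = X.nrow(), m = Z.nrow(), d = X.ncol();
  if (Z.ncol() != d) stop("feature dimension mismatch");
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      if (kind == 2) {
        for (int t = 0; t < d; ++t) {
          const double diff = X(i, t) - Z(j, t);
          acc += diff * diff;
        }
        K(i, j) = std::exp(-gamma * acc);
      } else {
        for (int t = 0; t < d; ++t) acc += X(i, t) * Z(j, t);
        if (kind == 0) K(i, j) = acc;
        else if (kind == 1) K(i, j) = std::pow(gamma * acc + coef0, degree);
        else K(i, j) = std::tanh(gamma * acc + coef0);
      }
    }
  }
  return K;
}

// Sequential minimal optimization (Platt 1998) on a precomputed Gram matrix.
// Maximizes sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
// s.t. 0 <= alpha_i <= C, sum(alpha_i y_i) = 0.
// Deterministic: no random second-choice fallback, fixed scan order.
namespace {

struct SmoState {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol, eps;
  int n;
  std::vector<double> alpha;
  std::vector<double> E;  // E_i = u_i - y_i with u_i = sum_j a_j y_j K_ij - b
  double b;

  SmoState(const NumericMatrix& K_, const NumericVector& y_, double C_,
           double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), eps(1e-12), n(K_.nrow()),
        alpha(n, 0.0), E(n), b(0.0) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // all-zero alpha, b = 0
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1o = alpha[i1], a2o = alpha[i2];
    const double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    const double E1 = E[i1], E2 = E[i2];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2o - a1o);
      H = std::min(C, C + a2o - a1o);
    } else {
      L = std::max(0.0, a1o + a2o - C);
      H = std::min(C, a1o + a2o);
    }
    if (L >= H) return false;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    if (eta <= 1e-12) return false;  // non-positive curvature: skip pair
    double a2 = a2o + y2 * (E1 - E2) / eta;
    if (a2 < L) a2 = L; else if (a2 > H) a2 = H;
    if (std::fabs(a2 - a2o) < eps * (a2 + a2o + eps)) return false;
    double a1 = a1o + s * (a2o - a2);
    if (a1 < 1e-10) a1 = 0.0; else if (a1 > C - 1e-10) a1 = C;
    if (a2 < 1e-10) a2 = 0.0; else if (a2 > C - 1e-10) a2 = C;

    const double d1 = a1 - a1o, d2 = a2 - a2o;
    const double b1 = E1 + y1 * d1 * k11 + y2 * d2 * k12 + b;
    const double b2 = E2 + y1 * d1 * k12 + y2 * d2 * k22 + b;
    double bnew;
    const bool f1 = a1 > 0.0 && a1 < C, f2 = a2 > 0.0 && a2 < C;
    if (f1) bnew = b1; else if (f2) bnew = b2; else bnew = 0.5 * (b1 + b2);
    const double db = bnew - b;
    b = bnew;
    alpha[i1] = a1;
    alpha[i2] = a2;
    for (int i = 0; i < n; ++i)
      E[i] += y1 * d1 * K(i1, i) + y2 * d2 * K(i2, i) - db;
    return true;
  }

  bool examine(int i2) {
    const double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    const double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0))) return false;
    // heuristic 1: maximal |E1 - E2| over free multipliers
    int best = -1;
    double gap = -1.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] > 0.0 && alpha[i] < C) {
        const double g = std::fabs(E[i] - E2);
        if (g > gap) { gap = g; best = i; }
      }
    }
    if (best >= 0 && takeStep(best, i2)) return true;
    // heuristic 2: sweep free multipliers from a deterministic offset
    for (int k = 0; k < n; ++k) {
      const int i = (i2 + 1 + k) % n;
      if (alpha[i] > 0.0 && alpha[i] < C && takeStep(i, i2)) return true;
    }
    // fall back: sweep everything
    for (int k = 0; k < n; ++k) {
      const int i = (i2 + 1 + k) % n;
      if (takeStep(i, i2)) return true;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export]]
List smo_train_cpp(const NumericMatrix& K, const NumericVector& y, double C,
                   double tol, int max_sweeps) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("inconsistent problem dimensions");
  SmoState st(K, y, C, tol);
  bool examineAll = true;
  int changed = 0, sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    ++sweeps;
    changed = 0;
    for (int i = 0; i < n; ++i) {
      if (examineAll || (st.alpha[i] > 0.0 && st.alpha[i] < C))
        if (st.examine(i)) ++changed;
    }
    if (examineAll) {
      if (changed == 0) { converged = true; break; }
      examineAll = false;
    } else if (changed == 0) {
      examineAll = true;
    }
  }
  // Intercept rho so that f(x) = sum_i a_i y_i K(x, x_i) + rho. With free
  // support vectors, KKT equality gives rho = mean(y_i - g_i) over them;
  // otherwise rho is the midpoint of the feasible KKT interval
  // [max lower bound, min upper bound] implied by the bound multipliers.
  double rho;
  int nfree = 0;
  double acc = 0.0;
  double lo = -std::numeric_limits<double>::infinity();
  double hi = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int j = 0; j < n; ++j) g += st.alpha[j] * y[j] * K(i, j);
    const double a = st.alpha[i];
    if (a > 0.0 && a < C) {
      acc += y[i] - g;
      ++nfree;
    } else if (y[i] > 0) {
      if (a <= 0.0) lo = std::max(lo, 1.0 - g);   // needs g + rho >= 1
      else          hi = std::min(hi, 1.0 - g);   // a = C: g + rho <= 1
    } else {
      if (a <= 0.0) hi = std::min(hi, -1.0 - g);  // needs g + rho <= -1
      else          lo = std::max(lo, -1.0 - g);  // a = C: g + rho >= -1
    }
  }
  if (nfree > 0) {
    rho = acc / nfree;
  } else if (std::isfinite(lo) && std::isfinite(hi)) {
    rho = 0.5 * (lo + hi);
  } else if (std::isfinite(lo)) {
    rho = lo;
  } else if (std::isfinite(hi)) {
    rho = hi;
  } else {
    rho = -st.b;
  }
  return List::create(_["alpha"] = NumericVector(st.alpha.begin(), st.alpha.end()),
                      _["rho"] = rho, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
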