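// Block coordinate descent for the joint two-condition node regression
// with knowledge-weighted lasso and fusion penalties.
//
// All matrices arriving here are the internally scaled design matrices
// (standardized columns times sqrt(2/N_c)); see R/solver.R for the scaling
// convention that ties the penalty level to the false-join closed form.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static inline double gval(double b1, double b2, double c1, double c2,
                          double a1, double a2, double w, double l2) {
  return 0.5 * a1 * b1 * b1 - c1 * b1 + 0.5 * a2 * b2 * b2 - c2 * b2 +
         w * (std::fabs(b1) + std::fabs(b2)) + l2 * std::fabs(b1 - b2);
}

// Exact minimizer of the two-coordinate subproblem
//   g(b1,b2) = a1 b1^2/2 - c1 b1 + a2 b2^2/2 - c2 b2
//              + w (|b1| + |b2|) + l2 |b1 - b2|.
// Convex case analysis: either the fused candidate b1 = b2 (combined
// penalty 2w) or a sign pattern of (b1 - b2), under which the fusion term
// is linear and each coordinate soft-thresholds at w with the +-l2 tilt.
// Ties within 1e-12 prefer the fused candidate (conservative for
// differential calls).
static inline void pair_update_impl(double c1, double c2, double a1, double a2,
                                    double w, double l2,
                                    double &b1, double &b2) {
  double bf = soft(c1 + c2, 2.0 * w) / (a1 + a2);
  double gbest = gval(bf, bf, c1, c2, a1, a2, w, l2);
  b1 = bf;
  b2 = bf;

  double u1 = soft(c1 - l2, w) / a1;
  double u2 = soft(c2 + l2, w) / a2;
  if (u1 > u2) {
    double g = gval(u1, u2, c1, c2, a1, a2, w, l2);
    if (g < gbest - 1e-12) { gbest = g; b1 = u1; b2 = u2; }
  }

  double v1 = soft(c1 + l2, w) / a1;
  double v2 = soft(c2 - l2, w) / a2;
  if (v1 < v2) {
    double g = gval(v1, v2, c1, c2, a1, a2, w, l2);
    if (g < gbest - 1e-12) { b1 = v1; b2 = v2; }
  }
}

// [[Rcpp::export]]
NumericVector pair_update_cpp(double c1, double c2, double a1, double a2,
                              double w, double lambda2) {
  if (a1 <= 0.0 || a2 <= 0.0) stop("a1 and a2 must be positive");
  if (w < 0.0 || lambda2 < 0.0) stop("penalties must be non-negative");
  double b1, b2;
  pair_update_impl(c1, c2, a1, a2, w, lambda2, b1, b2);
  return NumericVector::create(b1, b2);
}

struct NodeResult {
  int iters;
  double last_delta;
  bool converged;
};

// One node's block coordinate descent. b1/b2 are modified in place.
static NodeResult bcd_node_impl(const arma::mat &X1, const arma::mat &X2,
                                const arma::vec &a1, const arma::vec &a2,
                                int i, const arma::vec &w, double lambda2,
                                double tol, int max_iter,
                                arma::vec &b1, arma::vec &b2,
                                std::vector<double> *obj_trace) {
  const int p = X1.n_cols;
  arma::vec y1 = X1.col(i), y2 = X2.col(i);
  arma::vec r1 = y1 - X1 * b1;
  arma::vec r2 = y2 - X2 * b2;

  NodeResult res;
  res.iters = 0;
  res.last_delta = R_PosInf;
  res.converged = false;

  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (j == i) continue;
      double old1 = b1(j), old2 = b2(j);
      double c1 = arma::dot(X1.col(j), r1) + a1(j) * old1;
      double c2 = arma::dot(X2.col(j), r2) + a2(j) * old2;
      double n1, n2;
      pair_update_impl(c1, c2, a1(j), a2(j), w(j), lambda2, n1, n2);
      if (n1 != old1) { r1 += X1.col(j) * (old1 - n1); b1(j) = n1; }
      if (n2 != old2) { r2 += X2.col(j) * (old2 - n2); b2(j) = n2; }
      double d = std::max(std::fabs(n1 - old1), std::fabs(n2 - old2));
      if (d > delta) delta = d;
    }
    res.iters = it + 1;
    res.last_delta = delta;
    if (obj_trace) {
      double pen = 0.0;
      for (int j = 0; j < p; ++j) {
        pen += w(j) * (std::fabs(b1(j)) + std::fabs(b2(j))) +
               lambda2 * std::fabs(b1(j) - b2(j));
      }
      obj_trace->push_back(0.5 * (arma::dot(r1, r1) + arma::dot(r2, r2)) + pen);
    }
    if (delta < tol) { res.converged = true; break; }
  }
  return res;
}

// [[Rcpp::export]]
List bcd_node_cpp(const arma::mat &X1, const arma::mat &X2, int i1,
                  const arma::vec &w, double lambda2, double tol,
                  int max_iter, bool trace,
                  arma::vec b1_init, arma::vec b2_init) {
  const int p = X1.n_cols;
  if ((int)X2.n_cols != p) stop("condition matrices must share columns");
  if ((int)w.n_elem != p) stop("penalty weight vector has wrong length");
  if (i1 < 1 || i1 > p) stop("node index out of range");
  arma::vec a1(p), a2(p);
  for (int j = 0; j < p; ++j) {
    a1(j) = arma::dot(X1.col(j), X1.col(j));
    a2(j) = arma::dot(X2.col(j), X2.col(j));
  }
  arma::vec b1 = b1_init, b2 = b2_init;
  b1(i1 - 1) = 0.0;
  b2(i1 - 1) = 0.0;
  std::vector<double> tr;
  NodeResult res = bcd_node_impl(X1, X2, a1, a2, i1 - 1, w, lambda2, tol,
                                 max_iter, b1, b2, trace ? &tr : nullptr);
  return List::create(
      _["beta1"] = b1, _["beta2"] = b2, _["iters"] = res.iters,
      _["last_delta"] = res.last_delta, _["converged"] = res.converged,
      _["objective_trace"] = tr);
}

// Whole-network fit: node problems are independent; loop them here to keep
// calibration sweeps (thousands of refits) out of interpreted code.
// W is the p x p 0/1 prior adjacency; penalty weight for coordinate j in
// node i's problem is lambda1 * (1 - W(j,i) * theta).
// [[Rcpp::export]]
List fit_network_cpp(const arma::mat &X1, const arma::mat &X2,
                     const arma::mat &W, double lambda1, double theta,
                     double lambda2, double tol, int max_iter) {
  const int p = X1.n_cols;
  if ((int)X2.n_cols != p) stop("condition matrices must share columns");
  if ((int)W.n_rows != p || (int)W.n_cols != p) stop("prior has wrong dimension");
  arma::vec a1(p), a2(p);
  for (int j = 0; j < p; ++j) {
    a1(j) = arma::dot(X1.col(j), X1.col(j));
    a2(j) = arma::dot(X2.col(j), X2.col(j));
  }
  arma::mat B1(p, p, arma::fill::zeros), B2(p, p, arma::fill::zeros);
  IntegerVector iters(p);
  LogicalVector converged(p);
  NumericVector last_delta(p);
  for (int i = 0; i < p; ++i) {
    arma::vec w(p);
    for (int j = 0; j < p; ++j) w(j) = lambda1 * (1.0 - W(j, i) * theta);
    arma::vec b1(p, arma::fill::zeros), b2(p, arma::fill::zeros);
    NodeResult res = bcd_node_impl(X1, X2, a1, a2, i, w, lambda2, tol,
                                   max_iter, b1, b2, nullptr);
    B1.col(i) = b1;
    B2.col(i) = b2;
    iters[i] = res.iters;
    converged[i] = res.converged;
    last_delta[i] = res.last_delta;
  }
  return List::create(_["B1"] = B1, _["B2"] = B2, _["iters"] = iters,
                      _["converged"] = converged, _["last_delta"] = last_delta);
}
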