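// Alternating convex search cores for the decomposed (PDSMCCA) and plain
// (SMCCA) sparse multi-view CCA models. Both operate purely on precomputed
// cross-product matrices: slice k*K + j of `CP` holds X_k' X_j (so slice
// k*K + k is the k-th Gram matrix). Everything the loop needs — right-hand
// sides, constraint norms, the objective — is a function of these, which is
// what makes the nested-CV grid affordable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// solve (diag(d) + (K-1) * G) x = rhs by SPD factorization, with a small
// diagonal jitter retry; explicit inversion is never formed
static bool ridge_solve(const mat& G, const vec& d, double km1,
                        const vec& rhs, vec& out) {
  mat M = km1 * G;
  M.diag() += d;
  if (solve(out, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx))
    return true;
  M.diag() += 1e-10;
  return solve(out, M, rhs, solve_opts::no_approx);
}

static double pd_loss(const cube& CP, int K, const mat& W) {
  double loss = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int j = k + 1; j < K; ++j) {
      double t = dot(W.col(k), CP.slice(k * K + k) * W.col(k))
               - 2.0 * dot(W.col(k), CP.slice(k * K + j) * W.col(j))
               + dot(W.col(j), CP.slice(j * K + j) * W.col(j));
      loss += 0.5 * t;
    }
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List pdsmcca_core_cpp(const arma::cube& CP, int K,
                            double lambda_B, double lambda_S,
                            double tol, int max_iter, double eps,
                            const arma::mat& B0, const arma::mat& S0) {
  const int p = CP.n_rows;
  mat B = B0, S = S0;
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false, degenerate = false, nonfinite = false;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    mat Wold = B + S;
    for (int k = 0; k < K; ++k) {
      vec rhs(p, fill::zeros);
      for (int j = 0; j < K; ++j) {
        if (j == k) continue;
        rhs += CP.slice(k * K + j) * (B.col(j) + S.col(j));
      }
      // modality-specific update: reweighted l1 (diagonal 1/|b_i|)
      vec db = lambda_B / (abs(B.col(k)) + eps);
      vec bnew;
      if (!ridge_solve(CP.slice(k * K + k), db, K - 1.0, rhs, bnew)) {
        degenerate = true; break;
      }
      B.col(k) = bnew;
      // modality-shared update: reweighted l2,1 (diagonal 1/||s^i||_2,
      // row norms over the full current S, refreshed Gauss-Seidel style)
      vec ds = lambda_S / (sqrt(sum(square(S), 1)) + eps);
      vec snew;
      if (!ridge_solve(CP.slice(k * K + k), ds, K - 1.0, rhs, snew)) {
        degenerate = true; break;
      }
      S.col(k) = snew;
      // rescale so the variate-norm constraint ||X_k (b_k + s_k)|| = 1
      // holds exactly (both components share the scalar divisor)
      vec w = B.col(k) + S.col(k);
      double c2 = dot(w, CP.slice(k * K + k) * w);
      double scale = std::max(1.0, norm(rhs, 2));
      if (!std::isfinite(c2) || std::sqrt(std::max(c2, 0.0)) < 1e-10 * scale) {
        degenerate = true; break;
      }
      double c = std::sqrt(c2);
      B.col(k) /= c;
      S.col(k) /= c;
    }
    if (degenerate) break;
    double obj = pd_loss(CP, K, B + S)
               + lambda_B * accu(abs(B))
               + lambda_S * accu(sqrt(sum(square(S), 1)));
    if (!std::isfinite(obj)) { nonfinite = true; break; }
    trace.push_back(obj);
    double delta = abs((B + S) - Wold).max();
    if (delta <= tol) { converged = true; ++it; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("B") = B, Rcpp::Named("S") = S,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("n_iter") = (int) trace.size(),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("degenerate") = degenerate,
    Rcpp::Named("nonfinite") = nonfinite);
}

// [[Rcpp::export]]
Rcpp::List smcca_core_cpp(const arma::cube& CP, int K, double lambda,
                          double tol, int max_iter, double eps,
                          const arma::mat& V0, bool identity_cov) {
  const int p = CP.n_rows;
  mat V = V0;
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false, degenerate = false, nonfinite = false;
  mat eye_p;
  if (identity_cov) eye_p = eye(p, p);

  for (int it = 0; it < max_iter; ++it) {
    mat Vold = V;
    for (int k = 0; k < K; ++k) {
      vec rhs(p, fill::zeros);
      for (int j = 0; j < K; ++j) {
        if (j == k) continue;
        rhs += CP.slice(k * K + j) * V.col(j);
      }
      vec d = lambda / (abs(V.col(k)) + eps);
      const mat& G = identity_cov ? eye_p : CP.slice(k * K + k);
      vec vnew;
      if (!ridge_solve(G, d, K - 1.0, rhs, vnew)) { degenerate = true; break; }
      double c = norm(vnew, 2);
      // pre-normalization collapse relative to the driving signal means the
      // penalty has crushed the view (e.g. lambda far beyond the grid)
      if (!std::isfinite(c) || c < 1e-10 * std::max(1.0, norm(rhs, 2))) {
        degenerate = true; break;
      }
      V.col(k) = vnew / c;  // unit-norm weight constraint ||v_k||_2 = 1
    }
    if (degenerate) break;
    double obj = pd_loss(CP, K, V) + lambda * accu(abs(V));
    if (!std::isfinite(obj)) { nonfinite = true; break; }
    trace.push_back(obj);
    double delta = abs(V - Vold).max();
    if (delta <= tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("V") = V,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("n_iter") = (int) trace.size(),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("degenerate") = degenerate,
    Rcpp::Named("nonfinite") = nonfinite);
}
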