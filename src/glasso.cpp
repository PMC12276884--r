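#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Blockwise coordinate descent for the L1-penalized Gaussian likelihood
//   min_{Omega > 0}  -log|Omega| + tr(S Omega) + lambda * ||Omega||_1
// (Friedman/Hastie/Tibshirani 2008 scheme). Each column of the working
// covariance W is updated by solving a lasso subproblem with inner
// coordinate descent. When penalize_diag is true the diagonal of W is
// held at diag(S) + lambda, i.e. the diagonal is penalized too.
//
// W_init/B_init allow warm starts across a lambda path; B holds the
// lasso coefficients (column j: regression of variable j on the rest,
// entry (k, j) the coefficient of variable k, diagonal unused).
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, bool penalize_diag,
                      double tol, int max_iter,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const int p = S.n_rows;
  const double dpen = penalize_diag ? lambda : 0.0;

  // W is always re-initialized from S: a warm-started W from a different
  // input matrix breaks the blockwise updates; the lasso coefficients B
  // carry the useful warm-start information (sparsity pattern).
  mat W = S, B;
  W.diag() = S.diag() + dpen;
  if (B_init.isNotNull()) {
    B = Rcpp::as<mat>(B_init.get());
    if (!B.is_finite()) B.zeros(p, p);
  } else {
    B.zeros(p, p);
  }
  (void)W_init;

  // glasso-style stopping scale: average absolute off-diagonal of S
  double off_avg = 0.0;
  if (p > 1) {
    off_avg = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  }
  const double thr = tol * std::max(off_avg, 1e-12);
  const double inner_thr = thr / 10.0;
  const int max_inner = 1000;

  int iter = 0;
  bool converged = (p == 1);

  if (p > 1) {
    for (iter = 1; iter <= max_iter; ++iter) {
      double dw_max = 0.0;
      for (int j = 0; j < p; ++j) {
        uvec idx(p - 1);
        for (int k = 0, r = 0; k < p; ++k) if (k != j) idx(r++) = k;
        mat V = W.submat(idx, idx);          // (p-1) x (p-1)
        vec s12(p - 1), beta(p - 1);
        for (int k = 0; k < p - 1; ++k) {
          s12(k) = S(idx(k), j);
          beta(k) = B(idx(k), j);
        }
        // lasso: min 1/2 b'Vb - s12'b + lambda |b|_1, coordinate descent
        // with active-set sweeps between full passes; a small ridge is
        // added on retry if the descent drifts non-finite (singular V)
        double ridge = 0.0;
        for (int attempt = 0; attempt < 2; ++attempt) {
          bool ok = true;
          auto cd_pass = [&](const std::vector<int>& ks) {
            double db_max = 0.0;
            for (int k : ks) {
              double bk_old = beta(k);
              double vkk = V(k, k) + ridge;
              double r = s12(k) - dot(V.col(k), beta) + V(k, k) * bk_old;
              double bk = soft_threshold(r, lambda) / vkk;
              if (bk != bk_old) {
                beta(k) = bk;
                db_max = std::max(db_max, std::fabs(bk - bk_old));
              }
            }
            return db_max;
          };
          std::vector<int> all_k(p - 1);
          for (int k = 0; k < p - 1; ++k) all_k[k] = k;
          for (int it2 = 0; it2 < max_inner; ++it2) {
            double db_full = cd_pass(all_k);
            if (!beta.is_finite()) { ok = false; break; }
            if (db_full < inner_thr || db_full < 1e-12) break;
            std::vector<int> active;
            for (int k = 0; k < p - 1; ++k) if (beta(k) != 0.0) active.push_back(k);
            for (int it3 = 0; it3 < max_inner; ++it3) {
              double db_act = cd_pass(active);
              if (!beta.is_finite()) { ok = false; break; }
              if (db_act < inner_thr || db_act < 1e-12) break;
            }
            if (!ok) break;
          }
          if (ok) break;
          ridge = 1e-6 * mean(V.diag()) + 1e-12;
          beta.zeros();
        }
        vec w12 = V * beta;
        for (int k = 0; k < p - 1; ++k) {
          double d = std::fabs(w12(k) - W(idx(k), j));
          if (d > dw_max) dw_max = d;
          W(idx(k), j) = w12(k);
          W(j, idx(k)) = w12(k);
          B(idx(k), j) = beta(k);
        }
      }
      if (dw_max < thr) { converged = true; break; }
    }
    if (iter > max_iter) iter = max_iter;
  }

  // recover the precision matrix from (W, B)
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double cross = 0.0;
    for (int k = 0; k < p; ++k) if (k != j) cross += W(k, j) * B(k, j);
    double tjj = 1.0 / (W(j, j) - cross);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("omega") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("b") = B,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
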