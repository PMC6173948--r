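// Fuzzy c-means core: alternating centroid / distance / membership updates
// with a correlation-based distance. The hot loop is two n x p x c GEMMs per
// iteration, so the whole sweep machinery sits on top of this routine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise power with fast paths for the exponents the defaults produce
// (m = 1.5 gives U^1.5 and D^-4; m = 2 gives U^2 and D^-2).
static mat pow_elem(const mat& M, double e) {
  if (e == 1.0) return M;
  if (e == 2.0) return square(M);
  if (e == 4.0) return square(square(M));
  if (e == 1.5) return M % sqrt(M);
  return pow(M, e);
}

// Rows standardised to zero mean / unit sum of squares, so that
// Z_x * Z_v.t() is exactly the matrix of Pearson correlations.
// Zero-variance rows are zeroed (correlation defined as 0 downstream).
static mat standardize_rows(const mat& M) {
  mat Z = M.each_col() - mean(M, 1);
  vec ss = sqrt(sum(square(Z), 1));
  for (uword i = 0; i < Z.n_rows; ++i) {
    if (ss(i) > 0) Z.row(i) /= ss(i); else Z.row(i).zeros();
  }
  return Z;
}

// Correlation -> distance transform. variant 1: (1-cc)/(1+cc);
// variant 2: (sqrt(|cc|)-cc)/(sqrt(|cc|)+cc) with D(0) = 1 by continuity.
// cc is clamped to [-1 + clamp_eps, 1] so distances stay finite.
static mat cc_to_dist(mat CC, int variant, double clamp_eps) {
  CC.clamp(-1.0 + clamp_eps, 1.0);
  mat D(size(CC));
  if (variant == 1) {
    D = (1.0 - CC) / (1.0 + CC);
  } else {
    mat s = sqrt(abs(CC));
    D = (s - CC) / (s + CC);
    D.elem(find(CC == 0)).ones();
  }
  return D;
}

// stop_rule 1: max |delta U| < tol; stop_rule 2: |delta J| < tol
// [[Rcpp::export(name = ".fcm_fit_cpp")]]
Rcpp::List fcm_fit_cpp(const arma::mat& X, const arma::mat& Xs,
                       arma::mat U, double m, int max_iter, double tol,
                       int dist_variant, double clamp_eps,
                       int stop_rule = 1) {
  const uword n = X.n_rows;
  const double e_mem = 2.0 / (m - 1.0);
  std::vector<double> jhist;
  jhist.reserve(64);

  mat V, D, W;
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // Eq. 3: centroids as U^m-weighted means of the raw time-courses
    W = pow_elem(U, m);
    rowvec wsum = sum(W, 0);
    if (wsum.min() <= 0)
      Rcpp::stop("degenerate cluster: zero total membership weight");
    V = W.t() * X;
    V.each_col() /= wsum.t();

    // Pearson correlations voxel x centroid, then Eq. 4/5 transform
    D = cc_to_dist(Xs * standardize_rows(V).t(), dist_variant, clamp_eps);

    // Eq. 2: U_ij = D_ij^{-2/(m-1)} / sum_k D_ik^{-2/(m-1)},
    // with the usual singularity convention at D = 0.
    mat Unew(n, U.n_cols);
    mat A = pow_elem(1.0 / D, e_mem);
    vec rs = sum(A, 1);
    Unew = A.each_col() / rs;
    if (!Unew.is_finite() || D.min() == 0) {
      for (uword i = 0; i < n; ++i) {
        rowvec di = D.row(i);
        uvec z = find(di == 0);
        if (z.n_elem > 0) {
          Unew.row(i).zeros();
          for (uword k = 0; k < z.n_elem; ++k)
            Unew(i, z(k)) = 1.0 / z.n_elem;
        } else if (!Unew.row(i).is_finite()) {
          rowvec a = pow(di, -e_mem);
          Unew.row(i) = a / accu(a);
        }
      }
    }

    // Eq. 1 objective with the freshly updated memberships
    double J = accu(pow_elem(Unew, m) % square(D));
    double deltaJ = jhist.empty() ? R_PosInf
                                  : std::fabs(jhist.back() - J);
    jhist.push_back(J);

    double delta = abs(Unew - U).max();
    U = std::move(Unew);
    if (stop_rule == 2 ? (deltaJ < tol) : (delta < tol)) {
      converged = true; break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("U") = U,
    Rcpp::Named("V") = V,
    Rcpp::Named("D") = D,
    Rcpp::Named("J_history") = jhist,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
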