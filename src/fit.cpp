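#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Log-linear tensor fit. X: q x p design, logS: q x n (one column per voxel).
// One OLS pass, then `reweight` WLS passes with weights = squared predicted
// signal (the usual heteroscedasticity correction for log-transformed data).
// [[Rcpp::export]]
arma::mat cpp_wls_fit(const arma::mat& X, const arma::mat& logS, int reweight) {
  mat P = pinv(X);
  mat B = P * logS;
  for (int it = 0; it < reweight; ++it) {
    for (uword j = 0; j < logS.n_cols; ++j) {
      vec w = exp(2.0 * (X * B.col(j)));
      mat Xw = X.each_col() % w;
      mat A = X.t() * Xw;
      vec b = X.t() * (w % logS.col(j));
      vec sol;
      if (solve(sol, A, b, solve_opts::no_approx)) B.col(j) = sol;
    }
  }
  return B;
}

static inline void unpack6(const arma::mat& D6, uword j, mat33& M) {
  M(0, 0) = D6(0, j); M(1, 1) = D6(1, j); M(2, 2) = D6(2, j);
  M(0, 1) = M(1, 0) = D6(3, j);
  M(0, 2) = M(2, 0) = D6(4, j);
  M(1, 2) = M(2, 1) = D6(5, j);
}

// Eigen-decompose 3x3 tensors (rows dxx,dyy,dzz,dxy,dxz,dyz), clamp the
// eigenvalues into [lo, hi] and rebuild. Returns descending eigenvalues of
// the clamped tensor, the clamped 6-element tensors, and a flag marking
// voxels whose raw eigenvalues fell outside the bounds.
// [[Rcpp::export]]
Rcpp::List cpp_eig_clamp(const arma::mat& D6, double lo, double hi) {
  uword n = D6.n_cols;
  mat evals(3, n), out(6, n);
  Rcpp::IntegerVector flag(n);
  mat33 M, V;
  vec3 ev;
  for (uword j = 0; j < n; ++j) {
    unpack6(D6, j, M);
    eig_sym(ev, V, M);                       // ascending
    flag[j] = (ev(0) < lo || ev(2) > hi) ? 1 : 0;
    vec3 evc = clamp(ev, lo, hi);
    mat33 R = V * diagmat(evc) * V.t();
    out(0, j) = R(0, 0); out(1, j) = R(1, 1); out(2, j) = R(2, 2);
    out(3, j) = R(0, 1); out(4, j) = R(0, 2); out(5, j) = R(1, 2);
    evals(0, j) = evc(2); evals(1, j) = evc(1); evals(2, j) = evc(0);
  }
  return Rcpp::List::create(Rcpp::Named("evals") = evals,
                            Rcpp::Named("tensor") = out,
                            Rcpp::Named("flag") = flag);
}

struct FwWork {
  const mat& S;      // q x n signals
  const mat& X;      // q x 7 log-linear design
  const mat& P;      // 7 x q pseudo-inverse of X (precomputed once)
  const vec& s0;     // n: per-voxel b0 level
  const mat& Xb;     // q x 6: b_q * [gx2, gy2, gz2, 2gxgy, 2gxgz, 2gygz]
  double lo, hi;
};

// Profile objective at fraction f for voxel j: subtract the water
// compartment, refit the tissue tensor by WLS with eigenvalue clamping,
// and score the bi-tensor prediction against the normalized signal.
static double fw_objective(const FwWork& wk, uword j, double f,
                           const vec& W, vec& D6out) {
  vec Sc = (wk.S.col(j) - f * wk.s0(j) * W) / (1.0 - f);
  double mx = Sc.max();
  double floorv = (mx > 0) ? mx * 1e-6 : 1e-12;
  vec pos = Sc(find(Sc > 0));
  if (pos.n_elem > 0) floorv = pos.min() * 1e-3;
  Sc = arma::clamp(Sc, floorv, datum::inf);
  vec logS = log(Sc);
  vec B = wk.P * logS;
  for (int it = 0; it < 1; ++it) {
    vec w = exp(2.0 * (wk.X * B));
    mat Xw = wk.X.each_col() % w;
    vec sol;
    if (solve(sol, wk.X.t() * Xw, wk.X.t() * (w % logS), solve_opts::no_approx))
      B = sol;
  }
  mat33 M, V; vec3 ev;
  mat D6(6, 1);
  for (int i = 0; i < 6; ++i) D6(i, 0) = B(i + 1);
  unpack6(D6, 0, M);
  eig_sym(ev, V, M);
  vec3 evc = clamp(ev, wk.lo, wk.hi);
  mat33 R = V * diagmat(evc) * V.t();
  D6out = {R(0, 0), R(1, 1), R(2, 2), R(0, 1), R(0, 2), R(1, 2)};
  vec quad = wk.Xb * D6out;                  // q: b g^T D g
  vec A = exp(-quad);
  vec pred = (1.0 - f) * A + f * W;
  vec resid = wk.S.col(j) / wk.s0(j) - pred;
  return dot(resid, resid);
}

// Per-voxel variable-projection free-water fit: golden-section search for
// the water fraction on [fmin, fmax], tissue tensor refit nested inside the
// objective. Returns f, the clamped tissue tensor at the optimum, the
// objective value, and a central-difference curvature used to flag
// flat-ridge voxels.
// [[Rcpp::export]]
Rcpp::List cpp_fw_profile(const arma::mat& S, const arma::mat& X,
                          const arma::mat& Xb, const arma::vec& s0,
                          const arma::vec& bvals, double dw,
                          double fmin, double fmax, double lo, double hi,
                          double ftol) {
  uword n = S.n_cols;
  vec W = exp(-bvals * dw);
  mat P = pinv(X);
  FwWork wk{S, X, P, s0, Xb, lo, hi};
  vec f(n), J(n), curv(n);
  mat D6(6, n);
  vec d6a(6), d6b(6), dtmp(6);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double fhibound = std::min(fmax, 0.99);
  for (uword j = 0; j < n; ++j) {
    double a = fmin, b = fhibound;
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = fw_objective(wk, j, x1, W, d6a);
    double f2 = fw_objective(wk, j, x2, W, d6b);
    while (b - a > ftol) {
      if (f1 < f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = fw_objective(wk, j, x1, W, d6a);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = fw_objective(wk, j, x2, W, d6b);
      }
    }
    double fj = (f1 < f2) ? x1 : x2;
    double Jj = std::min(f1, f2);
    J(j) = fw_objective(wk, j, fj, W, dtmp);
    D6.col(j) = dtmp;
    f(j) = fj;
    double dlt = 0.05;
    double flft = std::max(fmin, fj - dlt), frgt = std::min(fhibound, fj + dlt);
    double Jl = fw_objective(wk, j, flft, W, d6a);
    double Jr = fw_objective(wk, j, frgt, W, d6b);
    double h = std::max(fj - flft, frgt - fj);
    curv(j) = (Jl + Jr - 2.0 * Jj) / (h * h);
  }
  return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("tensor") = D6,
                            Rcpp::Named("objective") = J,
                            Rcpp::Named("curvature") = curv);
}

// Profile objective evaluated on a fixed grid of candidate fractions for
// every voxel (rows = grid values, columns = voxels). Feeds the spatially
// regularized fit: objectives are kernel-smoothed across voxels before the
// per-voxel argmin, pooling data over neighborhoods instead of iterating.
// [[Rcpp::export]]
arma::mat cpp_fw_objective_grid(const arma::mat& S, const arma::mat& X,
                                const arma::mat& Xb, const arma::vec& s0,
                                const arma::vec& bvals, double dw,
                                const arma::vec& fgrid, double lo, double hi) {
  uword n = S.n_cols, nf = fgrid.n_elem;
  vec W = exp(-bvals * dw);
  mat P = pinv(X);
  FwWork wk{S, X, P, s0, Xb, lo, hi};
  mat J(nf, n);
  vec dtmp(6);
  for (uword j = 0; j < n; ++j) {
    for (uword i = 0; i < nf; ++i) {
      J(i, j) = fw_objective(wk, j, fgrid(i), W, dtmp);
    }
  }
  return J;
}

// Tissue tensor refit at fixed per-voxel fractions: subtract the water
// compartment, floor, WLS fit, eigenvalue clamp. Used once after the
// regularized fraction field is chosen.
// [[Rcpp::export]]
Rcpp::List cpp_fw_tensor_at_f(const arma::mat& S, const arma::mat& X,
                              const arma::vec& s0, const arma::vec& bvals,
                              double dw, const arma::vec& f,
                              double lo, double hi) {
  uword n = S.n_cols;
  vec W = exp(-bvals * dw);
  mat D6(6, n);
  mat33 M, V; vec3 ev;
  for (uword j = 0; j < n; ++j) {
    double fr = std::min(f(j), 0.99);
    vec Sc = (S.col(j) - fr * s0(j) * W) / (1.0 - fr);
    double floorv = 1e-12;
    vec pos = Sc(find(Sc > 0));
    if (pos.n_elem > 0) floorv = pos.min() * 1e-3;
    Sc = arma::clamp(Sc, floorv, datum::inf);
    vec logS = log(Sc);
    vec B = pinv(X) * logS;
    vec w = exp(2.0 * (X * B));
    mat Xw = X.each_col() % w;
    vec sol;
    if (solve(sol, X.t() * Xw, X.t() * (w % logS), solve_opts::no_approx)) B = sol;
    mat d1(6, 1);
    for (int i = 0; i < 6; ++i) d1(i, 0) = B(i + 1);
    unpack6(d1, 0, M);
    eig_sym(ev, V, M);
    vec3 evc = clamp(ev, lo, hi);
    mat33 R = V * diagmat(evc) * V.t();
    D6(0, j) = R(0, 0); D6(1, j) = R(1, 1); D6(2, j) = R(2, 2);
    D6(3, j) = R(0, 1); D6(4, j) = R(0, 2); D6(5, j) = R(1, 2);
  }
  return Rcpp::List::create(Rcpp::Named("tensor") = D6);
}
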