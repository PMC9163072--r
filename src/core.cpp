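// Core numerics for the sparse recurrent signaling model: steady-state
// forward iteration, steady-state adjoint (backward) iteration with
// gradient clipping, per-edge weight gradients, and dominant eigenpairs
// of the linearized transition matrix.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// activation codes: 0 = MML, 1 = leaky ReLU, 2 = sigmoid
static inline double act_fun(double x, int code, double leak) {
  switch (code) {
  case 0:
    if (x < 0.0) return leak * x;
    if (x < 0.5) return x;
    return 1.0 - 0.25 / x; // 0.5 + 0.5*(x-0.5)/x
  case 1:
    return x < 0.0 ? leak * x : x;
  default:
    return 1.0 / (1.0 + std::exp(-x));
  }
}

static inline double act_grad(double x, int code, double leak) {
  switch (code) {
  case 0:
    if (x < 0.0) return leak;
    if (x < 0.5) return 1.0;
    return 0.25 / (x * x);
  case 1:
    return x < 0.0 ? leak : 1.0;
  default: {
    double s = 1.0 / (1.0 + std::exp(-x));
    return s * (1.0 - s);
  }
  }
}

// tanh-tailed clip: identity on [-c, c], saturates smoothly to +/- 2c
static inline double clip_fun(double g, double c) {
  if (g > c)  return c + c * std::tanh((g - c) / c);
  if (g < -c) return -c - c * std::tanh((-g - c) / c);
  return g;
}

static void apply_act(mat& Z, mat& H, int code, double leak) {
  const uword nel = Z.n_elem;
  for (uword k = 0; k < nel; ++k) H[k] = act_fun(Z[k], code, leak);
}

// Forward pass: H_{n+1} = sigma(A H_n + bias + X), H_0 = 0.
// X is n x s (projected input per condition as columns). Optionally a
// nonzero initial state H0 may be supplied (used for stability checks).
// [[Rcpp::export]]
Rcpp::List cpp_forward(const arma::sp_mat& A, const arma::vec& bias, const arma::mat& X,
                       int max_steps, double tol, int act_code,
                       double leak, Rcpp::Nullable<Rcpp::NumericMatrix> H0 =
                         R_NilValue) {
  const uword n = A.n_rows, s = X.n_cols;
  mat H(n, s, fill::zeros);
  if (H0.isNotNull()) H = Rcpp::as<mat>(H0.get());
  mat B = X;
  B.each_col() += bias;
  mat Z(n, s);
  rowvec resid(s, fill::value(datum::inf));
  int steps = 0;
  // fused CSC iteration: z = A h + b + x, h <- sigma(z), residual inline
  A.sync();
  const double* vals = A.values;
  const uword* rowi = A.row_indices;
  const uword* colp = A.col_ptrs;
  for (int it = 0; it < max_steps; ++it) {
    for (uword c = 0; c < s; ++c) {
      double* z = Z.colptr(c);
      const double* b = B.colptr(c);
      double* h = H.colptr(c);
      std::memcpy(z, b, n * sizeof(double));
      for (uword j = 0; j < n; ++j) {
        const double hv = h[j];
        if (hv == 0.0) continue;
        for (uword k = colp[j]; k < colp[j + 1]; ++k)
          z[rowi[k]] += vals[k] * hv;
      }
      double r = 0.0;
      for (uword i = 0; i < n; ++i) {
        const double hn = act_fun(z[i], act_code, leak);
        const double d = std::abs(hn - h[i]);
        if (d > r) r = d;
        h[i] = hn;
      }
      resid[c] = r;
    }
    steps = it + 1;
    if (!H.is_finite())
      Rcpp::stop("forward iteration diverged to non-finite state at step %d",
                 steps);
    if (resid.max() < tol) break;
  }
  // pre-activation consistent with the returned state
  Z = B;
  for (uword c = 0; c < s; ++c) {
    double* z = Z.colptr(c);
    const double* h = H.colptr(c);
    for (uword j = 0; j < n; ++j) {
      const double hv = h[j];
      if (hv == 0.0) continue;
      for (uword k = colp[j]; k < colp[j + 1]; ++k)
        z[rowi[k]] += vals[k] * hv;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("states") = H, Rcpp::Named("pre_activation") = Z,
    Rcpp::Named("residual") = Rcpp::NumericVector(resid.begin(), resid.end()),
    Rcpp::Named("steps_used") = steps);
}

// Steady-state adjoint: u_{k+1} = clip(G + A' (sigma'(Z) % u_k)), u_0 = G.
// Returns Delta = sigma'(Z) % u (so dL/dbias = Delta summed over
// conditions, dL/dA_ij = sum_s Delta(i,s) H(j,s)).
// [[Rcpp::export]]
Rcpp::List cpp_backward(const arma::sp_mat& A, const arma::mat& Z, const arma::mat& G,
                        int max_steps, double tol, int act_code, double leak,
                        double clip_c) {
  const uword n = Z.n_rows, s = Z.n_cols;
  mat Sp(n, s);
  for (uword k = 0; k < Sp.n_elem; ++k) Sp[k] = act_grad(Z[k], act_code, leak);
  sp_mat At = A.t();
  At.sync();
  const double* vals = At.values;
  const uword* rowi = At.row_indices;
  const uword* colp = At.col_ptrs;
  mat U = G;
  vec buf(n);
  double resid = datum::inf;
  int steps = 0;
  for (int it = 0; it < max_steps; ++it) {
    resid = 0.0;
    for (uword c = 0; c < s; ++c) {
      double* u = U.colptr(c);
      const double* g = G.colptr(c);
      const double* sp = Sp.colptr(c);
      double* z = buf.memptr();
      std::memcpy(z, g, n * sizeof(double));
      for (uword j = 0; j < n; ++j) {
        const double uv = sp[j] * u[j];
        if (uv == 0.0) continue;
        for (uword k = colp[j]; k < colp[j + 1]; ++k)
          z[rowi[k]] += vals[k] * uv;
      }
      for (uword i = 0; i < n; ++i) {
        const double un = clip_fun(z[i], clip_c);
        const double d = std::abs(un - u[i]);
        if (d > resid) resid = d;
        u[i] = un;
      }
    }
    steps = it + 1;
    if (!U.is_finite())
      Rcpp::stop("adjoint iteration diverged to non-finite values at step %d",
                 steps);
    if (resid < tol) break;
  }
  mat Delta = Sp % U;
  return Rcpp::List::create(Rcpp::Named("delta") = Delta,
                            Rcpp::Named("adjoint") = U,
                            Rcpp::Named("residual") = resid,
                            Rcpp::Named("steps_used") = steps);
}

// Per-edge weight gradient: grad_e = sum_s Delta(tgt_e, s) * H(src_e, s).
// tgt, src are 0-based node indices per edge.
// [[Rcpp::export]]
arma::vec cpp_weight_grad(const arma::uvec& tgt, const arma::uvec& src,
                          const arma::mat& Delta, const arma::mat& H) {
  const uword m = tgt.n_elem, s = Delta.n_cols;
  vec g(m, fill::zeros);
  for (uword e = 0; e < m; ++e) {
    double acc = 0.0;
    for (uword j = 0; j < s; ++j) acc += Delta(tgt[e], j) * H(src[e], j);
    g[e] = acc;
  }
  return g;
}

// Dominant eigenpair (largest |lambda|) of a sparse real matrix, with the
// matching left eigenvector. Small matrices use the dense solver; larger
// ones try the sparse solver first and fall back to dense on failure.
// [[Rcpp::export]]
Rcpp::List cpp_dominant_eigs(const arma::sp_mat& T, int k = 4,
                             double tol = 0.0) {
  const uword n = T.n_rows;
  cx_vec eval;
  cx_mat evec;
  bool dense = n < 50;
  if (!dense) {
    uword kk = std::min<uword>(std::max(1, k), n - 2);
    bool ok = eigs_gen(eval, evec, T, kk, "lm", tol);
    if (!ok || eval.n_elem == 0) dense = true;
  }
  if (dense) {
    eig_gen(eval, evec, mat(T));
  }
  uword imax = index_max(abs(eval));
  cx_double lam = eval(imax);
  cx_vec v = evec.col(imax);

  // left eigenvector: right eigenvector of T' for the eigenvalue closest
  // to lam
  cx_vec evalL;
  cx_mat evecL;
  bool denseL = dense;
  if (!denseL) {
    uword kk = std::min<uword>(std::max(1, k), n - 2);
    bool ok = eigs_gen(evalL, evecL, sp_mat(T.t()), kk, "lm", tol);
    if (!ok || evalL.n_elem == 0) denseL = true;
  }
  if (denseL) {
    eig_gen(evalL, evecL, mat(T.t()));
  }
  uword iL = index_min(abs(evalL - lam));
  cx_vec w = evecL.col(iL);

  return Rcpp::List::create(Rcpp::Named("lambda") = lam,
                            Rcpp::Named("right_vec") = v,
                            Rcpp::Named("left_vec") = w,
                            Rcpp::Named("rho") = std::abs(lam));
}

// Spectral radius only (no eigenvectors), used for initialization scaling.
// [[Rcpp::export]]
double cpp_spectral_radius(const arma::sp_mat& A) {
  const uword n = A.n_rows;
  cx_vec eval;
  if (n >= 50) {
    bool ok = eigs_gen(eval, A, std::min<uword>(4, n - 2), "lm");
    if (ok && eval.n_elem > 0) return abs(eval).max();
  }
  eig_gen(eval, mat(A));
  return abs(eval).max();
}

// One-pass per-column mean, population variance, min, max with 1-based
// argmin/argmax rows; the state regularizer calls this every batch.
// [[Rcpp::export]]
Rcpp::List cpp_colstats(const arma::mat& M) {
  const uword n = M.n_rows, p = M.n_cols;
  vec mu(p), va(p), mn(p), mx(p);
  uvec imn(p), imx(p);
  for (uword j = 0; j < p; ++j) {
    double s = 0, s2 = 0, lo = M(0, j), hi = M(0, j);
    uword ilo = 0, ihi = 0;
    for (uword i = 0; i < n; ++i) {
      double x = M(i, j);
      s += x; s2 += x * x;
      if (x < lo) { lo = x; ilo = i; }
      if (x > hi) { hi = x; ihi = i; }
    }
    mu[j] = s / n;
    va[j] = s2 / n - mu[j] * mu[j];
    mn[j] = lo; mx[j] = hi; imn[j] = ilo + 1; imx[j] = ihi + 1;
  }
  return Rcpp::List::create(
    Rcpp::Named("mean") = mu, Rcpp::Named("var") = va,
    Rcpp::Named("min") = mn, Rcpp::Named("max") = mx,
    Rcpp::Named("which_min") = imn, Rcpp::Named("which_max") = imx);
}
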