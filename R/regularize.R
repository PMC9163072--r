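#' Regularization configuration
#'
#' Coefficients and constants for every loss term beyond the data fit.
#'
#' @param l2_coeff L2 coefficient on weights and biases (default 1e-8; the
#'   reference parameterization uses 1e-6).
#' @param antizero_enabled Add the anti-zero weight term
#'   `sum(1 / (w^2 + 0.5))` that keeps weights from getting stuck at zero.
#' @param antizero_coeff Coefficient on the anti-zero term (default 1e-6).
#'   The term's constant outward pressure is amplified by adaptive
#'   optimizers; stronger settings inflate weights until the model is
#'   only saturation-stabilized and training collapses.
#' @param state_coeff Coefficient on the state-uniformity regularization
#'   (default 1e-5).
#' @param uniform_a,uniform_b Interval of the target uniform distribution
#'   for node states (defaults 0.01 and 0.99).
#' @param moa_coeff Coefficient on the mode-of-action sign constraint.
#' @param ligand_bias_coeff Coefficient on the squared ligand biases.
#' @param noise_factor Bias-noise scale: noise sd is
#'   `noise_factor * learning rate` (default 10).
#' @param spectral_coeff Coefficient on the spectral-radius barrier
#'   (default 1e-3 for data training; 1e-2 for reference
#'   parameterization). Weaker settings let larger models drift unstable
#'   mid-training. Set to 0 to disable.
#' @param spectral_k Barrier steepness `k` (default 50).
#' @param spectral_target_precision,spectral_max_steps Define the target
#'   spectral radius `exp(target_precision / max_steps)`: with defaults
#'   `log(1e-6)` and 150, linearized dynamics decay below 1e-6 within the
#'   150-step budget, giving target rho ~ 0.912.
#' @return A list of class `"sn_regularization"`.
#' @export
regularization_config <- function(l2_coeff = 1e-8, antizero_enabled = TRUE,
                                  antizero_coeff = 1e-6,
                                  state_coeff = 1e-5, uniform_a = 0.01,
                                  uniform_b = 0.99, moa_coeff = 1,
                                  ligand_bias_coeff = 1, noise_factor = 10,
                                  spectral_coeff = 1e-3, spectral_k = 50,
                                  spectral_target_precision = log(1e-6),
                                  spectral_max_steps = 150) {
  stopifnot(uniform_a < uniform_b, l2_coeff >= 0, state_coeff >= 0,
            moa_coeff >= 0, ligand_bias_coeff >= 0, spectral_coeff >= 0)
  structure(list(l2_coeff = l2_coeff, antizero_enabled = antizero_enabled,
                 antizero_coeff = antizero_coeff,
                 state_coeff = state_coeff, uniform_a = uniform_a,
                 uniform_b = uniform_b, moa_coeff = moa_coeff,
                 ligand_bias_coeff = ligand_bias_coeff,
                 noise_factor = noise_factor,
                 spectral_coeff = spectral_coeff, spectral_k = spectral_k,
                 spectral_target = exp(spectral_target_precision /
                                         spectral_max_steps)),
            class = "sn_regularization")
}

#' Mode-of-action sign-violation loss
#'
#' Sum of absolute values of weights whose sign contradicts the prior
#' knowledge mode of action; edges with unknown mode of action are exempt.
#' Zero exactly when all constrained signs agree.
#'
#' @param model An `sn_model`.
#' @return Scalar loss; the per-weight gradient is available via
#'   `attr(, "grad")`.
#' @export
sign_violation_loss <- function(model) {
  moa <- model$network$interactions$moa
  w <- model$weights
  viol_pos <- moa == 1L & w < 0
  viol_neg <- moa == -1L & w > 0
  loss <- sum(-w[viol_pos]) + sum(w[viol_neg])
  g <- numeric(length(w))
  g[viol_pos] <- -1
  g[viol_neg] <- 1
  structure(loss, grad = g)
}

#' Ligand-bias loss
#'
#' Sum of squared biases at ligand nodes. Ligand concentrations enter as
#' inputs, so the model is discouraged from absorbing them into biases.
#'
#' @param model An `sn_model`.
#' @return Scalar loss with per-bias gradient in `attr(, "grad")`.
#' @export
ligand_bias_loss <- function(model) {
  li <- model$ligand_idx
  b <- model$bias
  loss <- sum(b[li]^2)
  g <- numeric(length(b))
  g[li] <- 2 * b[li]
  structure(loss, grad = g)
}

#' Anti-zero weight loss
#'
#' `sum(1 / (w_i^2 + 0.5))` over the weight vector: large for weights near
#' zero, vanishing for large weights, so training does not strand weights
#' at zero where the data gradient also vanishes.
#'
#' @param weights Numeric weight vector.
#' @return Scalar loss with gradient in `attr(, "grad")`.
#' @export
antizero_loss <- function(weights) {
  d <- weights^2 + 0.5
  structure(sum(1 / d), grad = -2 * weights / d^2)
}

# Statistics of a uniform distribution on [a, b] and the squared-deviation
# loss of per-column empirical mean/variance/min/max from them, plus a
# barrier on negative maxima. `M` holds one column per unit whose
# distribution across rows should be uniform. `grad_rows`: rows that
# receive gradient (default all).
uniform_stat_loss <- function(M, a = 0.01, b = 0.99,
                              grad_rows = seq_len(nrow(M))) {
  n <- nrow(M)
  mu_t <- (b - a) / 2
  var_t <- (b - a)^2 / 12
  st <- cpp_colstats(M)
  mu <- st$mean; v <- st$var; mn <- st$min; mx <- st$max
  loss <- sum((mu - mu_t)^2) + sum((v - var_t)^2) +
    sum((mn - a)^2) + sum((mx - b)^2) + sum(pmax(-mx, 0))
  nb <- length(grad_rows)
  # mean and variance terms (population variance)
  gr <- matrix(2 * (mu - mu_t) / n, nb, ncol(M), byrow = TRUE)
  Mb_c <- sweep(M[grad_rows, , drop = FALSE], 2, mu)
  gr <- gr + sweep(Mb_c, 2, 4 * (v - var_t) / n, `*`)
  # min/max subgradients at the (first) attaining row, if in grad_rows
  jn <- which(st$which_min %in% grad_rows)
  for (j in jn) {
    r <- match(st$which_min[j], grad_rows)
    gr[r, j] <- gr[r, j] + 2 * (mn[j] - a)
  }
  jx <- which(st$which_max %in% grad_rows)
  for (j in jx) {
    r <- match(st$which_max[j], grad_rows)
    gr[r, j] <- gr[r, j] + 2 * (mx[j] - b)
    if (mx[j] < 0) gr[r, j] <- gr[r, j] - 1
  }
  list(loss = loss, grad = gr)
}

#' State-uniformity regularization
#'
#' Encourages each node's state to be approximately uniform on
#' `[a, b]` across conditions by penalizing squared deviations of the
#' empirical mean, variance, minimum, and maximum from those of the target
#' uniform distribution (mean `(a+b)/2`, variance `(b-a)^2/12`, min `a`,
#' max `b`), plus a barrier on negative maxima. Statistics are computed
#' across *all* conditions using a store of the latest states
#' per condition; only conditions in the current batch contribute
#' gradient (stale entries are treated as constants).
#'
#' @param store Conditions-by-nodes matrix of the latest computed state for
#'   every condition (stale outside the current batch).
#' @param batch_rows Integer indices of the rows belonging to the current
#'   batch.
#' @param config A [regularization_config()].
#' @return List with `loss` (scalar, unweighted) and `grad`, a
#'   `length(batch_rows)`-by-nodes matrix of gradients w.r.t. the current
#'   batch states.
#' @export
state_uniformity_loss <- function(store, batch_rows,
                                  config = regularization_config()) {
  uniform_stat_loss(store, config$uniform_a, config$uniform_b,
                    grad_rows = batch_rows)
}

#' Add learning-rate-scaled Gaussian noise to the biases
#'
#' `b <- b + noise_factor * lr * N(0, 1)`, applied before each forward
#' pass during training so fitted parameters are robust to small
#' perturbations; the noise anneals with the learning rate.
#'
#' @param model An `sn_model`.
#' @param lr Current learning rate (>= 0).
#' @param seed Optional seed for reproducibility.
#' @param noise_factor Noise scale (default 10).
#' @return Model copy with perturbed biases.
#' @export
perturb_bias_with_noise <- function(model, lr, seed = NULL,
                                    noise_factor = 10) {
  stopifnot(lr >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (lr > 0)
    model$bias <- model$bias +
      noise_factor * lr * stats::rnorm(length(model$bias))
  model
}

#' Dominant eigenpair of the linearized transition matrix
#'
#' Linearizing the steady-state update around a converged state gives the
#' transition matrix `T = diag(sigma'(z_ss)) A`; deviations from steady
#' state decay iff its spectral radius (largest absolute eigenvalue) is
#' below 1. Returns the dominant eigenvalue with matching left and right
#' eigenvectors (the left vector is obtained from the transposed matrix,
#' targeting the eigenvalue found in the first pass).
#'
#' @param model An `sn_model`.
#' @param ss A converged `sn_steady_state`.
#' @param condition Column index of the condition to linearize around.
#' @param settings [simulation_settings()].
#' @param k,tol Eigensolver subspace size and tolerance (defaults: exact).
#' @return An `sn_spectrum`: list with `rho`, `lambda` (complex),
#'   `right_vec`, `left_vec`, and the sigma-prime vector `sp`.
#' @export
transition_spectrum <- function(model, ss, condition = 1L,
                                settings = simulation_settings(),
                                k = 4L, tol = 0) {
  z <- ss$pre_activation[, condition]
  sp <- act_apply_grad(z, settings$act_kind, settings$activation)
  A <- weight_matrix(model)
  T_ <- Matrix::Diagonal(x = sp) %*% A
  eg <- cpp_dominant_eigs(methods::as(T_, "dgCMatrix"), k, tol)
  structure(list(rho = eg$rho, lambda = eg$lambda,
                 right_vec = eg$right_vec, left_vec = eg$left_vec,
                 sp = sp, condition = condition),
            class = "sn_spectrum")
}

#' @export
print.sn_spectrum <- function(x, ...) {
  cat("<sn_spectrum> rho = ", format(x$rho), ", lambda = ",
      format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Spectral-radius barrier loss and its weight gradient
#'
#' Exponential barrier `a * exp(k * rho)` with
#' `a = 1 / exp(k * target_rho)`, so the loss equals 1 exactly at the
#' target radius and grows steeply beyond it. The gradient of `rho` with
#' respect to each non-zero weight follows from first-order eigenvalue
#' perturbation: `d(lambda)/dT_ij = u_i v_j / (u' v)` with `u` the left
#' and `v` the right eigenvector, projected onto the radius direction by
#' `Re(conj(lambda)/rho * .)` (the imaginary component is orthogonal to
#' the radius and is discarded), then chained with the `sigma'` factor of
#' the row.
#'
#' @param spec An `sn_spectrum` (from [transition_spectrum()], or built
#'   from a plain matrix via [matrix_spectrum()]).
#' @param src_idx,tgt_idx 1-based source/target node indices per edge.
#' @param config A [regularization_config()].
#' @return Scalar loss with per-weight gradient in `attr(, "grad")` and
#'   the radius gradient in `attr(, "rho_grad")`.
#' @export
spectral_radius_loss <- function(spec, src_idx, tgt_idx,
                                 config = regularization_config()) {
  k <- config$spectral_k
  # work with exp(k * (rho - target)) to stay finite for large rho
  loss <- exp(k * (spec$rho - config$spectral_target))
  u <- spec$left_vec
  v <- spec$right_vec
  uv <- sum(u * v)
  if (Mod(uv) < 1e-12)
    stop("left and right eigenvectors are orthogonal (defective matrix); ",
         "spectral gradient undefined")
  fac <- Conj(spec$lambda) / spec$rho / uv
  drho <- Re(fac * u[tgt_idx] * v[src_idx]) * spec$sp[tgt_idx]
  structure(loss, grad = loss * k * drho, rho_grad = drho)
}

#' Eigen-spectrum of a plain sparse matrix
#'
#' Convenience wrapper treating a matrix as its own transition matrix
#' (`sigma' = 1`), for use with [spectral_radius_loss()] and
#' [shrink_spectral_radius()].
#'
#' @param A A square sparse (or dense) matrix.
#' @param k,tol Eigensolver subspace size and tolerance.
#' @return An `sn_spectrum`.
#' @export
matrix_spectrum <- function(A, k = 4L, tol = 0) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  eg <- cpp_dominant_eigs(A, k, tol)
  structure(list(rho = eg$rho, lambda = eg$lambda,
                 right_vec = eg$right_vec, left_vec = eg$left_vec,
                 sp = rep(1, nrow(A)), condition = NA_integer_),
            class = "sn_spectrum")
}

#' Shrink the spectral radius of a sparse matrix by gradient descent
#'
#' Runs plain gradient descent on the exponential spectral-radius barrier,
#' updating only the existing non-zero entries. The barrier factor is
#' capped (trust region) so early steps remain finite when the initial
#' radius is far above the target; once below target the gradient is tiny
#' and the matrix is left essentially unchanged. Weight values before and
#' after remain strongly correlated: the update is concentrated along the
#' dominant eigen-direction.
#'
#' @param A Square sparse matrix.
#' @param steps Number of descent steps (default 200).
#' @param lr Step size (default 1e-4).
#' @param config A [regularization_config()].
#' @return List with the updated sparse `matrix` and the `rho` trajectory.
#' @export
shrink_spectral_radius <- function(A, steps = 200L, lr = 1e-4,
                                   config = regularization_config()) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(A) == ncol(A))
  trip <- Matrix::mat2triplet(A)
  src <- trip$j; tgt <- trip$i
  w <- trip$x
  k <- config$spectral_k
  rho_hist <- numeric(steps)
  for (s in seq_len(steps)) {
    M <- Matrix::sparseMatrix(i = tgt, j = src, x = w,
                              dims = dim(A))
    spec <- matrix_spectrum(M)
    rho_hist[s] <- spec$rho
    sl <- tryCatch(spectral_radius_loss(spec, src, tgt, config),
                   error = function(e) NULL)
    if (is.null(sl)) {
      # eigenvalue collision (near-defective): nudge off the degeneracy
      w <- w + stats::rnorm(length(w)) * 1e-8
      next
    }
    fac <- min(as.numeric(sl) * k, 10 * k) # trust-region cap
    step <- lr * fac * attr(sl, "rho_grad")
    nrm <- sqrt(sum(step^2))
    if (nrm > 0.05) step <- step * (0.05 / nrm)
    w <- w - step
  }
  list(matrix = Matrix::sparseMatrix(i = tgt, j = src, x = w,
                                     dims = dim(A)),
       rho = rho_hist,
       rho_final = matrix_spectrum(
         Matrix::sparseMatrix(i = tgt, j = src, x = w, dims = dim(A)))$rho)
}
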