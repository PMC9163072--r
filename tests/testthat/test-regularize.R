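test_that("constraint losses evaluate their defining formulas", {
  net <- toy_network()
  model <- initialize_parameters(net, 1) # signs agree with moa
  expect_equal(as.numeric(sign_violation_loss(model)), 0)
  # flip one activating weight negative
  m2 <- model
  act_edge <- which(net$interactions$moa == 1L)[1]
  m2$weights[act_edge] <- -0.3
  expect_equal(as.numeric(sign_violation_loss(m2)), 0.3)
  # unknown-moa edges are exempt
  m3 <- model
  m3$network$interactions$moa[act_edge] <- 0L
  m3$weights[act_edge] <- -5
  expect_equal(as.numeric(sign_violation_loss(m3)), 0)

  m4 <- model
  m4$bias[] <- 0
  expect_equal(as.numeric(ligand_bias_loss(m4)), 0)
  m4$bias[m4$ligand_idx[1]] <- 0.2
  m4$bias[setdiff(seq_along(m4$bias), m4$ligand_idx)] <- 9 # ignored
  expect_equal(as.numeric(ligand_bias_loss(m4)), 0.04)

  expect_equal(as.numeric(antizero_loss(0)), 2)
  expect_equal(as.numeric(antizero_loss(c(0, 1))), 2 + 1 / 1.5)
  expect_lt(as.numeric(antizero_loss(1e6)), 1e-10)
  # gradient check
  w <- c(-1.2, 0, 0.4, 2)
  g <- attr(antizero_loss(w), "grad")
  fd <- vapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- wp[i] + 1e-6; wm <- w; wm[i] <- wm[i] - 1e-6
    (as.numeric(antizero_loss(wp)) - as.numeric(antizero_loss(wm))) / 2e-6
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("state uniformity loss matches its target-statistics formula", {
  a <- 0.01; b <- 0.99
  mu_t <- (b - a) / 2; var_t <- (b - a)^2 / 12
  # oracle: direct evaluation of the squared-deviation formula
  oracle <- function(M) {
    sum(apply(M, 2, function(col) {
      v <- mean(col^2) - mean(col)^2
      (mean(col) - mu_t)^2 + (v - var_t)^2 + (min(col) - a)^2 +
        (max(col) - b)^2 + max(-max(col), 0)
    }))
  }
  set.seed(12)
  M <- matrix(runif(60, -0.2, 1.1), 12, 5)
  res <- state_uniformity_loss(M, seq_len(12))
  expect_equal(res$loss, oracle(M), tolerance = 1e-12)
  # a near-uniform sample on [a, b] gives near-zero loss
  U <- matrix(seq(a, b, length.out = 200) - (a + b) / 2 + mu_t, 200, 2)
  expect_lt(state_uniformity_loss(U, 1:200)$loss, 1e-3)
  # all-negative states trigger the negative-max barrier
  res_neg <- state_uniformity_loss(matrix(-0.5, 4, 2), 1:4)
  expect_equal(res_neg$loss, oracle(matrix(-0.5, 4, 2)), tolerance = 1e-12)
  expect_gt(res_neg$loss, 2 * 0.5) # barrier contributes -max = 0.5 per node
  # constant 0.49: mean term 0, variance/min/max terms positive
  resc <- state_uniformity_loss(matrix(0.49, 5, 1), 1:5)
  expect_equal(resc$loss,
               (0 - var_t)^2 + (0.49 - a)^2 + (0.49 - b)^2,
               tolerance = 1e-12)
})

test_that("stale-store gradient only flows to batch rows", {
  set.seed(4)
  M <- matrix(runif(50), 10, 5)
  res <- state_uniformity_loss(M, batch_rows = c(2, 7))
  expect_equal(dim(res$grad), c(2, 5))
  # numeric check: perturb a batch entry
  h <- 1e-6
  M2 <- M; M2[2, 3] <- M2[2, 3] + h
  fd <- (state_uniformity_loss(M2, c(2, 7))$loss -
           state_uniformity_loss(M, c(2, 7))$loss) / h
  expect_equal(res$grad[1, 3], fd, tolerance = 1e-4)
})

test_that("bias noise scales with the learning rate and is seeded", {
  net <- toy_network()
  model <- initialize_parameters(net, 1)
  expect_identical(perturb_bias_with_noise(model, 0)$bias, model$bias)
  a <- perturb_bias_with_noise(model, 0.01, seed = 5)
  b <- perturb_bias_with_noise(model, 0.01, seed = 5)
  expect_identical(a$bias, b$bias)
  # Monte-Carlo sd of the noise ~ 10 * lr
  set.seed(1)
  draws <- replicate(3000, perturb_bias_with_noise(model, 0.01)$bias[1] -
                       model$bias[1])
  expect_equal(sd(draws), 10 * 0.01, tolerance = 0.05)
})

test_that("transition spectrum recovers known eigenstructure", {
  # diagonal matrix: rho equals the diagonal entry
  d <- Matrix::Diagonal(x = rep(0.5, 6))
  spec <- matrix_spectrum(d)
  expect_equal(spec$rho, 0.5, tolerance = 1e-10)
  # 2x2 companion-like matrix: lambda^2 = 0.25
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 0.25),
                            dims = c(2, 2))
  expect_equal(matrix_spectrum(m)$rho, 0.5, tolerance = 1e-10)
  # eigenpair identities for a random sparse matrix
  set.seed(9)
  n <- 30
  A <- Matrix::rsparsematrix(n, n, density = 0.2)
  sp <- matrix_spectrum(A)
  Ad <- as.matrix(A)
  expect_lt(max(Mod(Ad %*% sp$right_vec - sp$lambda * sp$right_vec)),
            1e-8)
  expect_lt(max(Mod(t(Ad) %*% sp$left_vec - sp$lambda * sp$left_vec)),
            1e-8)
  expect_equal(sp$rho, Mod(sp$lambda))
})

test_that("spectral barrier is 1 at target and increasing in rho", {
  cfg <- regularization_config()
  mk_spec <- function(rho) structure(
    list(rho = rho, lambda = complex(real = rho), right_vec = 1,
         left_vec = 1, sp = 1), class = "sn_spectrum")
  at_target <- spectral_radius_loss(mk_spec(cfg$spectral_target), 1, 1,
                                    cfg)
  expect_equal(as.numeric(at_target), 1, tolerance = 1e-12)
  lower <- as.numeric(spectral_radius_loss(mk_spec(0.5), 1, 1, cfg))
  higher <- as.numeric(spectral_radius_loss(mk_spec(1.1), 1, 1, cfg))
  expect_lt(lower, 1)
  expect_gt(higher, 1)
})

test_that("eigen-gradient of rho matches finite differences (10x10)", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 10; m <- 20
    ij <- unique(cbind(sample(n, m, TRUE), sample(n, m, TRUE)))
    w <- rnorm(nrow(ij))
    mk <- function(w) Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                                           x = w, dims = c(n, n))
    spec <- matrix_spectrum(mk(w))
    sl <- spectral_radius_loss(spec, src_idx = ij[, 2], tgt_idx = ij[, 1])
    drho <- attr(sl, "rho_grad")
    h <- 1e-6
    fd <- vapply(seq_along(w), function(e) {
      wp <- w; wp[e] <- wp[e] + h; wm <- w; wm[e] <- wm[e] - h
      (matrix_spectrum(mk(wp))$rho - matrix_spectrum(mk(wm))$rho) / (2 * h)
    }, numeric(1))
    expect_equal(drho, fd, tolerance = 1e-5)
  }
})

test_that("gradient descent on the barrier stabilizes a sparse matrix", {
  set.seed(1)
  n <- 100; m <- round(0.2 * n * n)
  ij <- unique(cbind(sample(n, 2 * m, TRUE), sample(n, 2 * m, TRUE)))[
    seq_len(m), ]
  w <- rnorm(m)
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = w,
                            dims = c(n, n))
  A <- A * (1.2 / matrix_spectrum(A)$rho) # just unstable: rho = 1.2
  w0 <- A[cbind(ij[, 1], ij[, 2])]
  res <- shrink_spectral_radius(A, steps = 200, lr = 1e-4)
  expect_gt(res$rho[1], 1)
  expect_lt(res$rho_final, 1)
  w1 <- res$matrix[cbind(ij[, 1], ij[, 2])]
  expect_gt(cor(w0, w1), 0.95)
  # trajectories of the shrunk matrix decay geometrically
  x <- rnorm(n)
  norms <- vapply(1:100, function(i) {
    x <<- as.numeric(res$matrix %*% x)
    sqrt(sum(x^2))
  }, numeric(1))
  expect_lt(norms[100], norms[10])
  expect_lt(norms[100] / norms[50], 1)
  # an already-stable matrix is left nearly unchanged
  stable <- A * (0.5 / 1.2)
  ws <- stable[cbind(ij[, 1], ij[, 2])]
  res2 <- shrink_spectral_radius(stable, steps = 50, lr = 1e-4)
  expect_equal(res2$matrix[cbind(ij[, 1], ij[, 2])], ws,
               tolerance = 1e-4)
})
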