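test_that("initialization follows the documented rules", {
  net <- random_network(60, 5, 8, 4, seed = 2)
  model <- initialize_parameters(net, 11)
  rho <- signalnet:::cpp_spectral_radius(weight_matrix(model))
  expect_equal(rho, 0.8, tolerance = 1e-6)
  moa <- net$interactions$moa
  expect_true(all(model$weights[moa == 1L] > 0))
  expect_true(all(model$weights[moa == -1L] < 0))
  expect_equal(model$input_scale, rep(3, length(net$ligands)))
  expect_equal(model$output_scale, rep(1.2, length(net$tfs)))
  # nodes with only inhibitory inputs start at bias 1, others at 0.001
  moa_in <- split(moa, net$interactions$target)
  all_inh <- names(moa_in)[vapply(moa_in, function(m) all(m == -1L),
                                  logical(1))]
  for (nd in net$nodes) {
    b <- model$bias[match(nd, net$nodes)]
    if (nd %in% all_inh) expect_equal(b, 1) else expect_equal(b, 0.001)
  }
  # reproducible
  again <- initialize_parameters(net, 11)
  expect_identical(again$weights, model$weights)
  # inhibitory weights drawn in (-0.2, -0.1) before rescaling
  set.seed(11)
  raw <- runif(nrow(net$interactions), 0, 0.1) + 0.1
  expect_true(all(raw >= 0.1 & raw <= 0.2))
})

test_that("input projection zero-pads and scales", {
  net <- toy_network()
  model <- initialize_parameters(net, 1)
  cond <- tibble::tibble(condition = c("a", "b"),
                         L1 = c(1, 0), L2 = c(0.5, 0))
  X <- project_input(cond, model)
  expect_equal(dim(X), c(7, 2))
  expect_equal(X[match("L1", net$nodes), "a"], 3)   # scale 3 x conc 1
  expect_equal(X[match("L2", net$nodes), "a"], 1.5) # scale 3 x conc 0.5
  expect_equal(sum(X != 0), 2)
  expect_true(all(X[, "b"] == 0))
  expect_error(project_input(
    tibble::tibble(condition = "a", BAD = 1), model), "not ligands")
})

test_that("forward pass reproduces hand-computed steady states", {
  # sigma(0) = 0 fixed point
  net <- chain_network()
  m0 <- manual_model(net, weights = 1, bias = 0)
  X0 <- matrix(0, 2, 1, dimnames = list(net$nodes, "c1"))
  ss0 <- forward_steady_state(m0, X0)
  expect_equal(max(abs(ss0$states)), 0)
  # chain L -> T, projected input 3 at L:
  # h_L = sigma(3) = 0.9166667, h_T = sigma(0.9166667) = 0.7272727
  X <- X0; X[match("L", net$nodes), 1] <- 3
  ss <- forward_steady_state(m0, X)
  expect_equal(ss$states[match("L", net$nodes), 1], 1 - 0.25 / 3,
               tolerance = 1e-9)
  expect_equal(ss$states[match("T", net$nodes), 1],
               1 - 0.25 / (1 - 0.25 / 3), tolerance = 1e-9)
  expect_equal(ss$states, signalnet:::act_apply(
    ss$pre_activation, "mml", activation_settings()),
    tolerance = 1e-12)
  expect_lt(ss$residual[1], 1e-6)
})

test_that("contractive models converge well before the step budget", {
  net <- random_network(40, 4, 6, 4, seed = 7)
  model <- initialize_parameters(net, 7) # rho = 0.8 < 1
  cond <- sample_conditions(6, 2, net$ligands, seed = 1)
  X <- project_input(cond, model)
  ss <- forward_steady_state(model, X)
  expect_lt(ss$steps_used, 150)
  expect_true(all(ss$residual < 1e-6))
})

test_that("steady state is independent of the initial state when rho < 1", {
  net <- random_network(40, 4, 6, 4, seed = 8)
  model <- initialize_parameters(net, 9)
  cond <- sample_conditions(4, 2, net$ligands, seed = 2)
  X <- project_input(cond, model)
  sett <- simulation_settings(max_steps = 500, tolerance = 1e-10)
  ss_zero <- forward_steady_state(model, X, sett)
  set.seed(33)
  for (rep in 1:3) {
    H0 <- matrix(runif(length(X), -1, 1), nrow(X), ncol(X))
    ss_rand <- forward_steady_state(model, X, sett, init_state = H0)
    expect_equal(ss_rand$states, ss_zero$states, tolerance = 1e-6)
  }
})

test_that("output projection selects and scales TF states", {
  net <- toy_network()
  model <- initialize_parameters(net, 1)
  cond <- sample_conditions(3, 2, net$ligands, seed = 4)
  X <- project_input(cond, model)
  ss <- forward_steady_state(model, X)
  y <- project_output(ss, model)
  expect_equal(y$T1,
               as.numeric(ss$states[match("T1", net$nodes), ]) * 1.2)
  m1 <- model; m1$output_scale <- rep(1, length(net$tfs))
  expect_equal(project_output(ss, m1)$T1,
               as.numeric(ss$states[match("T1", net$nodes), ]))
})

test_that("conditions are exchangeable and batching matches one-by-one", {
  net <- random_network(30, 3, 5, 4, seed = 5)
  model <- initialize_parameters(net, 5)
  cond <- sample_conditions(6, 2, net$ligands, seed = 3)
  y <- predict(model, cond)
  perm <- c(4, 1, 6, 2, 5, 3)
  y_perm <- predict(model, cond[perm, ])
  expect_equal(y_perm, y[perm, ], tolerance = 1e-12)
  # one-at-a-time evaluation agrees (early stopping may differ by an
  # iteration, so agreement is to the convergence tolerance)
  one_by_one <- dplyr::bind_rows(
    lapply(seq_len(nrow(cond)), function(i) predict(model, cond[i, ])))
  expect_equal(one_by_one, y, tolerance = 1e-5)
})

test_that("zero output gradient gives exactly zero parameter gradients", {
  net <- toy_network()
  model <- initialize_parameters(net, 2)
  cond <- sample_conditions(2, 2, net$ligands, seed = 1)
  X <- project_input(cond, model)
  ss <- forward_steady_state(model, X)
  gr <- backward_steady_state(model, ss,
                              matrix(0, 2, length(net$tfs)),
                              conditions = cond)
  expect_true(all(gr$weights == 0))
  expect_true(all(gr$bias == 0))
  expect_true(all(gr$output_scale == 0))
})

test_that("adjoint gradients match finite differences on small chains", {
  net <- chain_network()
  model <- manual_model(net, weights = 0.8, bias = 0.05)
  cond <- tibble::tibble(condition = "c1", L = 0.7)
  obs <- tibble::tibble(condition = "c1", T = 0.4)
  sett <- precise_settings()
  X <- project_input(cond, model)
  ss <- forward_steady_state(model, X, sett)
  err <- as.matrix(predict(model, cond, sett)[, -1]) -
    as.matrix(obs[, -1])
  gr <- backward_steady_state(model, ss, 2 * err / length(err),
                              conditions = cond, settings = sett)
  ana <- unname(c(gr$weights, gr$bias, gr$input_scale, gr$output_scale))
  fd <- fd_gradient(model, cond, obs, sett)
  expect_equal(ana, fd, tolerance = 1e-6)
})

test_that("backpropagation refuses an unconverged forward state", {
  net <- chain_network()
  model <- manual_model(net, weights = 1, bias = 0)
  X <- matrix(c(3, 0), 2, 1, dimnames = list(net$nodes, "c1"))
  ss <- forward_steady_state(model, X, simulation_settings(max_steps = 2))
  expect_error(backward_steady_state(
    model, ss, matrix(1, 1, 1), settings = simulation_settings()),
    "not converged")
})

test_that("node-bias perturbation obeys its contract", {
  net <- chain3_network()
  model <- manual_model(net, weights = 1, bias = 0)
  expect_error(apply_node_bias(model, "L", -5), "ligand")
  expect_error(apply_node_bias(model, "XX", -5), "not in the network")
  same <- apply_node_bias(model, "M", 0)
  expect_identical(same$bias, model$bias)
  ko <- apply_node_bias(model, "M", -5)
  cond <- tibble::tibble(condition = "c1", L = 1)
  X <- project_input(cond, ko)
  ss <- forward_steady_state(ko, X)
  # M receives sigma(3) - 5 < 0: post-activation state ~ 0 (leaky floor)
  hM <- ss$states[match("M", net$nodes), 1]
  expect_lt(abs(hM), 0.05)
  expect_lt(hM, 0)
})
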