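#' Simulation settings
#'
#' @param max_steps Number of forward (and backward) iterations; default
#'   150. Iteration stops early once the residual falls below `tolerance`.
#' @param tolerance Steady-state residual threshold (max absolute change of
#'   any state between consecutive steps); default 1e-6.
#' @param activation An [activation_settings()] object.
#' @param act_kind Activation function: `"mml"` (default), `"leaky_relu"`,
#'   or `"sigmoid"`.
#' @param clip_threshold Gradient-clipping threshold `c` for the backward
#'   pass; default 5, far above ordinary gradient magnitudes so clipping
#'   only engages when gradients genuinely explode.
#' @return A list of class `"sn_settings"`.
#' @export
simulation_settings <- function(max_steps = 150L, tolerance = 1e-6,
                                activation = activation_settings(),
                                act_kind = "mml", clip_threshold = 5) {
  stopifnot(max_steps >= 1, tolerance > 0, clip_threshold > 0)
  structure(list(max_steps = as.integer(max_steps), tolerance = tolerance,
                 activation = activation, act_kind = act_kind,
                 clip_threshold = clip_threshold),
            class = "sn_settings")
}

# conditions tibble (condition + ligand columns) -> s x i numeric matrix
conditions_matrix <- function(conditions, net) {
  stopifnot("condition" %in% names(conditions))
  ligs <- setdiff(names(conditions), "condition")
  unknown <- setdiff(ligs, net$ligands)
  if (length(unknown) > 0)
    stop("condition table column(s) are not ligands of the network: ",
         paste(unknown, collapse = ", "))
  C <- as.matrix(conditions[, ligs, drop = FALSE])
  rownames(C) <- conditions$condition
  C
}

activities_matrix <- function(activities, net) {
  stopifnot("condition" %in% names(activities))
  tfs <- setdiff(names(activities), "condition")
  unknown <- setdiff(tfs, net$tfs)
  if (length(unknown) > 0)
    stop("activity table column(s) are not TFs of the network: ",
         paste(unknown, collapse = ", "))
  Y <- as.matrix(activities[, tfs, drop = FALSE])
  rownames(Y) <- activities$condition
  Y
}

#' Project ligand concentrations onto the network state space
#'
#' Inserts each ligand concentration, multiplied by its input-projection
#' scale, at the ligand's position in a zero-padded node-by-condition
#' matrix; all non-ligand entries are zero.
#'
#' @param conditions Tibble with a `condition` column and one numeric
#'   column per ligand (concentrations in `[0, 1]`).
#' @param model An `sn_model`.
#' @return An n-by-s matrix (nodes by conditions).
#' @export
project_input <- function(conditions, model) {
  net <- model$network
  C <- conditions_matrix(conditions, net)
  X <- matrix(0, length(net$nodes), nrow(C),
              dimnames = list(net$nodes, rownames(C)))
  li <- match(colnames(C), net$ligands)
  X[model$ligand_idx[li], ] <- t(C) * model$input_scale[li]
  X
}

#' Iterate the recurrent model to steady state
#'
#' Starting from the zero state (or a supplied initial state), repeatedly
#' applies `h <- sigma(A h + bias + x)` for up to `max_steps` iterations,
#' stopping early once the largest absolute state change falls below
#' `tolerance`. When the spectral radius of the linearized transition
#' matrix is below 1 the iteration contracts locally and the fixed point is
#' independent of the initial state.
#'
#' @param model An `sn_model`.
#' @param X Projected-input matrix from [project_input()] (nodes x
#'   conditions).
#' @param settings A [simulation_settings()] object.
#' @param init_state Optional nodes-by-conditions starting state.
#' @return An `sn_steady_state`: list with `states` and `pre_activation`
#'   (nodes x conditions), per-condition `residual`, and `steps_used`.
#' @export
forward_steady_state <- function(model, X, settings = simulation_settings(),
                                 init_state = NULL) {
  A <- weight_matrix(model)
  res <- cpp_forward(A, model$bias, X, settings$max_steps,
                     settings$tolerance, act_code(settings$act_kind),
                     settings$activation$leak_slope, init_state)
  dimnames(res$states) <- dimnames(X)
  dimnames(res$pre_activation) <- dimnames(X)
  names(res$residual) <- colnames(X)
  structure(res, class = "sn_steady_state")
}

#' @export
print.sn_steady_state <- function(x, ...) {
  cat("<sn_steady_state> ", ncol(x$states), " condition(s), ",
      nrow(x$states), " nodes; steps used ", x$steps_used,
      "; max residual ", format(max(x$residual)), "\n", sep = "")
  invisible(x)
}

#' Project TF activities from a steady state
#'
#' Selects the TF rows of the steady-state matrix and multiplies each by
#' its trainable output-projection scale.
#'
#' @param ss An `sn_steady_state`.
#' @param model The `sn_model` that produced it.
#' @return A tibble with a `condition` column and one column per TF.
#' @export
project_output <- function(ss, model) {
  net <- model$network
  Yhat <- t(ss$states[model$tf_idx, , drop = FALSE] * model$output_scale)
  colnames(Yhat) <- net$tfs
  tibble::as_tibble(cbind(
    tibble::tibble(condition = colnames(ss$states)),
    as.data.frame(Yhat)))
}

#' Predict TF activities for a set of conditions
#'
#' Runs the full pipeline: input projection, steady-state iteration, and
#' output projection.
#'
#' @param object An `sn_model`.
#' @param conditions Tibble of ligand concentrations (see
#'   [project_input()]).
#' @param settings [simulation_settings()].
#' @param ... Unused.
#' @return Tibble of predicted TF activities, conditions as rows.
#' @export
predict.sn_model <- function(object, conditions,
                             settings = simulation_settings(), ...) {
  X <- project_input(conditions, object)
  ss <- forward_steady_state(object, X, settings)
  project_output(ss, object)
}

#' Backpropagate a loss gradient through the steady state
#'
#' Solves the steady-state adjoint equations by iterating the transposed
#' linearized system: `u <- clip(g + A' (sigma'(z_ss) * u))`, where `g` is
#' the loss gradient with respect to the node states (the output-projected
#' part of `g` is assembled from `dL_dy`). The clip is applied elementwise
#' once per iteration to prevent exploding gradients; it is inactive for
#' ordinary magnitudes. From the converged adjoint, gradients for all
#' parameter blocks follow: the weight gradient is the adjoint/state outer
#' product restricted to the sparse pattern, the bias gradient is the
#' adjoint itself, and the projection-scale gradients contract the adjoint
#' (or `dL_dy`) with the raw inputs (or TF states).
#'
#' @param model An `sn_model`.
#' @param ss A converged `sn_steady_state` for these conditions.
#' @param dL_dy Conditions-by-TF matrix of loss gradients at the outputs.
#' @param conditions The condition tibble used for the forward pass
#'   (needed for the input-scale gradient); may be `NULL` to skip it.
#' @param dL_dh Optional extra conditions-independent gradient directly on
#'   node states (nodes x conditions), e.g. from state regularization.
#' @param settings [simulation_settings()].
#' @param check Refuse to backpropagate from an unconverged forward state
#'   (default `TRUE`; the training loop relaxes this since clipping bounds
#'   the gradients of transiently unstable parameterizations).
#' @return List with `weights`, `bias`, `input_scale`, `output_scale`
#'   gradient vectors, plus adjoint convergence diagnostics.
#' @export
backward_steady_state <- function(model, ss, dL_dy, conditions = NULL,
                                  dL_dh = NULL,
                                  settings = simulation_settings(),
                                  check = TRUE) {
  net <- model$network
  if (check && max(ss$residual) > settings$tolerance * 10)
    stop("forward state not converged (max residual ",
         format(max(ss$residual)), "); refusing to backpropagate")
  n <- length(net$nodes); s <- ncol(ss$states)
  G <- matrix(0, n, s)
  if (!is.null(dL_dy)) {
    stopifnot(ncol(dL_dy) == length(net$tfs), nrow(dL_dy) == s)
    G[model$tf_idx, ] <- G[model$tf_idx, ] +
      t(dL_dy) * model$output_scale
  }
  if (!is.null(dL_dh)) G <- G + dL_dh
  A <- weight_matrix(model)
  bw <- cpp_backward(A, ss$pre_activation, G, settings$max_steps,
                     settings$tolerance, act_code(settings$act_kind),
                     settings$activation$leak_slope,
                     settings$clip_threshold)
  if (any(!is.finite(bw$delta))) stop("non-finite adjoint gradient")
  delta <- bw$delta
  gw <- cpp_weight_grad(model$tgt_idx - 1L, model$src_idx - 1L,
                        delta, ss$states)
  gb <- rowSums(delta)
  gi <- rep(0, length(model$input_scale))
  if (!is.null(conditions)) {
    C <- conditions_matrix(conditions, net)
    li <- match(colnames(C), net$ligands)
    gi[li] <- rowSums(delta[model$ligand_idx[li], , drop = FALSE] * t(C))
  }
  go <- if (is.null(dL_dy)) rep(0, length(model$output_scale)) else
    colSums(dL_dy * t(ss$states[model$tf_idx, , drop = FALSE]))
  list(weights = as.numeric(gw), bias = gb, input_scale = gi,
       output_scale = go, adjoint_residual = bw$residual,
       adjoint_steps = bw$steps_used)
}

#' Offset the bias of a node (perturbation hook)
#'
#' Adds `delta` to the bias of `node`, the primitive behind in-silico
#' knockout (strongly negative offset, conventionally -5, drives the
#' node's state to ~0) and knock-in (positive offset). Ligand nodes cannot
#' be targeted: their levels are model inputs, not internal states.
#'
#' @param model An `sn_model`.
#' @param node Node identifier.
#' @param delta Bias offset.
#' @return A modified copy of the model.
#' @export
apply_node_bias <- function(model, node, delta) {
  net <- model$network
  i <- match(node, net$nodes)
  if (is.na(i)) stop("node '", node, "' is not in the network")
  if (node %in% net$ligands)
    stop("node '", node, "' is a ligand; ligand levels are inputs and ",
         "cannot be perturbed through the bias")
  model$bias[i] <- model$bias[i] + delta
  model
}
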