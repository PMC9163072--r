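new_sn_model <- function(net, weights, bias, input_scale, output_scale) {
  stopifnot(length(weights) == nrow(net$interactions),
            length(bias) == length(net$nodes),
            length(input_scale) == length(net$ligands),
            length(output_scale) == length(net$tfs))
  structure(list(
    network = net,
    weights = as.numeric(weights),
    bias = as.numeric(bias),
    input_scale = as.numeric(input_scale),
    output_scale = as.numeric(output_scale),
    src_idx = match(net$interactions$source, net$nodes),
    tgt_idx = match(net$interactions$target, net$nodes),
    ligand_idx = match(net$ligands, net$nodes),
    tf_idx = match(net$tfs, net$nodes)
  ), class = "sn_model")
}

#' @export
print.sn_model <- function(x, ...) {
  cat("<sn_model> ", length(x$weights), " weights, ", length(x$bias),
      " biases over ", length(x$network$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' Sparse weight matrix of a model
#'
#' Builds the n-by-n sparse interaction matrix `A` (rows = targets,
#' columns = sources) whose non-zero pattern is the network's edge list and
#' whose values are the model's weight vector.
#'
#' @param model An `sn_model`.
#' @return A `dgCMatrix`.
#' @export
weight_matrix <- function(model) {
  n <- length(model$network$nodes)
  Matrix::sparseMatrix(i = model$tgt_idx, j = model$src_idx,
                       x = model$weights, dims = c(n, n))
}

#' Initialize model parameters
#'
#' Weights are drawn uniformly on (0.1, 0.2), negated for inhibitory
#' interactions, and the whole weight matrix is rescaled by `0.8 / rho(A)`
#' so its spectral radius is exactly 0.8, guaranteeing convergent dynamics
#' at the start of training. Biases start at 0.001, except for nodes whose
#' incoming interactions are all inhibitory, which start at 1 so their
#' states can move in the positive regime. Input-projection scales start at
#' 3 (a saturated ligand maps to a node state of ~0.92 under the MML
#' activation) and output-projection scales at 1.2.
#'
#' @param net A reconstructed `sn_network`.
#' @param seed Integer seed; the draw is reproducible.
#' @return An `sn_model`.
#' @export
initialize_parameters <- function(net, seed = 1) {
  stopifnot(inherits(net, "sn_network"))
  m <- nrow(net$interactions)
  if (m == 0) stop("network has no interactions")
  set.seed(seed)
  w <- stats::runif(m, 0, 0.1) + 0.1
  w[net$interactions$moa == -1L] <- -w[net$interactions$moa == -1L]
  model <- new_sn_model(
    net, weights = w,
    bias = rep(0.001, length(net$nodes)),
    input_scale = rep(3, length(net$ligands)),
    output_scale = rep(1.2, length(net$tfs)))
  rho <- cpp_spectral_radius(weight_matrix(model))
  model$weights <- model$weights * (0.8 / rho)
  # nodes whose inputs are all inhibitory start at bias 1
  moa_in <- split(net$interactions$moa, net$interactions$target)
  all_inhib <- names(moa_in)[vapply(moa_in, function(m) all(m == -1L),
                                    logical(1))]
  model$bias[match(all_inhib, net$nodes)] <- 1
  model
}

#' Reference-style parameter initialization
#'
#' The alternative initialization used when parameterizing a reference
#' model for synthetic-data generation (deliberately different from
#' [initialize_parameters()] to preempt information leakage between the
#' reference and models later trained on its data): weights uniform on
#' [0, 3] signed by mode of action and rescaled to spectral radius 0.8;
#' biases uniform on [0, 0.01].
#'
#' @inheritParams initialize_parameters
#' @return An `sn_model`.
#' @export
initialize_reference <- function(net, seed = 1) {
  stopifnot(inherits(net, "sn_network"))
  m <- nrow(net$interactions)
  if (m == 0) stop("network has no interactions")
  set.seed(seed)
  w <- stats::runif(m, 0, 3)
  w[net$interactions$moa == -1L] <- -w[net$interactions$moa == -1L]
  model <- new_sn_model(
    net, weights = w,
    bias = stats::runif(length(net$nodes), 0, 0.01),
    input_scale = rep(3, length(net$ligands)),
    output_scale = rep(1.2, length(net$tfs)))
  rho <- cpp_spectral_radius(weight_matrix(model))
  model$weights <- model$weights * (0.8 / rho)
  model
}

# Reusable sparse-pattern template: the non-zero pattern of A never
# changes during training, so the dgCMatrix is built once and only its
# value slot is refreshed (A@x <- w[perm]). `perm` maps value slots to
# edge indices; `slot_tgt` gives the target (row) node of each slot.
weight_template <- function(model) {
  n <- length(model$network$nodes)
  A <- Matrix::sparseMatrix(i = model$tgt_idx, j = model$src_idx,
                            x = as.numeric(seq_along(model$weights)),
                            dims = c(n, n))
  perm <- as.integer(A@x)
  A@x <- model$weights[perm]
  list(A = A, perm = perm, slot_tgt = A@i + 1L)
}

template_matrix <- function(tmpl, weights, scale_rows = NULL) {
  x <- weights[tmpl$perm]
  if (!is.null(scale_rows)) x <- x * scale_rows[tmpl$slot_tgt]
  A <- tmpl$A
  A@x <- x
  A
}

# parameters as one flat vector (weights, bias, input_scale, output_scale)
# -- used by the optimizer and by finite-difference checks
flatten_params <- function(model) {
  c(model$weights, model$bias, model$input_scale, model$output_scale)
}

unflatten_params <- function(model, theta) {
  nw <- length(model$weights); nb <- length(model$bias)
  ni <- length(model$input_scale)
  model$weights <- theta[seq_len(nw)]
  model$bias <- theta[nw + seq_len(nb)]
  model$input_scale <- theta[nw + nb + seq_len(ni)]
  model$output_scale <- theta[-seq_len(nw + nb + ni)]
  model
}
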