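#' Pearson correlation between two activity tables
#'
#' Flattened Pearson correlation over all shared condition-by-TF pairs
#' (the single-number fit metric), with a two-tailed p-value and per-TF /
#' per-condition breakdowns for diagnostics.
#'
#' @param pred,ref Tibbles with a `condition` column and TF columns;
#'   aligned on condition ids and shared TF columns.
#' @return List with `r`, `p`, `n`, and tibbles `per_tf`, `per_condition`.
#'   Zero variance in either input yields `r = NA` with a warning.
#' @export
pearson_flat <- function(pred, ref) {
  tfs <- intersect(setdiff(names(pred), "condition"),
                   setdiff(names(ref), "condition"))
  if (length(tfs) == 0) stop("no shared TF columns")
  ref <- ref[match(pred$condition, ref$condition), , drop = FALSE]
  if (anyNA(ref$condition)) stop("condition ids do not match")
  P <- as.matrix(pred[, tfs, drop = FALSE])
  R <- as.matrix(ref[, tfs, drop = FALSE])
  sdP <- stats::sd(P); sdR <- stats::sd(R)
  if (length(P) < 3 || is.na(sdP) || is.na(sdR) || sdP == 0 || sdR == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(P),
                per_tf = NULL, per_condition = NULL))
  }
  ct <- stats::cor.test(as.vector(P), as.vector(R))
  safe_cor <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) NA_real_ else
      stats::cor(x, y)
  }
  per_tf <- tibble::tibble(
    tf = tfs,
    r = vapply(seq_along(tfs), function(j) safe_cor(P[, j], R[, j]),
               numeric(1)))
  per_condition <- tibble::tibble(
    condition = pred$condition,
    r = vapply(seq_len(nrow(P)), function(i) safe_cor(P[i, ], R[i, ]),
               numeric(1)))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(P),
       per_tf = per_tf, per_condition = per_condition)
}

scan_bias <- function(model, conditions, nodes, delta,
                      settings = simulation_settings()) {
  control <- predict.sn_model(model, conditions, settings)
  ctrl_long <- tidyr::pivot_longer(control, -"condition", names_to = "tf",
                                   values_to = "control")
  out <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    pm <- apply_node_bias(model, nodes[i], delta)
    pred <- predict.sn_model(pm, conditions, settings)
    pl <- tidyr::pivot_longer(pred, -"condition", names_to = "tf",
                              values_to = "perturbed")
    merged <- dplyr::inner_join(ctrl_long, pl, by = c("condition", "tf"))
    merged$node <- nodes[i]
    out[[i]] <- merged
  }
  res <- dplyr::bind_rows(out)
  res$delta_tf <- res$perturbed - res$control
  res <- res[, c("condition", "node", "tf", "control", "perturbed",
                 "delta_tf")]
  structure(list(results = res, bias_delta = delta, control = control),
            class = "sn_perturbation")
}

#' In-silico knockout scan
#'
#' Simulates knockout of each listed node by adding a strong negative bias
#' (default -5) to it -- which drives the node's post-activation state to
#' approximately zero -- re-running the forward pass for every condition,
#' and recording the change in each TF activity relative to the
#' unperturbed control.
#'
#' @param model A trained `sn_model`.
#' @param conditions Tibble of ligand concentrations.
#' @param nodes Character vector of internal (non-ligand) nodes to knock
#'   out; default all non-ligand nodes.
#' @param delta Bias offset (default -5).
#' @param settings [simulation_settings()].
#' @return An `"sn_perturbation"`: long tibble in `$results` with columns
#'   `condition`, `node`, `tf`, `control`, `perturbed`, `delta_tf`.
#' @export
ko_scan <- function(model, conditions,
                    nodes = setdiff(model$network$nodes,
                                    model$network$ligands),
                    delta = -5, settings = simulation_settings()) {
  stopifnot(delta <= 0)
  scan_bias(model, conditions, nodes, delta, settings)
}

#' In-silico knock-in scan
#'
#' Mirror image of [ko_scan()]: each node is activated by a positive bias
#' offset (default +5, the mirror of the knockout bias), and TF-activity
#' changes relative to control are recorded.
#'
#' @inheritParams ko_scan
#' @param delta Positive bias offset (default +5).
#' @export
knockin_scan <- function(model, conditions,
                         nodes = setdiff(model$network$nodes,
                                         model$network$ligands),
                         delta = 5, settings = simulation_settings()) {
  stopifnot(delta >= 0)
  scan_bias(model, conditions, nodes, delta, settings)
}

#' @export
print.sn_perturbation <- function(x, ...) {
  cat("<sn_perturbation> ", length(unique(x$results$node)), " node(s) x ",
      length(unique(x$results$condition)), " condition(s), bias ",
      x$bias_delta, "\n", sep = "")
  invisible(x)
}

#' Sensitivity analysis of TF activities to signaling-node perturbations
#'
#' For each condition the unperturbed steady state is simulated and each
#' node's raw (pre-activation) state `z` recorded. Each node is then
#' perturbed by adding `epsilon * z` to the input term at that node and
#' the simulation re-run. The change in each TF activity is scaled by
#' `1/epsilon` (x100 for the default 0.01) and divided by the perturbed
#' node's raw state -- the perturbation's own scale -- to give the
#' sensitivity; the raw activity change is returned alongside. Nodes with
#' zero raw state receive a zero perturbation and are flagged with
#' sensitivity 0.
#'
#' @param model A trained `sn_model`.
#' @param conditions Tibble of ligand concentrations.
#' @param nodes Nodes to perturb (default all non-ligand nodes).
#' @param epsilon Relative perturbation size (default 0.01).
#' @param threshold Absolute-sensitivity cutoff for the strong-effect
#'   summary (default 0.5).
#' @param settings [simulation_settings()].
#' @return An `"sn_sensitivity"`: long tibble in `$results` (`condition`,
#'   `node`, `tf`, `delta`, `sensitivity`), and `$strong_nodes`, the nodes
#'   whose maximum absolute sensitivity reaches `threshold` in at least
#'   one condition.
#' @export
sensitivity_analysis <- function(model, conditions,
                                 nodes = setdiff(model$network$nodes,
                                                 model$network$ligands),
                                 epsilon = 0.01, threshold = 0.5,
                                 settings = simulation_settings()) {
  net <- model$network
  X <- project_input(conditions, model)
  ref <- forward_steady_state(model, X, settings)
  ref_y <- project_output(ref, model)
  ref_long <- tidyr::pivot_longer(ref_y, -"condition", names_to = "tf",
                                  values_to = "reference")
  out <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    ni <- match(nodes[i], net$nodes)
    if (is.na(ni)) stop("node '", nodes[i], "' is not in the network")
    z <- ref$pre_activation[ni, ]
    if (all(z == 0))
      message("node ", nodes[i],
              " has zero pre-activation in all conditions; sensitivity 0")
    Xp <- X
    Xp[ni, ] <- Xp[ni, ] + epsilon * z
    pert <- forward_steady_state(model, Xp, settings)
    pert_y <- project_output(pert, model)
    pl <- tidyr::pivot_longer(pert_y, -"condition", names_to = "tf",
                              values_to = "perturbed")
    merged <- dplyr::inner_join(ref_long, pl, by = c("condition", "tf"))
    merged$node <- nodes[i]
    merged$z <- z[match(merged$condition, colnames(ref$states))]
    out[[i]] <- merged
  }
  res <- dplyr::bind_rows(out)
  res$delta <- res$perturbed - res$reference
  # delta / (epsilon * z): activity change per unit relative perturbation
  res$sensitivity <- ifelse(res$z == 0, 0, res$delta / (epsilon * res$z))
  res <- res[, c("condition", "node", "tf", "delta", "sensitivity")]
  strong <- res |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(max_abs = max(abs(.data$sensitivity)),
                     .groups = "drop")
  structure(list(results = res, threshold = threshold,
                 strong_nodes = strong$node[strong$max_abs >= threshold],
                 node_summary = strong, epsilon = epsilon),
            class = "sn_sensitivity")
}

#' @export
print.sn_sensitivity <- function(x, ...) {
  cat("<sn_sensitivity> ", nrow(x$node_summary), " node(s); ",
      length(x$strong_nodes), " with |sensitivity| >= ", x$threshold,
      "\n", sep = "")
  invisible(x)
}
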