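#' Tidy a signaling model
#'
#' Returns one row per parameter: weights (with source/target and mode of
#' action), biases, and input/output projection scales.
#'
#' @param x An `sn_model`.
#' @param ... Unused.
#' @return A tibble with columns `type`, `source`, `target`, `moa`,
#'   `value`.
#' @export
tidy.sn_model <- function(x, ...) {
  net <- x$network
  dplyr::bind_rows(
    tibble::tibble(type = "weight", source = net$interactions$source,
                   target = net$interactions$target,
                   moa = net$interactions$moa, value = x$weights),
    tibble::tibble(type = "bias", source = net$nodes,
                   target = NA_character_, moa = NA_integer_,
                   value = x$bias),
    tibble::tibble(type = "input_projection", source = net$ligands,
                   target = NA_character_, moa = NA_integer_,
                   value = x$input_scale),
    tibble::tibble(type = "output_projection", source = net$tfs,
                   target = NA_character_, moa = NA_integer_,
                   value = x$output_scale))
}

#' @rdname tidy.sn_model
#' @export
glance.sn_model <- function(x, ...) {
  net <- x$network
  sv <- sign_violation_loss(x)
  tibble::tibble(
    n_nodes = length(net$nodes), n_edges = nrow(net$interactions),
    n_ligands = length(net$ligands), n_tfs = length(net$tfs),
    n_parameters = length(x$weights) + length(x$bias) +
      length(x$output_scale),
    sign_violation = as.numeric(sv))
}

#' Tidy a fitted training run
#'
#' @param x An `sn_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `lr`, `loss` and the
#'   per-term breakdown).
#' @export
tidy.sn_fit <- function(x, ...) x$history

#' @rdname tidy.sn_fit
#' @export
glance.sn_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    final_fit_mse = utils::tail(x$history$fit_mse, 1),
    train_r = x$train_r,
    max_residual = utils::tail(x$history$max_residual, 1))
}

#' Tidy cross-validation results
#'
#' @param x An `sn_cv` from [crossvalidate()].
#' @param ... Unused.
#' @return Tibble of held-out predictions with fold labels.
#' @export
tidy.sn_cv <- function(x, ...) x$predictions

#' @rdname tidy.sn_cv
#' @export
glance.sn_cv <- function(x, ...) {
  tibble::tibble(folds = length(x$fold_r), pooled_r = x$pooled_r,
                 mean_fold_r = mean(x$fold_r), min_fold_r = min(x$fold_r))
}

#' Tidy a perturbation scan
#'
#' @param x An `sn_perturbation` from [ko_scan()] or [knockin_scan()].
#' @param ... Unused.
#' @return Long tibble with `condition`, `node`, `tf`, `control`,
#'   `perturbed`, `delta_tf`.
#' @export
tidy.sn_perturbation <- function(x, ...) x$results

#' Tidy a sensitivity analysis
#'
#' @param x An `sn_sensitivity` from [sensitivity_analysis()].
#' @param ... Unused.
#' @return Long tibble with `condition`, `node`, `tf`, `delta`,
#'   `sensitivity`.
#' @export
tidy.sn_sensitivity <- function(x, ...) x$results

#' Plot the training history of a fitted model
#'
#' Loss components per epoch on a log scale.
#'
#' @param object An `sn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$history[, c("epoch", "loss", "fit_mse", "state", "spectral",
                       "param")],
    -"epoch", names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot held-out predictions against observations
#'
#' @param object An `sn_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sn_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "observed TF activity", y = "predicted TF activity",
      subtitle = sprintf("pooled r = %.3f", object$pooled_r)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of perturbation effects
#'
#' Top nodes ranked by median absolute TF-activity change.
#'
#' @param object An `sn_perturbation`.
#' @param top Number of nodes shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sn_perturbation <- function(object, top = 10, ...) {
  ranked <- object$results |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(effect = stats::median(abs(.data$delta_tf)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$effect)) |>
    utils::head(top)
  sub <- object$results[object$results$node %in% ranked$node, ]
  sub$node <- factor(sub$node, levels = rev(ranked$node))
  ggplot2::ggplot(sub, ggplot2::aes(.data$node, .data$delta_tf)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "change in TF activity vs control") +
    ggplot2::theme_minimal()
}

#' Heatmap of maximum absolute sensitivities
#'
#' @param object An `sn_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sn_sensitivity <- function(object, ...) {
  mx <- object$results |>
    dplyr::group_by(.data$node, .data$tf) |>
    dplyr::summarise(sensitivity = .data$sensitivity[
      which.max(abs(.data$sensitivity))], .groups = "drop")
  ggplot2::ggplot(mx, ggplot2::aes(.data$tf, .data$node,
                                   fill = .data$sensitivity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "TF", y = "perturbed node",
                  fill = "max sensitivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
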