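#' Training configuration
#'
#' @param epochs Number of epochs (default 10000, the full-scale budget;
#'   small studies use far fewer).
#' @param batch_size Conditions per stochastic gradient step (default 5).
#' @param lr Base learning rate for the ADAM optimizer (default 2e-3).
#' @param restart_period Length (epochs) of the first cosine period
#'   (default 100).
#' @param period_growth Multiplier applied to the period at each warm
#'   restart (default 2).
#' @param min_lr Learning rate at the end of each cosine period (default
#'   `lr / 100`).
#' @param beta1,beta2,adam_eps ADAM moment decay rates and epsilon
#'   (conventional defaults).
#' @param max_grad_norm Global gradient-norm cap per step (default 5);
#'   protects the adaptive moments from the gradient spikes of
#'   transiently unstable batches.
#' @param regularization A [regularization_config()].
#' @param seed Integer seed controlling initialization, batching, and
#'   noise; training is reproducible given the seed (single-threaded).
#' @return A list of class `"sn_training"`.
#' @export
training_config <- function(epochs = 10000L, batch_size = 5L, lr = 2e-3,
                            restart_period = 100L, period_growth = 2,
                            min_lr = lr / 100, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, max_grad_norm = 5,
                            regularization = regularization_config(),
                            seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, restart_period >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 restart_period = as.integer(restart_period),
                 period_growth = period_growth, min_lr = min_lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 max_grad_norm = max_grad_norm,
                 regularization = regularization, seed = as.integer(seed)),
            class = "sn_training")
}

#' Cosine learning-rate schedule with warm restarts
#'
#' Within each period the learning rate decays from `lr` to `min_lr`
#' along a half cosine; at each restart it jumps back to `lr` and the
#' period length is multiplied by `period_growth`.
#'
#' @param config A [training_config()].
#' @return Numeric vector of per-epoch learning rates, length
#'   `config$epochs`.
#' @export
make_schedule <- function(config) {
  out <- numeric(config$epochs)
  period <- config$restart_period
  t <- 0
  for (e in seq_len(config$epochs)) {
    frac <- if (period > 1) t / (period - 1) else 0
    out[e] <- config$min_lr +
      0.5 * (config$lr - config$min_lr) * (1 + cos(pi * frac))
    t <- t + 1
    if (t >= period) {
      t <- 0
      period <- max(1L, as.integer(round(period * config$period_growth)))
    }
  }
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, config) {
  state$t <- state$t + 1L
  state$m <- config$beta1 * state$m + (1 - config$beta1) * grad
  state$v <- config$beta2 * state$v + (1 - config$beta2) * grad^2
  mhat <- state$m / (1 - config$beta1^state$t)
  vhat <- state$v / (1 - config$beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + config$adam_eps),
       state = state)
}

# regularization losses and gradients that depend only on the parameters
param_reg_terms <- function(model, reg) {
  sv <- sign_violation_loss(model)
  lb <- ligand_bias_loss(model)
  az <- if (reg$antizero_enabled) antizero_loss(model$weights) else
    structure(0, grad = numeric(length(model$weights)))
  l2 <- reg$l2_coeff * (sum(model$weights^2) + sum(model$bias^2))
  gw <- reg$moa_coeff * attr(sv, "grad") +
    reg$antizero_coeff * attr(az, "grad") + 2 * reg$l2_coeff * model$weights
  gb <- reg$ligand_bias_coeff * attr(lb, "grad") +
    2 * reg$l2_coeff * model$bias
  list(loss = reg$moa_coeff * as.numeric(sv) +
         reg$ligand_bias_coeff * as.numeric(lb) +
         reg$antizero_coeff * as.numeric(az) + l2,
       sign_loss = as.numeric(sv), ligand_bias = as.numeric(lb),
       antizero = as.numeric(az), l2 = l2, gw = gw, gb = gb)
}

#' Train a model on ligand-to-TF data
#'
#' Minimizes the mean squared error between predicted and observed TF
#' activities plus all regularization terms (mode-of-action sign
#' constraint, ligand-bias constraint, L2, anti-zero weights, state
#' uniformity with a stale-statistics store, and the spectral-radius
#' barrier applied to one steady state per batch -- a random one, or the
#' unconverged one when the batch contains one) by stochastic gradient
#' descent with ADAM, a cosine warm-restart schedule, and bias noise
#' proportional to the current learning rate. Conditions whose forward
#' pass has not converged contribute no fit gradient for that step, and
#' the global gradient norm is capped (see `max_grad_norm`).
#'
#' @param net A reconstructed `sn_network`.
#' @param conditions Tibble of ligand concentrations (`condition` column +
#'   one column per ligand).
#' @param activities Tibble of observed TF activities (same `condition`
#'   ids).
#' @param config A [training_config()].
#' @param settings [simulation_settings()].
#' @param init Optional starting `sn_model` (default: fresh
#'   [initialize_parameters()] with the config seed).
#' @param verbose Print progress every 100 epochs.
#' @return An object of class `"sn_fit"`: list with the trained `model`, a
#'   per-epoch `history` tibble, and the final training predictions.
#' @export
train_model <- function(net, conditions, activities,
                        config = training_config(),
                        settings = simulation_settings(), init = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(net, "sn_network"))
  stopifnot(nrow(conditions) >= 1,
            identical(conditions$condition, activities$condition))
  reg <- config$regularization
  model <- if (is.null(init)) initialize_parameters(net, config$seed) else
    init
  Y <- activities_matrix(activities, net)
  tf_cols <- match(net$tfs, colnames(Y))
  if (anyNA(tf_cols))
    stop("activity table must cover every TF of the network")
  Y <- Y[, tf_cols, drop = FALSE]
  s_all <- nrow(conditions)
  n <- length(net$nodes)
  set.seed(config$seed)
  lr_sched <- make_schedule(config)
  X_all <- project_input(conditions, model)

  # stale-statistics store of per-condition states (conditions x nodes)
  ss0 <- forward_steady_state(model, X_all, settings)
  store <- t(ss0$states)

  theta <- flatten_params(model)
  opt <- adam_init(length(theta))
  nw <- length(model$weights); nb <- length(model$bias)
  ni <- length(model$input_scale)
  tmpl <- weight_template(model)
  acode <- act_code(settings$act_kind)
  leak <- settings$activation$leak_slope
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_sched[epoch]
    perm <- sample.int(s_all)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep <- c(fit = 0, state = 0, spectral = 0, param = 0, total = 0,
            max_resid = 0, sign = 0, ligand_bias = 0, antizero = 0,
            l2 = 0)
    for (bi in batches) {
      nbi <- length(bi)
      noisy_bias <- model$bias +
        reg$noise_factor * lr * stats::rnorm(nb)
      A <- template_matrix(tmpl, model$weights)
      fw <- cpp_forward(A, noisy_bias, X_all[, bi, drop = FALSE],
                        settings$max_steps, settings$tolerance, acode,
                        leak, NULL)
      store[bi, ] <- t(fw$states)
      Yhat <- t(fw$states[model$tf_idx, , drop = FALSE] *
                  model$output_scale)
      err <- Yhat - Y[bi, , drop = FALSE]
      fit_loss <- mean(err^2)
      dL_dy <- 2 * err / length(err)
      # predictions are only defined at steady state: conditions that
      # failed to converge contribute no fit gradient (the spectral
      # barrier below restores their stability first)
      unstable <- fw$residual > 100 * settings$tolerance
      if (any(unstable)) dL_dy[unstable, ] <- 0

      su <- state_uniformity_loss(store, bi, reg)
      G <- reg$state_coeff * t(su$grad)
      G[model$tf_idx, ] <- G[model$tf_idx, ] + t(dL_dy) * model$output_scale

      bw <- cpp_backward(A, fw$pre_activation, G, settings$max_steps,
                         settings$tolerance, acode, leak,
                         settings$clip_threshold)
      pt <- param_reg_terms(model, reg)
      gw <- as.numeric(cpp_weight_grad(model$tgt_idx - 1L,
                                       model$src_idx - 1L, bw$delta,
                                       fw$states)) + pt$gw
      gb <- rowSums(bw$delta) + pt$gb
      go <- colSums(dL_dy * t(fw$states[model$tf_idx, , drop = FALSE]))
      spec_loss <- 0
      if (reg$spectral_coeff > 0) {
        # one steady state per batch is regularized, chosen at random;
        # when a condition failed to converge it takes priority, since
        # restoring stability is the barrier's purpose
        ci <- if (any(unstable)) which.max(fw$residual) else
          sample.int(nbi, 1)
        spv <- act_apply_grad(fw$pre_activation[, ci], settings$act_kind,
                              settings$activation)
        Tm <- template_matrix(tmpl, model$weights, scale_rows = spv)
        eg <- tryCatch(cpp_dominant_eigs(Tm, 3L, 1e-3),
                       error = function(e) NULL)
        if (!is.null(eg)) {
          spec <- structure(list(rho = eg$rho, lambda = eg$lambda,
                                 right_vec = eg$right_vec,
                                 left_vec = eg$left_vec, sp = spv),
                            class = "sn_spectrum")
          sl <- tryCatch(
            spectral_radius_loss(spec, model$src_idx, model$tgt_idx, reg),
            error = function(e) NULL)
          if (!is.null(sl)) {
            spec_loss <- reg$spectral_coeff * as.numeric(sl)
            gsl <- attr(sl, "grad")
            # trust-region cap keeps steps finite when rho >> target;
            # an unconverged condition boosts the barrier (emergency
            # brake) since its fit gradient is suspended
            cap <- 10 * reg$spectral_k
            fac <- min(1, cap / max(as.numeric(sl) * reg$spectral_k, 1))
            boost <- if (any(unstable)) 20 else 1
            gw <- gw + boost * reg$spectral_coeff * fac * gsl
          }
        }
      }
      state_loss <- reg$state_coeff * su$loss
      total <- fit_loss + state_loss + spec_loss + pt$loss
      if (!is.finite(total))
        stop("training loss diverged (non-finite) at epoch ", epoch)
      # input scales stay fixed: ligand concentrations are inputs and the
      # data cannot identify the scales separately from receptor weights
      grad <- c(gw, gb, numeric(ni), go)
      # cap the global gradient norm so a single unstable batch cannot
      # poison the optimizer's second-moment estimates
      gn <- sqrt(sum(grad^2))
      if (gn > config$max_grad_norm)
        grad <- grad * (config$max_grad_norm / gn)
      st <- adam_step(opt, theta, grad, lr, config)
      theta <- st$theta; opt <- st$state
      model <- unflatten_params(model, theta)
      ep <- ep + c(fit_loss, state_loss, spec_loss, pt$loss, total,
                   max(0, max(fw$residual)), pt$sign_loss,
                   pt$ligand_bias, pt$antizero, pt$l2)
    }
    nbatch <- length(batches)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = ep[["total"]] / nbatch,
      fit_mse = ep[["fit"]] / nbatch, state = ep[["state"]] / nbatch,
      spectral = ep[["spectral"]] / nbatch, param = ep[["param"]] / nbatch,
      sign = ep[["sign"]] / nbatch,
      ligand_bias = ep[["ligand_bias"]] / nbatch,
      antizero = ep[["antizero"]] / nbatch, l2 = ep[["l2"]] / nbatch,
      max_residual = ep[["max_resid"]] / nbatch)
    if (verbose && epoch %% 100 == 0)
      message(sprintf("epoch %d  lr %.2e  loss %.4g  fit %.4g", epoch, lr,
                      ep[["total"]] / nbatch, ep[["fit"]] / nbatch))
  }

  history <- dplyr::bind_rows(hist)
  preds <- predict.sn_model(model, conditions, settings)
  fitr <- pearson_flat(preds, activities)
  structure(list(model = model, history = history, predictions = preds,
                 observed = activities, train_r = fitr$r,
                 config = config, settings = settings),
            class = "sn_fit")
}

#' @export
print.sn_fit <- function(x, ...) {
  cat("<sn_fit> ", nrow(x$history), " epochs; final loss ",
      format(utils::tail(x$history$loss, 1)), "; train r ",
      format(x$train_r, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Scramble condition labels of an activity table
#'
#' Permutes the rows of the TF-activity table with a seeded non-identity
#' permutation while leaving the ligand inputs untouched, destroying the
#' input-output relation. Models trained on scrambled data provide the
#' negative control against which generalization is judged.
#'
#' @param activities Tibble of TF activities (>= 2 conditions).
#' @param seed Integer seed.
#' @return Tibble with the same `condition` column but permuted activity
#'   rows.
#' @export
scramble_labels <- function(activities, seed = 1L) {
  s <- nrow(activities)
  if (s < 2) stop("need at least 2 conditions to scramble")
  set.seed(seed)
  repeat {
    perm <- sample.int(s)
    if (any(perm != seq_len(s))) break
  }
  out <- activities
  out[, setdiff(names(out), "condition")] <-
    activities[perm, setdiff(names(activities), "condition")]
  out
}

#' Cross-validated training
#'
#' Splits conditions into folds, trains a fresh model per fold, and
#' evaluates predictions on the held-out conditions. Warns when a ligand
#' active in a test fold never appears in the corresponding training set
#' (its receptor weights are then unconstrained by data).
#'
#' @param net A reconstructed `sn_network`.
#' @param conditions,activities Data tibbles as in [train_model()].
#' @param folds Number of folds (integer) or a list of integer index
#'   vectors defining the test set of each fold.
#' @param config A [training_config()].
#' @param settings [simulation_settings()].
#' @param verbose Passed to [train_model()].
#' @return An `"sn_cv"` object: tibble of held-out predictions
#'   (`condition`, `tf`, `observed`, `predicted`, `fold`), per-fold and
#'   pooled Pearson correlations.
#' @export
crossvalidate <- function(net, conditions, activities, folds = 5L,
                          config = training_config(),
                          settings = simulation_settings(),
                          verbose = FALSE) {
  s <- nrow(conditions)
  if (is.numeric(folds) && length(folds) == 1) {
    set.seed(config$seed)
    idx <- sample.int(s)
    folds <- split(idx, cut(seq_len(s), folds, labels = FALSE))
  }
  if (any(lengths(folds) == 0)) stop("every fold must hold out >= 1 condition")
  C <- conditions_matrix(conditions, net)
  rows <- list()
  fold_r <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(s), test)
    if (length(train) == 0) stop("fold ", f, " leaves no training data")
    test_ligs <- colnames(C)[colSums(C[test, , drop = FALSE] != 0) > 0]
    train_ligs <- colnames(C)[colSums(C[train, , drop = FALSE] != 0) > 0]
    unseen <- setdiff(test_ligs, train_ligs)
    if (length(unseen) > 0)
      warning("fold ", f, ": ligand(s) only active in the test set: ",
              paste(unseen, collapse = ", "))
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_model(net, conditions[train, , drop = FALSE],
                       activities[train, , drop = FALSE], cfg, settings,
                       verbose = verbose)
    pred <- predict.sn_model(fit$model, conditions[test, , drop = FALSE],
                             settings)
    obs_long <- tidyr::pivot_longer(activities[test, , drop = FALSE],
                                    -"condition", names_to = "tf",
                                    values_to = "observed")
    pred_long <- tidyr::pivot_longer(pred, -"condition", names_to = "tf",
                                     values_to = "predicted")
    merged <- dplyr::inner_join(obs_long, pred_long,
                                by = c("condition", "tf"))
    merged$fold <- f
    rows[[f]] <- merged
    fold_r[f] <- stats::cor(merged$observed, merged$predicted)
  }
  all_rows <- dplyr::bind_rows(rows)
  structure(list(predictions = all_rows, fold_r = fold_r,
                 pooled_r = stats::cor(all_rows$observed,
                                       all_rows$predicted),
                 folds = folds),
            class = "sn_cv")
}

#' @export
print.sn_cv <- function(x, ...) {
  cat("<sn_cv> ", length(x$fold_r), " folds; pooled r = ",
      format(x$pooled_r, digits = 3), "\n", sep = "")
  invisible(x)
}
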