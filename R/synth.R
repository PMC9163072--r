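#' Minimal demonstration signaling network
#'
#' A seven-node network -- two ligands (L1, L2), two receptors (R1, R2),
#' two signaling proteins (S1, S2), one TF (T1) -- wired by eight
#' interactions including an inhibitory input to the TF and a negative
#' feedback loop from the TF onto the signaling layer. Useful for
#' demonstrations and for parameter-recovery studies where the topology is
#' identifiable.
#'
#' @return A reconstructed `sn_network`.
#' @export
toy_network <- function() {
  interactions <- tibble::tibble(
    source = c("L1", "L2", "R1", "R2", "S1", "S2", "S1", "T1"),
    target = c("R1", "R2", "S1", "S2", "T1", "T1", "S2", "S1"),
    moa = c(1L, 1L, 1L, 1L, 1L, -1L, 1L, -1L),
    reversible = FALSE,
    references = list(character(0)),
    pubmed = list(character(0)))
  annotations <- tibble::tibble(
    id = c("L1", "L2", "R1", "R2", "S1", "S2", "T1"),
    roles = list("ligand", "ligand", "receptor", "receptor", "signaling",
                 "signaling", "TF"),
    synonym = c("ligand 1", "ligand 2", "receptor 1", "receptor 2",
                "kinase 1", "kinase 2", "factor 1"))
  reconstruct(signaling_network(interactions, annotations))
}

#' Random signaling-network fixture
#'
#' Generates a connected directed network with biological-like structure:
#' ligands feed receptors, an internal signaling layer with
#' preferential-attachment out-degrees (hubs) and feedback edges, and TF
#' sinks. Every node lies on a directed ligand-to-TF path, so
#' [reconstruct()] leaves the network unchanged. Modes of action are
#' drawn randomly (activating with probability 0.75).
#'
#' @param n_nodes Total node count.
#' @param n_ligands,n_tfs Number of ligand and TF nodes
#'   (`n_ligands + n_tfs < n_nodes`).
#' @param mean_out_degree Average edges per node; total edge count is
#'   approximately `n_nodes * mean_out_degree`.
#' @param seed Integer seed; generation is deterministic.
#' @return An `sn_network` (already in reconstructed form).
#' @export
random_network <- function(n_nodes, n_ligands, n_tfs, mean_out_degree = 4,
                           seed = 1L) {
  if (n_ligands + n_tfs >= n_nodes)
    stop("n_ligands + n_tfs must be smaller than n_nodes")
  n_int <- n_nodes - n_ligands - n_tfs
  if (n_int < 2) stop("need at least 2 internal nodes")
  set.seed(seed)
  ligands <- sprintf("L%04d", seq_len(n_ligands))
  internals <- sprintf("S%04d", seq_len(n_int))
  tfs <- sprintf("T%04d", seq_len(n_tfs))

  m_target <- round(n_nodes * mean_out_degree)
  src <- character(m_target * 2); tgt <- character(m_target * 2)
  ne <- 0L
  add_edge <- function(s, t) {
    ne <<- ne + 1L
    src[ne] <<- s
    tgt[ne] <<- t
  }
  # backbone in a random internal order: guarantees ligand -> ... -> TF
  order_int <- sample(internals)
  n_rec <- max(n_ligands, ceiling(n_int * 0.15))
  receptors <- order_int[seq_len(min(n_rec, n_int))]
  for (l in ligands) add_edge(l, sample(receptors, 1))
  used_rec <- unique(tgt[seq_len(ne)])
  for (r in setdiff(receptors, used_rec)) {
    # unused receptor: attach an extra ligand edge so it is reachable
    add_edge(sample(ligands, 1), r)
  }
  is_receptor <- order_int %in% receptors
  for (i in seq_along(order_int)) {
    v <- order_int[i]
    if (!is_receptor[i] && i > 1)
      add_edge(order_int[sample.int(i - 1, 1)], v)
    if (i < length(order_int))
      add_edge(v, order_int[i + sample.int(length(order_int) - i, 1)])
    else
      add_edge(v, sample(tfs, 1))
  }
  for (t in setdiff(tfs, tgt[seq_len(ne)]))
    add_edge(sample(internals, 1), t)

  # fill with preferential-attachment extras (hubs), feedback allowed
  key <- function(s, t) paste(s, t, sep = "\r")
  seen <- new.env(hash = TRUE)
  for (k in key(src[seq_len(ne)], tgt[seq_len(ne)]))
    assign(k, TRUE, envir = seen)
  sources_pool <- c(ligands, internals)
  out_deg <- stats::setNames(rep(0, length(sources_pool)), sources_pool)
  tab <- table(src[seq_len(ne)])
  out_deg[names(tab)] <- as.numeric(tab)
  attempts <- 0
  while (ne < m_target && attempts < m_target * 30) {
    attempts <- attempts + 1
    s <- sample(sources_pool, 1, prob = out_deg + 1)
    t <- if (s %in% ligands) sample(receptors, 1) else
      sample(c(internals, tfs), 1)
    if (s == t || exists(key(s, t), envir = seen)) next
    add_edge(s, t)
    assign(key(s, t), TRUE, envir = seen)
    out_deg[s] <- out_deg[s] + 1
  }
  src <- src[seq_len(ne)]; tgt <- tgt[seq_len(ne)]

  moa <- sample(c(1L, -1L), length(src), replace = TRUE,
                prob = c(0.75, 0.25))
  interactions <- tibble::tibble(
    source = src, target = tgt, moa = moa, reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  interactions <- interactions[!duplicated(interactions[, 1:2]), ]
  role_of <- function(id) {
    if (id %in% ligands) "ligand"
    else if (id %in% receptors) "receptor"
    else if (id %in% tfs) "TF"
    else "signaling"
  }
  ids <- c(ligands, internals, tfs)
  annotations <- tibble::tibble(
    id = ids, roles = lapply(ids, role_of), synonym = ids)
  reconstruct(signaling_network(interactions, annotations))
}

#' Sample random stimulation conditions
#'
#' Each condition activates exactly `k` distinct ligands with
#' concentrations drawn uniformly on (0, 1]; all other ligands are 0.
#'
#' @param n Number of conditions.
#' @param k Simultaneous ligands per condition (default 5).
#' @param ligands Character vector of ligand ids.
#' @param seed Integer seed.
#' @param prefix Condition-id prefix.
#' @return Tibble with `condition` plus one column per ligand.
#' @export
sample_conditions <- function(n, k = 5, ligands, seed = 1L,
                              prefix = "cond") {
  stopifnot(k <= length(ligands), k >= 1, n >= 1)
  set.seed(seed)
  C <- matrix(0, n, length(ligands),
              dimnames = list(NULL, ligands))
  for (i in seq_len(n)) {
    act <- sample.int(length(ligands), k)
    C[i, act] <- 1 - stats::runif(k) # uniform on (0, 1]
  }
  dplyr::bind_cols(
    tibble::tibble(condition = sprintf("%s%05d", prefix, seq_len(n))),
    tibble::as_tibble(C))
}

# mean absolute pairwise correlation of the columns of Y, with gradient;
# columns with (near) zero variance are skipped
corr_mean_loss <- function(Y, eps = 1e-10) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  nrm <- sqrt(colSums(Yc^2))
  ok <- which(nrm > eps)
  G <- matrix(0, n, ncol(Y))
  if (length(ok) < 2 || n < 3)
    return(list(loss = 0, grad = G))
  Z <- sweep(Yc[, ok, drop = FALSE], 2, nrm[ok], `/`)
  C <- crossprod(Z)
  S <- sign(C)
  diag(S) <- 0
  npair <- length(ok) * (length(ok) - 1) / 2
  loss <- sum(abs(C[upper.tri(C)])) / npair
  Gz <- Z %*% S / npair # d sum_{i<j}|C_ij|/dZ = Z S (S symmetric, diag 0)
  # chain through z = yc / ||yc||, then through centering
  Gy <- sweep(Gz - sweep(Z, 2, colSums(Gz * Z), `*`), 2, nrm[ok], `/`)
  Gy <- sweep(Gy, 2, colMeans(Gy))
  G[, ok] <- Gy
  list(loss = loss, grad = G)
}

#' Reference-model parameterization settings
#'
#' @param conditions_per_epoch Random conditions resampled each epoch
#'   (default 200).
#' @param ligands_per_condition Simultaneous ligands per condition
#'   (default 5, capped at the ligand count).
#' @param epochs Optimization epochs (default 2000).
#' @param lr ADAM learning rate (default 5e-3).
#' @param spectral_coeff Spectral-barrier coefficient (default 1e-2).
#' @param l2_coeff L2 coefficient on weights and biases (default 1e-6).
#' @param output_uniform_coeff Coefficient on the output-uniformity terms
#'   (default 1).
#' @param corr_coeff Coefficient on the mean-correlation term (default 1).
#' @param seed Integer seed.
#' @return List of class `"sn_reference_spec"`.
#' @export
reference_spec <- function(conditions_per_epoch = 200L,
                           ligands_per_condition = 5L, epochs = 2000L,
                           lr = 5e-3, spectral_coeff = 1e-2,
                           l2_coeff = 1e-6, output_uniform_coeff = 1,
                           corr_coeff = 1, seed = 1L) {
  structure(list(conditions_per_epoch = as.integer(conditions_per_epoch),
                 ligands_per_condition = as.integer(ligands_per_condition),
                 epochs = as.integer(epochs), lr = lr,
                 spectral_coeff = spectral_coeff, l2_coeff = l2_coeff,
                 output_uniform_coeff = output_uniform_coeff,
                 corr_coeff = corr_coeff, seed = as.integer(seed)),
            class = "sn_reference_spec")
}

#' Automatically parameterize a reference model
#'
#' Randomly parameterized biological topologies produce near-constant TF
#' outputs; this optimizer finds parameters whose TF activities vary
#' richly across random ligand stimulations, so the model can serve as a
#' ground-truth generator of synthetic datasets. Each epoch draws fresh
#' random conditions and minimizes, simultaneously: the mean absolute
#' pairwise correlation of the TF-output matrix across conditions and
#' across TFs (discouraging redundant responses); deviations of the
#' output distribution from uniform on [0.01, 0.99], across conditions
#' and across TFs; the L2 norm of weights and biases; the mode-of-action
#' and ligand-bias constraints; and the spectral-radius barrier (one
#' random condition per epoch). Initialization is deliberately different
#' from training initialization (see [initialize_reference()]).
#'
#' @param net A reconstructed `sn_network`.
#' @param spec A [reference_spec()].
#' @param settings [simulation_settings()].
#' @param verbose Print progress every 100 epochs.
#' @return An `sn_model` whose TF outputs vary across random inputs, with
#'   the optimization trace in `attr(, "history")`.
#' @export
parameterize_reference <- function(net, spec = reference_spec(),
                                   settings = simulation_settings(),
                                   verbose = FALSE) {
  stopifnot(inherits(net, "sn_network"))
  k <- min(spec$ligands_per_condition, length(net$ligands))
  model <- initialize_reference(net, spec$seed)
  reg <- regularization_config(l2_coeff = spec$l2_coeff,
                               spectral_coeff = spec$spectral_coeff,
                               antizero_enabled = FALSE)
  theta <- flatten_params(model)
  opt <- adam_init(length(theta))
  nw <- length(model$weights); nb <- length(model$bias)
  cfg <- list(beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8)
  hist <- vector("list", spec$epochs)
  set.seed(spec$seed)
  for (epoch in seq_len(spec$epochs)) {
    cond_seed <- sample.int(.Machine$integer.max, 1)
    conditions <- sample_conditions(spec$conditions_per_epoch, k,
                                    net$ligands, seed = cond_seed)
    X <- project_input(conditions, model)
    ss <- forward_steady_state(model, X, settings)
    Yhat <- t(ss$states[model$tf_idx, , drop = FALSE] *
                model$output_scale)

    zero_term <- list(loss = 0, grad = matrix(0, nrow(Yhat), ncol(Yhat)))
    ccols <- corr_mean_loss(Yhat)      # across TFs
    crows <- corr_mean_loss(t(Yhat))   # across conditions
    ucols <- uniform_stat_loss(Yhat, reg$uniform_a, reg$uniform_b)
    # across-TF uniformity is meaningful only with >= 2 TFs
    urows <- if (ncol(Yhat) >= 2) {
      u <- uniform_stat_loss(t(Yhat), reg$uniform_a, reg$uniform_b)
      list(loss = u$loss, grad = t(u$grad))
    } else zero_term
    dL_dY <- spec$corr_coeff * (ccols$grad + t(crows$grad)) / 2 +
      spec$output_uniform_coeff * (ucols$grad + urows$grad)
    gr <- backward_steady_state(model, ss, dL_dY,
                                conditions = conditions,
                                settings = settings, check = FALSE)
    pt <- param_reg_terms(model, reg)
    gw <- gr$weights + pt$gw
    gb <- gr$bias + pt$gb
    spec_loss <- 0
    if (reg$spectral_coeff > 0) {
      sp <- tryCatch(transition_spectrum(
        model, ss, sample.int(ncol(X), 1), settings, k = 3L, tol = 1e-4),
        error = function(e) NULL)
      if (!is.null(sp)) {
        sl <- tryCatch(
          spectral_radius_loss(sp, model$src_idx, model$tgt_idx, reg),
          error = function(e) NULL)
        if (!is.null(sl)) {
          spec_loss <- reg$spectral_coeff * as.numeric(sl)
          cap <- 10 * reg$spectral_k
          fac <- min(1, cap / max(as.numeric(sl) * reg$spectral_k, 1))
          gw <- gw + reg$spectral_coeff * fac * attr(sl, "grad")
        }
      }
    }
    loss <- spec$corr_coeff * (ccols$loss + crows$loss) / 2 +
      spec$output_uniform_coeff * (ucols$loss + urows$loss) +
      pt$loss + spec_loss
    if (!is.finite(loss))
      stop("reference objective diverged (non-finite) at epoch ", epoch)
    grad <- c(gw, gb, gr$input_scale, gr$output_scale)
    grad[nw + nb + seq_along(model$input_scale)] <- 0 # input scales fixed
    st <- adam_step(opt, theta, grad, spec$lr, cfg)
    theta <- st$theta; opt <- st$state
    model <- unflatten_params(model, theta)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = loss,
                                    corr = (ccols$loss + crows$loss) / 2,
                                    uniform = ucols$loss + urows$loss,
                                    spectral = spec_loss)
    if (verbose && epoch %% 100 == 0)
      message(sprintf("reference epoch %d loss %.4g", epoch, loss))
  }
  attr(model, "history") <- dplyr::bind_rows(hist)
  model
}

#' Generate a synthetic TF-activity dataset from a reference model
#'
#' Runs the forward pass of the (typically auto-parameterized) reference
#' model on the supplied conditions and returns the projected TF
#' activities. Deterministic given the model and conditions; warns about
#' conditions that fail to converge.
#'
#' @param reference An `sn_model`.
#' @param conditions Tibble of ligand concentrations.
#' @param settings [simulation_settings()].
#' @return Tibble of TF activities.
#' @export
generate_dataset <- function(reference, conditions,
                             settings = simulation_settings()) {
  X <- project_input(conditions, reference)
  ss <- forward_steady_state(reference, X, settings)
  bad <- which(ss$residual > settings$tolerance)
  if (length(bad) > 0)
    warning(length(bad), " condition(s) not converged; worst residual ",
            format(max(ss$residual)))
  project_output(ss, reference)
}

#' Probe the nonlinearity of a reference model
#'
#' Fits cross-validated linear maps from ligand concentrations to TF
#' activities for increasing numbers of simultaneous ligands, and
#' additionally extrapolates a linear model fitted on single-ligand data.
#' On a parameterized reference the linear fit degrades with the number
#' of simultaneous ligands: TF activity is not a linear combination of
#' single-ligand responses.
#'
#' @param reference An `sn_model`.
#' @param k_values Simultaneous-ligand counts to probe.
#' @param n Conditions per level (default 200).
#' @param folds Cross-validation folds (default 20).
#' @param seed Integer seed.
#' @param settings [simulation_settings()].
#' @return Tibble with columns `k`, `cv_r` (cross-validated linear fit)
#'   and `single_ligand_r` (extrapolated single-ligand model).
#' @export
nonlinearity_probe <- function(reference, k_values = c(1, 2, 3, 5),
                               n = 200L, folds = 20L, seed = 1L,
                               settings = simulation_settings()) {
  net <- reference$network
  k_values <- pmin(k_values, length(net$ligands))
  cond1 <- sample_conditions(n, 1, net$ligands, seed = seed)
  y1 <- generate_dataset(reference, cond1, settings)
  C1 <- as.matrix(cond1[, -1]); Y1 <- as.matrix(y1[, -1])
  beta1 <- stats::lm.fit(cbind(1, C1), Y1)$coefficients
  out <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    cond <- sample_conditions(n, k, net$ligands, seed = seed + k)
    y <- generate_dataset(reference, cond, settings)
    C <- as.matrix(cond[, -1]); Y <- as.matrix(y[, -1])
    fold_id <- rep(seq_len(folds), length.out = n)
    set.seed(seed + k)
    fold_id <- sample(fold_id)
    preds <- matrix(NA_real_, n, ncol(Y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      beta <- stats::lm.fit(cbind(1, C[tr, , drop = FALSE]),
                            Y[tr, , drop = FALSE])$coefficients
      beta[is.na(beta)] <- 0
      preds[!tr, ] <- cbind(1, C[!tr, , drop = FALSE]) %*% beta
    }
    ext <- cbind(1, C) %*% beta1
    out[[i]] <- tibble::tibble(
      k = k,
      cv_r = stats::cor(as.vector(preds), as.vector(Y)),
      single_ligand_r = stats::cor(as.vector(ext), as.vector(Y)))
  }
  dplyr::bind_rows(out)
}

#' Steady-state activity of a two-input molecular mechanism
#'
#' For the independent activation/inhibition mechanism -- a target
#' interconverting between inactive and active forms, activated at rate
#' `k1 * [A]` and deactivated at rate `k2 * [B]` (kinase/phosphatase
#' pair) -- the analytic steady state is `k1 A / (k1 A + k2 B)`. The ODE
#' route integrates the mass-action system (states initialized at
#' 1/number-of-states) to `t = 100` and reads off the activity; generic
#' user-supplied mass-action schemes are integrated the same way. With
#' both source concentrations zero, activity is defined as 0.
#'
#' @param A,B Numeric vectors (recycled to a common length) of source
#'   concentrations.
#' @param k1,k2 Rate constants (>= 0, not all zero).
#' @param method `"analytic"` (independent mechanism only) or `"ode"`.
#' @param deriv Optional derivative function
#'   `function(t, state, parms)` returning `list(dstate)` for a generic
#'   scheme integrated by [deSolve::ode()]; `parms` receives
#'   `list(A, B, k1, k2)`. The first state component is taken as the
#'   activity.
#' @param n_states Number of molecular states for the generic scheme
#'   (initialization `1/n_states`).
#' @param t_end Integration horizon (default 100 time units).
#' @param scale_max Scale activities so the maximum over the input grid
#'   is 1 (default `FALSE`).
#' @return Numeric vector of steady-state activities.
#' @export
mechanism_steady_state <- function(A, B, k1 = 1, k2 = 1,
                                   method = c("analytic", "ode"),
                                   deriv = NULL, n_states = 2,
                                   t_end = 100, scale_max = FALSE) {
  method <- match.arg(method)
  if (k1 < 0 || k2 < 0 || (k1 == 0 && k2 == 0))
    stop("rates must be non-negative and not all zero")
  len <- max(length(A), length(B))
  A <- rep_len(A, len); B <- rep_len(B, len)
  if (method == "analytic") {
    if (!is.null(deriv))
      stop("analytic solution only available for the independent ",
           "activation/inhibition mechanism")
    den <- k1 * A + k2 * B
    act <- ifelse(den == 0, 0, k1 * A / den)
  } else {
    act <- vapply(seq_len(len), function(i) {
      if (A[i] == 0 && B[i] == 0) return(0)
      if (is.null(deriv)) {
        f <- function(t, state, parms) {
          with(parms, list(k1 * A * (1 - state[1]) - k2 * B * state[1]))
        }
        y0 <- 0.5
      } else {
        f <- deriv
        y0 <- rep(1 / n_states, n_states)
      }
      sol <- deSolve::ode(y = y0, times = c(0, t_end), func = f,
                          parms = list(A = A[i], B = B[i], k1 = k1,
                                       k2 = k2))
      sol[nrow(sol), 2]
    }, numeric(1))
  }
  if (scale_max && max(act) > 0) act <- act / max(act)
  act
}

# small dense feed-forward net with 0 or 1 hidden layer and a trainable
# output scale, trained by full-batch ADAM with L2 decay
ffnn_fit <- function(X, y, act_kind, hidden = 0L, epochs = 5000L,
                     lr = 0.002, l2 = 1e-5, seed = 1L) {
  set.seed(seed)
  settings <- activation_settings()
  d <- ncol(X)
  if (hidden == 0L) {
    w <- stats::rnorm(d, 0, 0.5); b <- 0; s <- 1
    opt <- adam_init(d + 2)
    cfg <- list(beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8)
    theta <- c(w, b, s)
    for (e in seq_len(epochs)) {
      w <- theta[1:d]; b <- theta[d + 1]; s <- theta[d + 2]
      z <- as.vector(X %*% w) + b
      a <- act_apply(z, act_kind, settings)
      yhat <- s * a
      err <- yhat - y
      dz <- 2 * err * s * act_apply_grad(z, act_kind, settings) / length(y)
      grad <- c(as.vector(crossprod(X, dz)) + 2 * l2 * w, sum(dz),
                sum(2 * err * a) / length(y))
      st <- adam_step(opt, theta, grad, lr, cfg)
      theta <- st$theta; opt <- st$state
    }
    list(predict = function(Xn) {
      w <- theta[1:d]; b <- theta[d + 1]; s <- theta[d + 2]
      s * act_apply(as.vector(Xn %*% w) + b, act_kind, settings)
    })
  } else {
    h <- hidden
    np <- d * h + h + h + 1 + 1
    theta <- c(stats::rnorm(d * h, 0, 2), stats::rnorm(h, 0, 0.5),
               stats::rnorm(h, 0, 2), 0, 1)
    unpack <- function(th) list(
      W1 = matrix(th[seq_len(d * h)], d, h),
      b1 = th[d * h + seq_len(h)],
      w2 = th[d * h + h + seq_len(h)],
      b2 = th[d * h + 2 * h + 1], s = th[np])
    opt <- adam_init(np)
    cfg <- list(beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8)
    for (e in seq_len(epochs)) {
      p <- unpack(theta)
      Z1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
      A1 <- act_apply(Z1, act_kind, settings)
      z2 <- as.vector(A1 %*% p$w2) + p$b2
      a2 <- act_apply(z2, act_kind, settings)
      yhat <- p$s * a2
      err <- yhat - y
      dz2 <- 2 * err * p$s * act_apply_grad(z2, act_kind, settings) /
        length(y)
      dA1 <- outer(dz2, p$w2)
      dZ1 <- dA1 * act_apply_grad(Z1, act_kind, settings)
      grad <- c(as.vector(crossprod(X, dZ1)) + 2 * l2 * p$W1,
                colSums(dZ1),
                as.vector(crossprod(A1, dz2)) + 2 * l2 * p$w2,
                sum(dz2), sum(2 * err * a2) / length(y))
      st <- adam_step(opt, theta, grad, lr, cfg)
      theta <- st$theta; opt <- st$state
    }
    list(predict = function(Xn) {
      p <- unpack(theta)
      Z1 <- sweep(Xn %*% p$W1, 2, p$b1, `+`)
      A1 <- act_apply(Z1, act_kind, settings)
      p$s * act_apply(as.vector(A1 %*% p$w2) + p$b2, act_kind, settings)
    })
  }
}

#' Approximate a molecular mechanism with a small feed-forward net
#'
#' Trains a feed-forward approximator (no hidden layer, or one hidden
#' layer of `hidden` nodes, with a trainable output scale) on the steady
#' state of a two-input mechanism over a grid of linearly spaced source
#' concentrations, and evaluates the Pearson correlation between
#' prediction and the mechanism on a finer test grid. Full-batch ADAM,
#' 5000 epochs, learning rate 0.002, L2 decay 1e-5; the mean correlation
#' over `runs` random restarts is reported.
#'
#' @param act_kind Activation: `"mml"`, `"leaky_relu"`, or `"sigmoid"`.
#' @param hidden Hidden nodes (0 for none, 5 for one hidden layer).
#' @param train_n,test_n Grid resolutions (defaults 7 and 20).
#' @param k1,k2 Mechanism rates.
#' @param runs Random restarts averaged (default 3).
#' @param epochs,lr,l2 Optimizer settings.
#' @param seed Base seed.
#' @return List with `mean_r`, per-run `r`, and the fitted predictor of
#'   the last run. Constant test surfaces give `mean_r = NaN` with a
#'   warning.
#' @export
fit_mechanism_ffnn <- function(act_kind = "mml", hidden = 0L,
                               train_n = 7L, test_n = 20L, k1 = 1, k2 = 1,
                               runs = 3L, epochs = 5000L, lr = 0.002,
                               l2 = 1e-5, seed = 1L) {
  grid <- function(n) {
    g <- seq(0, 1, length.out = n)
    as.matrix(expand.grid(A = g, B = g))
  }
  Xtr <- grid(train_n); Xte <- grid(test_n)
  ytr <- mechanism_steady_state(Xtr[, 1], Xtr[, 2], k1, k2)
  yte <- mechanism_steady_state(Xte[, 1], Xte[, 2], k1, k2)
  if (stats::sd(yte) == 0) {
    warning("constant target surface; correlation undefined")
    return(list(mean_r = NaN, r = rep(NaN, runs)))
  }
  rs <- numeric(runs)
  fit <- NULL
  for (run in seq_len(runs)) {
    fit <- ffnn_fit(Xtr, ytr, act_kind, hidden, epochs, lr, l2,
                    seed = seed + run)
    rs[run] <- stats::cor(fit$predict(Xte), yte)
  }
  list(mean_r = mean(rs), r = rs, fit = fit)
}
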