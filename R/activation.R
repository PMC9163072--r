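#' Activation settings
#'
#' Settings for the Michaelis-Menten-like (MML) activation function used
#' throughout the recurrent signaling model. The function is composed of
#' three segments: a leaky segment below 0 (slope `leak_slope`, preventing
#' irrecoverably dead nodes), an identity segment on `[0, linear_upper)`
#' (signals pass through unchanged), and a shifted/scaled Michaelis-Menten
#' segment above `linear_upper` that saturates towards `saturation_cap`.
#' States are thereby kept in a physiologically meaningful range: never much
#' below 0 and never at or above 1 for finite input.
#'
#' @param leak_slope Slope for negative pre-activation, in (0, 1).
#'   Default 0.01, the conventional leaky-rectifier slope.
#' @param linear_upper Breakpoint between the linear and saturating
#'   segments. Fixed at 0.5 by the construction of the saturating segment.
#' @param saturation_cap Asymptotic maximum of the activation. Fixed at 1.
#' @return A list of class `"sn_activation"`.
#' @export
#' @examples
#' act <- activation_settings()
#' act_mml(3, act) # ~0.92
activation_settings <- function(leak_slope = 0.01, linear_upper = 0.5,
                                saturation_cap = 1) {
  stopifnot(leak_slope > 0, leak_slope < 1,
            isTRUE(all.equal(linear_upper, 0.5)),
            isTRUE(all.equal(saturation_cap, 1)))
  structure(list(leak_slope = leak_slope, linear_upper = linear_upper,
                 saturation_cap = saturation_cap),
            class = "sn_activation")
}

#' Michaelis-Menten-like activation function
#'
#' Piecewise: `leak_slope * x` for `x < 0`; `x` for `0 <= x < 0.5`;
#' `0.5 + 0.5 * (x - 0.5) / x` (equivalently `1 - 0.25 / x`) for
#' `x >= 0.5`. The saturating branch is the unique shifted and scaled
#' Michaelis-Menten curve with value 0.5 and slope 1 at `x = 0.5` and
#' asymptote 1, so the function is continuous with a continuous first
#' derivative everywhere except at 0.
#'
#' @param x Numeric vector of pre-activation values.
#' @param settings An [activation_settings()] object.
#' @return Numeric vector of activities, each `< 1` for finite input.
#' @export
act_mml <- function(x, settings = activation_settings()) {
  out <- x
  out[x < 0] <- settings$leak_slope * x[x < 0]
  hi <- x >= 0.5
  out[hi] <- 1 - 0.25 / x[hi]
  out
}

#' Derivative of the MML activation
#'
#' `leak_slope` for `x < 0`; 1 for `0 < x < 0.5`; `0.25 / x^2` for
#' `x >= 0.5`. Continuous at 0.5; undefined at 0 (the right-derivative, 1,
#' is returned there).
#'
#' @inheritParams act_mml
#' @export
act_mml_grad <- function(x, settings = activation_settings()) {
  out <- rep(1, length(x))
  out[x < 0] <- settings$leak_slope
  hi <- x >= 0.5
  out[hi] <- 0.25 / x[hi]^2
  out
}

#' Leaky rectifier activation (comparison)
#' @inheritParams act_mml
#' @export
act_leaky_relu <- function(x, settings = activation_settings()) {
  ifelse(x < 0, settings$leak_slope * x, x)
}

#' @rdname act_leaky_relu
#' @export
act_leaky_relu_grad <- function(x, settings = activation_settings()) {
  ifelse(x < 0, settings$leak_slope, 1)
}

#' Sigmoid activation (comparison)
#' @param x Numeric vector.
#' @export
act_sigmoid <- function(x) stats::plogis(x)

#' @rdname act_sigmoid
#' @export
act_sigmoid_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 - s)
}

#' Gradient clipping with smooth saturation
#'
#' Identity on `[-c, c]`, then saturates along a hyperbolic-tangent tail to
#' the finite bound `2c`. Odd, monotone non-decreasing, and continuously
#' differentiable, so clipping is inactive for gradients of ordinary
#' magnitude and only caps genuinely exploding components.
#'
#' @param g Numeric vector of gradient values.
#' @param c Positive clip threshold (default 5).
#' @return Clipped values, bounded by `2c` in magnitude.
#' @export
clip_gradient <- function(g, c = 5) {
  stopifnot(c > 0)
  out <- g
  hi <- g > c
  lo <- g < -c
  out[hi] <- c + c * tanh((g[hi] - c) / c)
  out[lo] <- -c - c * tanh((-g[lo] - c) / c)
  out
}

act_code <- function(kind = c("mml", "leaky_relu", "sigmoid")) {
  match(match.arg(kind), c("mml", "leaky_relu", "sigmoid")) - 1L
}

act_apply <- function(x, kind, settings = activation_settings()) {
  switch(kind,
         mml = act_mml(x, settings),
         leaky_relu = act_leaky_relu(x, settings),
         sigmoid = act_sigmoid(x))
}

act_apply_grad <- function(x, kind, settings = activation_settings()) {
  switch(kind,
         mml = act_mml_grad(x, settings),
         leaky_relu = act_leaky_relu_grad(x, settings),
         sigmoid = act_sigmoid_grad(x))
}
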