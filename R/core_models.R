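# Pure model evaluators. All take time in seconds relative to flash onset
# (onset at t = 0) and return OPL change in nm. The Heaviside gate is
# closed on the left: u(t) = 1 for t >= 0 (inclusive), 0 for t < 0.

.check_t <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be numeric and finite")
  as.numeric(t)
}

#' Evaluate the single-flash response model
#'
#' \deqn{\Delta OPL(t) = u(t)\,[A_0 + A_1(-e^{-\tau_a t} + e^{-\tau_b t})]}
#' where \eqn{u(t)} is the Heaviside step (1 for \eqn{t \ge 0}, 0
#' otherwise). At \eqn{t = 0} the two exponentials cancel and the model
#' equals \eqn{A_0}: the rapid outer-segment contraction is represented as
#' a step, because at practical volume rates (~400 Hz) it spans only a few
#' samples.
#'
#' @param params [response_params()].
#' @param t Time(s) relative to flash onset, s; vectorized.
#' @return \eqn{\Delta OPL} in nm, same length as `t`.
#' @export
eval_single_flash <- function(params, t) {
  stopifnot(inherits(params, "org_params"))
  t <- .check_t(t)
  out <- numeric(length(t))
  on <- t >= 0
  if (any(on)) {
    tt <- t[on]
    out[on] <- params$a0 +
      params$a1 * (-exp(-params$tau_a * tt) + exp(-params$tau_b * tt))
  }
  out
}

#' Evaluate the outer-segment elongation rate
#'
#' The derivative of the single-flash model for `t > 0`:
#' \deqn{A_1(\tau_a e^{-\tau_a t} - \tau_b e^{-\tau_b t}).}
#' The distributional impulse contributed by the step discontinuity at
#' onset is excluded; the rate is defined only for strictly positive
#' times.
#'
#' @inheritParams eval_single_flash
#' @param t Time(s) after onset, s; all must be > 0.
#' @return Elongation rate, nm/s.
#' @export
eval_rate <- function(params, t) {
  stopifnot(inherits(params, "org_params"))
  t <- .check_t(t)
  if (any(t <= 0)) stop("eval_rate is defined only for t > 0")
  params$a1 * (params$tau_a * exp(-params$tau_a * t) -
               params$tau_b * exp(-params$tau_b * t))
}

#' Derived figures of merit of the single-flash response
#'
#' Closed-form time of maximum elongation and maximum OPL change:
#' \deqn{t_{max} = -\log(\tau_b/\tau_a)/(\tau_a - \tau_b)}
#' with \eqn{\Delta OPL_{max}} the model value there. When
#' `tau_a == tau_b` the formula is a 0/0 form whose analytic limit is
#' `1/tau_a`; that limit is returned with `degenerate = TRUE` (the
#' two-exponential term is then identically zero and the maximum value is
#' `a0`). Because the rate of early elongation is not well defined at the
#' onset step, the early slope is reported as the model rate at a
#' caller-chosen time (`rate_time`, default 50 ms).
#'
#' @inheritParams eval_single_flash
#' @param rate_time Time at which the early elongation rate is quoted, s.
#' @return A list of class `org_derived_metrics` with elements `t_max` (s),
#'   `dopl_max` (nm), `rate_early` (nm/s at `rate_time`), `rate_at`
#'   (function of time), and `degenerate`.
#' @export
derived_metrics <- function(params, rate_time = 0.05) {
  stopifnot(inherits(params, "org_params"))
  ta <- params$tau_a; tb <- params$tau_b
  if (ta == tb) {
    t_max <- 1 / ta
    degenerate <- TRUE
  } else {
    t_max <- -log(tb / ta) / (ta - tb)
    degenerate <- FALSE
  }
  structure(list(
    t_max = t_max,
    dopl_max = eval_single_flash(params, t_max),
    rate_early = eval_rate(params, rate_time),
    rate_at = function(t) eval_rate(params, t),
    degenerate = degenerate
  ), class = "org_derived_metrics")
}

#' Evaluate the shifted-sum paired-flash model
#'
#' The response to two flashes separated by `t_isi` is modeled as the sum
#' of two single-flash responses, the second delayed by `t_isi`.
#'
#' @param params [two_flash_params()].
#' @param t Time(s) relative to the first flash onset, s.
#' @return \eqn{\Delta OPL} in nm.
#' @export
eval_two_flash <- function(params, t) {
  stopifnot(inherits(params, "org_two_flash_params"))
  t <- .check_t(t)
  eval_single_flash(params$alpha, t) +
    eval_single_flash(params$beta, t - params$t_isi)
}

#' Evaluate the flash-on-background model
#'
#' Single-flash response plus the ungated linear ramp `m * t` produced by
#' steady background bleaching (the ramp runs before onset as well, since
#' the background precedes the flash).
#'
#' @param params [background_params()].
#' @param t Time(s) relative to flash onset, s.
#' @return \eqn{\Delta OPL} in nm.
#' @export
eval_background <- function(params, t) {
  stopifnot(inherits(params, "org_background_params"))
  t <- .check_t(t)
  eval_single_flash(params$flash, t) + params$m * t
}

#' Evaluate an alternative single-flash model
#'
#' Evaluates the model named by `spec$model_id`; see [alt_model_spec()]
#' for the five parameterizations.
#'
#' @param spec [alt_model_spec()].
#' @param t Time(s) relative to flash onset, s.
#' @return \eqn{\Delta OPL} in nm.
#' @export
eval_alternative <- function(spec, t) {
  stopifnot(inherits(spec, "org_alt_spec"))
  t <- .check_t(t)
  p <- spec$params
  out <- numeric(length(t))
  on <- t >= 0
  if (!any(on)) return(out)
  tt <- t[on]
  out[on] <- switch(spec$model_id,
    magenta = p$a0 + p$a1 * (-exp(-p$tau_a * tt) + exp(-p$tau_b * tt)),
    green   = p$a1 * (-exp(-p$tau_a * (tt - p$t0)) +
                        exp(-p$tau_b * (tt - p$t0))),
    red     = p$a1 * (1 - exp(-p$tau_a * tt)),
    blue    = p$a1 * (-exp(-p$tau_a * tt) + exp(-p$tau_b * tt)),
    cyan    = p$a0 * (1 - exp(-p$tau_a * tt)) + p$a1 * (1 - exp(-p$tau_b * tt)))
  out
}

#' Evaluate the en-face interference intensity model
#'
#' Forward model for 2D intensity-based ORG detection:
#' \deqn{I(t) = C_1 + C_2 \cos\!\big[n\,\tfrac{4\pi}{\lambda} A_1
#'   (-e^{-\tau_a t} + e^{-\tau_b t}) + \phi_0\big].}
#' The phase argument carries the elongation term only (no contraction
#' offset), as the model is printed; output is bounded in
#' `[c1 - c2, c1 + c2]`.
#'
#' @param enface [enface_params()].
#' @param params [response_params()] (only `a1`, `tau_a`, `tau_b` enter).
#' @param t Time(s) relative to flash onset, s.
#' @return Intensity, arbitrary units.
#' @export
eval_enface_intensity <- function(enface, params, t) {
  stopifnot(inherits(enface, "org_enface_params"),
            inherits(params, "org_params"))
  t <- .check_t(t)
  elong <- params$a1 * (-exp(-params$tau_a * t) + exp(-params$tau_b * t))
  enface$c1 + enface$c2 *
    cos(enface$n * 4 * pi / enface$lambda_nm * elong + enface$phi0)
}
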