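#' Single-flash response parameters
#'
#' Container for the four parameters of the biexponential single-flash
#' response model \eqn{\Delta OPL(t) = u(t)[A_0 + A_1(-e^{-\tau_a t} +
#' e^{-\tau_b t})]}: the contraction amplitude `a0` (nm, typically
#' negative), the elongation amplitude `a1` (nm), and the elongation and
#' recovery rate constants `tau_a`, `tau_b` (s^-1).
#'
#' The parameterization is degenerate under `(a1, tau_a, tau_b) ->
#' (-a1, tau_b, tau_a)`; the canonical orientation used for all reported
#' fits is `tau_a >= tau_b` (and hence `a1 >= 0` for elongation-type
#' responses). Use [canonicalize_params()] to map an arbitrary orientation
#' onto the canonical one.
#'
#' @param a0 Contraction amplitude, nm.
#' @param a1 Elongation amplitude, nm.
#' @param tau_a Elongation rate constant, s^-1; must be > 0.
#' @param tau_b Recovery rate constant, s^-1; must be > 0.
#' @return An object of class `org_params`.
#' @examples
#' p <- response_params(a0 = -36.4, a1 = 200.8, tau_a = 9.5, tau_b = 0.07)
#' eval_single_flash(p, c(-0.05, 0, 0.5, 1))
#' @export
response_params <- function(a0, a1, tau_a, tau_b) {
  stopifnot(is.numeric(a0), is.numeric(a1), is.numeric(tau_a),
            is.numeric(tau_b), length(a0) == 1L, length(a1) == 1L,
            length(tau_a) == 1L, length(tau_b) == 1L)
  if (!is.finite(tau_a) || tau_a <= 0) stop("tau_a must be a positive finite rate (s^-1)")
  if (!is.finite(tau_b) || tau_b <= 0) stop("tau_b must be a positive finite rate (s^-1)")
  structure(list(a0 = as.numeric(a0), a1 = as.numeric(a1),
                 tau_a = as.numeric(tau_a), tau_b = as.numeric(tau_b)),
            class = "org_params")
}

#' Map response parameters onto the canonical orientation
#'
#' Applies the exact model identity `(a1, tau_a, tau_b) == (-a1, tau_b,
#' tau_a)` so that `tau_a >= tau_b`.
#'
#' @param params An [response_params()] object.
#' @return An `org_params` object describing the identical response curve.
#' @export
canonicalize_params <- function(params) {
  stopifnot(inherits(params, "org_params"))
  if (params$tau_a < params$tau_b) {
    params <- response_params(params$a0, -params$a1, params$tau_b, params$tau_a)
  }
  params
}

#' @export
print.org_params <- function(x, ...) {
  cat(sprintf("Single-flash response parameters:\n  a0 = %.3g nm, a1 = %.3g nm, tau_a = %.3g s^-1, tau_b = %.3g s^-1\n",
              x$a0, x$a1, x$tau_a, x$tau_b))
  invisible(x)
}

#' Paired-flash response parameters
#'
#' Parameters of the shifted-sum two-flash model: the full response is the
#' single-flash response of the first flash (`alpha`) plus the single-flash
#' response of the second flash (`beta`) delayed by the inter-stimulus
#' interval `t_isi`.
#'
#' @param alpha,beta [response_params()] for the first and second flash.
#' @param t_isi Inter-stimulus (onset-to-onset) interval, s; >= 0.
#' @return An object of class `org_two_flash_params`.
#' @export
two_flash_params <- function(alpha, beta, t_isi) {
  stopifnot(inherits(alpha, "org_params"), inherits(beta, "org_params"),
            is.numeric(t_isi), length(t_isi) == 1L, is.finite(t_isi))
  if (t_isi < 0) stop("t_isi must be >= 0")
  structure(list(alpha = alpha, beta = beta, t_isi = as.numeric(t_isi)),
            class = "org_two_flash_params")
}

#' Flash-on-adapting-background response parameters
#'
#' The response to a flash delivered against a dim adapting background is
#' modeled as the single-flash response plus a linear ramp `m * t` driven
#' by ongoing background bleaching. The ramp is active over the whole
#' record (not gated by the flash-onset step).
#'
#' @param flash [response_params()] of the flash component.
#' @param m Ramp slope, nm/s.
#' @return An object of class `org_background_params`.
#' @export
background_params <- function(flash, m) {
  stopifnot(inherits(flash, "org_params"), is.numeric(m), length(m) == 1L,
            is.finite(m))
  structure(list(flash = flash, m = as.numeric(m)),
            class = "org_background_params")
}

#' Alternative single-flash model specification
#'
#' The single-flash response admits several parameterizations, referred to
#' by color:
#' \describe{
#'   \item{magenta}{the full four-parameter model (`a0`, `a1`, `tau_a`,
#'     `tau_b`) -- the primary model;}
#'   \item{green}{`u(t) * a1 * (-exp(-tau_a (t - t0)) + exp(-tau_b (t - t0)))`,
#'     an onset-shifted two-exponential that converges to 0 as t grows and
#'     models the contraction by its duration `t0` rather than its
#'     amplitude;}
#'   \item{red}{`u(t) * a1 * (1 - exp(-tau_a t))`, saturating elongation
#'     only;}
#'   \item{blue}{`u(t) * a1 * (-exp(-tau_a t) + exp(-tau_b t))`, elongation
#'     plus recovery without an offset (provisional form);}
#'   \item{cyan}{`u(t) * (a0 (1 - exp(-tau_a t)) + a1 (1 - exp(-tau_b t)))`,
#'     a pair of saturating exponentials with independent amplitudes.}
#' }
#'
#' @param model_id One of `"magenta"`, `"green"`, `"red"`, `"blue"`,
#'   `"cyan"`.
#' @param ... Named model parameters. All models use `a1`, `tau_a`;
#'   magenta/blue/cyan additionally `tau_b`; magenta/cyan `a0`; green
#'   `tau_b` and the onset shift `t0` (s, >= 0).
#' @return An object of class `org_alt_spec`.
#' @export
alt_model_spec <- function(model_id, ...) {
  model_id <- match.arg(model_id, c("magenta", "green", "red", "blue", "cyan"))
  p <- list(...)
  need <- switch(model_id,
    magenta = c("a0", "a1", "tau_a", "tau_b"),
    green   = c("a1", "tau_a", "tau_b", "t0"),
    red     = c("a1", "tau_a"),
    blue    = c("a1", "tau_a", "tau_b"),
    cyan    = c("a0", "a1", "tau_a", "tau_b"))
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop(sprintf("model '%s' requires parameters: %s", model_id,
                 paste(missing, collapse = ", ")))
  p <- p[need]
  rates <- intersect(c("tau_a", "tau_b"), need)
  for (r in rates)
    if (!is.finite(p[[r]]) || p[[r]] <= 0) stop(sprintf("%s must be > 0", r))
  if (model_id == "green" && p$t0 < 0) stop("t0 must be >= 0")
  structure(list(model_id = model_id, params = lapply(p, as.numeric)),
            class = "org_alt_spec")
}

#' En-face interference intensity model parameters
#'
#' In 2D (en-face) common-path interferometric ORG detection the outer
#' segment length change is encoded in cone brightness through interference
#' between the ISOS and COST reflections. The intensity model is
#' `I(t) = c1 + c2 * cos(n * 4*pi/lambda * a1 * (-exp(-tau_a t) +
#' exp(-tau_b t)) + phi0)`.
#'
#' @param c1 Intensity offset, arbitrary units.
#' @param c2 Modulation amplitude, arbitrary units; >= 0.
#' @param n Refractive index of the outer segment (dimensionless).
#' @param lambda_nm Probe wavelength, nm; > 0.
#' @param phi0 Phase offset, rad.
#' @return An object of class `org_enface_params`.
#' @export
enface_params <- function(c1, c2, n = 1.38, lambda_nm = 850, phi0 = 0) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(n),
            is.numeric(lambda_nm), is.numeric(phi0))
  if (c2 < 0) stop("c2 must be >= 0")
  if (lambda_nm <= 0) stop("lambda_nm must be > 0")
  structure(list(c1 = as.numeric(c1), c2 = as.numeric(c2), n = as.numeric(n),
                 lambda_nm = as.numeric(lambda_nm), phi0 = as.numeric(phi0)),
            class = "org_enface_params")
}
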