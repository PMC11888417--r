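# Stimulus radiometry and dose-response characterization.
#
# Radiant power at the cornea is converted to a retinal photon flux
# density assuming uniform illumination of a circular spot, and then to a
# photopigment bleach fraction through single-hit fluence bleaching
# p = 1 - exp(-Q s) with photosensitivity s (um^2/photon). The default
# s = 2.95e-8 um^2 (~10^-7.53) is the literature cone photosensitivity at
# 555 nm.

.PLANCK <- 6.62607015e-34   # J s
.C_LIGHT <- 2.99792458e8    # m/s

#' Stimulus radiometry specification
#'
#' @param power_w Radiant power at the cornea, W; >= 0.
#' @param duration_s Exposure duration, s; > 0.
#' @param wavelength_nm Stimulus wavelength, nm; > 0.
#' @param spot_diameter_um Diameter of the (circular) illuminated retinal
#'   spot, um; > 0.
#' @param transmission Ocular transmission, in (0, 1].
#' @param photosensitivity_um2 Photopigment photosensitivity, um^2 per
#'   photon.
#' @return An object of class `org_radiometry`.
#' @examples
#' spec <- radiometry_spec(power_w = 5.05e-6, duration_s = 0.010,
#'                         wavelength_nm = 555, spot_diameter_um = 360)
#' photon_flux_density(spec)   # ~1.4e8 photons s^-1 um^-2
#' bleach_fraction(spec)       # ~0.04
#' @export
radiometry_spec <- function(power_w, duration_s, wavelength_nm,
                            spot_diameter_um, transmission = 1.0,
                            photosensitivity_um2 = 2.95e-8) {
  stopifnot(is.numeric(power_w), is.numeric(duration_s),
            is.numeric(wavelength_nm), is.numeric(spot_diameter_um))
  if (power_w < 0) stop("power_w must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (wavelength_nm <= 0) stop("wavelength_nm must be > 0")
  if (spot_diameter_um <= 0) stop("spot_diameter_um must be > 0")
  if (transmission <= 0 || transmission > 1)
    stop("transmission must be in (0, 1]")
  if (photosensitivity_um2 <= 0) stop("photosensitivity_um2 must be > 0")
  structure(list(power_w = power_w, duration_s = duration_s,
                 wavelength_nm = wavelength_nm,
                 spot_diameter_um = spot_diameter_um,
                 transmission = transmission,
                 photosensitivity_um2 = photosensitivity_um2),
            class = "org_radiometry")
}

#' Retinal photon flux density of a stimulus
#'
#' `flux = T * P / (h c / lambda) / (pi (d/2)^2)`: power divided by the
#' photon energy and by the spot area.
#'
#' @param spec [radiometry_spec()].
#' @return Photon flux density, photons s^-1 um^-2.
#' @export
photon_flux_density <- function(spec) {
  stopifnot(inherits(spec, "org_radiometry"))
  e_photon <- .PLANCK * .C_LIGHT / (spec$wavelength_nm * 1e-9)  # J
  area_um2 <- pi * (spec$spot_diameter_um / 2)^2
  spec$transmission * spec$power_w / e_photon / area_um2
}

#' Photopigment bleach fraction of a stimulus
#'
#' Single-hit fluence bleaching without regeneration:
#' `p = 1 - exp(-Q s)` with fluence `Q = flux * duration`
#' (photons um^-2) and photosensitivity `s` (um^2/photon). For exposures
#' of seconds or less, regeneration (time constant of minutes) is
#' negligible.
#'
#' @param spec [radiometry_spec()].
#' @param flux Optional photon flux density override, photons s^-1 um^-2
#'   (used when the flux is known directly rather than derived from
#'   power).
#' @return Bleached fraction in \[0, 1).
#' @export
bleach_fraction <- function(spec, flux = NULL) {
  stopifnot(inherits(spec, "org_radiometry"))
  if (is.null(flux)) flux <- photon_flux_density(spec)
  q <- flux * spec$duration_s
  1 - exp(-q * spec$photosensitivity_um2)
}

#' Fit a log-linear dose-response model
#'
#' `y = a * log10(b) + k`, with `b` the bleach percentage. Useful for
#' parameters (notably the contraction amplitude) that are linear on a
#' semi-log dose axis within the experimental bleaching range.
#'
#' @param b Bleach percentages (> 0).
#' @param y Parameter values (nm or s^-1).
#' @return An object of class `org_dose_fit` with elements `form`
#'   (`"loglinear"`), `a` (per decade), `k`, `r_squared`.
#' @export
fit_loglinear <- function(b, y) {
  stopifnot(is.numeric(b), is.numeric(y), length(b) == length(y))
  if (length(b) < 2L) stop("need at least 2 points")
  if (any(b <= 0)) stop("log-linear dose model requires b > 0")
  fit <- lm(y ~ log10(b))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(form = "loglinear",
                 a = unname(coef(fit)[2]), k = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "org_dose_fit")
}

#' Fit a Michaelis-Menten dose-response model
#'
#' `y = b * vm / (b + b0)`: saturating response with asymptote `vm` and
#' half-saturation dose `b0` (%). `vm` may take either sign (contraction
#' amplitudes saturate at negative values); `b0` is constrained positive.
#'
#' @param b Bleach percentages (>= 0).
#' @param y Parameter values.
#' @return An object of class `org_dose_fit` with elements `form`
#'   (`"michaelis_menten"`), `vm`, `b0`, `r_squared`, `converged`.
#' @export
fit_michaelis_menten <- function(b, y) {
  stopifnot(is.numeric(b), is.numeric(y), length(b) == length(y))
  if (length(b) < 2L) stop("need at least 2 points")
  if (any(b < 0)) stop("b must be >= 0")
  vm0 <- y[which.max(b)] * 1.2
  if (vm0 == 0) vm0 <- max(abs(y)) + 1
  b00 <- max(median(b), 1e-3)
  fit <- minpack.lm::nls.lm(
    par = c(vm = vm0, b0 = b00),
    lower = c(vm = -Inf, b0 = 1e-9),
    fn = function(p) y - b * p[["vm"]] / (b + p[["b0"]]),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  yhat <- b * fit$par[["vm"]] / (b + fit$par[["b0"]])
  ss_tot <- sum((y - mean(y))^2)
  structure(list(form = "michaelis_menten",
                 vm = fit$par[["vm"]], b0 = fit$par[["b0"]],
                 r_squared = if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else NA_real_,
                 converged = fit$info %in% 1:3),
            class = "org_dose_fit")
}

#' Predict a model parameter at a bleach level
#'
#' Evaluates a fitted dose-response form at bleach percentage `b`.
#'
#' @param fit [fit_loglinear()] or [fit_michaelis_menten()] result.
#' @param b Bleach percentage(s); the log-linear form requires `b > 0`.
#' @return Predicted parameter value(s).
#' @export
predict_param <- function(fit, b) {
  stopifnot(inherits(fit, "org_dose_fit"), is.numeric(b))
  if (fit$form == "loglinear") {
    if (any(b <= 0)) stop("log-linear form is defined only for b > 0")
    fit$a * log10(b) + fit$k
  } else {
    if (any(b < 0)) stop("b must be >= 0")
    b * fit$vm / (b + fit$b0)
  }
}

#' @export
print.org_dose_fit <- function(x, ...) {
  if (x$form == "loglinear")
    cat(sprintf("Log-linear dose fit: y = %.4g * log10(b) + %.4g (R^2 = %.3f)\n",
                x$a, x$k, x$r_squared))
  else
    cat(sprintf("Michaelis-Menten dose fit: vm = %.4g, b0 = %.4g%% (R^2 = %.3f)\n",
                x$vm, x$b0, x$r_squared))
  invisible(x)
}
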