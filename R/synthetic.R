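# Synthetic-data generators. These emulate the acquisition conditions the
# analysis assumes -- 400 Hz volume rate, 1 s or 3 s records, stimulus
# onset 200 ms after record start, additive Gaussian OPL noise -- and, for
# the complex-field generator, circular complex Gaussian noise on the
# ISOS/COST samples. They provide fixtures for round-trip parameter
# recovery and Monte Carlo studies; they do not model eye motion or
# speckle.

#' Simulation configuration
#'
#' @param fs Sampling (volume) rate, Hz (default 400).
#' @param duration_s Record duration, s (default 3).
#' @param onset_s Stimulus onset after record start, s (default 0.2).
#' @param noise_sigma_nm Additive Gaussian OPL noise SD, nm (default 10).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return List of class `org_sim_config`.
#' @export
sim_config <- function(fs = 400, duration_s = 3.0, onset_s = 0.2,
                       noise_sigma_nm = 10, seed = NULL) {
  stopifnot(fs > 0, duration_s > 0, onset_s < duration_s,
            noise_sigma_nm >= 0)
  structure(list(fs = fs, duration_s = duration_s, onset_s = onset_s,
                 noise_sigma_nm = noise_sigma_nm, seed = seed),
            class = "org_sim_config")
}

.sim_grid <- function(cfg) {
  t <- seq(0, cfg$duration_s - 1 / cfg$fs, by = 1 / cfg$fs)
  round(t * cfg$fs) / cfg$fs   # exact uniformity
}

.add_noise <- function(y, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$noise_sigma_nm > 0) y <- y + rnorm(length(y), 0, cfg$noise_sigma_nm)
  y
}

#' Simulate a single-flash trace
#'
#' Evaluates the single-flash model on the uniform grid (onset at
#' `cfg$onset_s`) and adds i.i.d. Gaussian noise.
#'
#' @param params [response_params()].
#' @param cfg [sim_config()].
#' @return An [org_trace()].
#' @examples
#' tr <- simulate_single_flash_trace(response_params(-36.4, 200.8, 9.5, 0.07),
#'                                   sim_config(seed = 1))
#' @export
simulate_single_flash_trace <- function(params, cfg = sim_config()) {
  stopifnot(inherits(params, "org_params"), inherits(cfg, "org_sim_config"))
  t <- .sim_grid(cfg)
  y <- .add_noise(eval_single_flash(params, t - cfg$onset_s), cfg)
  org_trace(t = t, dopl = y, fs = cfg$fs, stimulus_onsets = cfg$onset_s,
            meta = list(scenario = "single", truth = params))
}

# default attenuation of the second response by the first:
# contraction amplitude scaled by min(1, slope * t_isi + intercept)
# (linear recovery reaching unity at ~0.3 s), elongation amplitude scaled
# by a constant factor in the observed 0.75-1 band; time constants
# unchanged. These constants parameterize the generator; they are
# configurable, not claims.
.attenuated_beta <- function(alpha, t_isi, a0_slope = 2.3, a0_intercept = 0.31,
                             a1_ratio = 0.85) {
  response_params(
    a0 = alpha$a0 * min(1, a0_slope * t_isi + a0_intercept),
    a1 = alpha$a1 * a1_ratio,
    tau_a = alpha$tau_a, tau_b = alpha$tau_b)
}

#' Simulate a paired-flash trace
#'
#' The second flash's parameters are derived from the first's by the
#' default attenuation rule: `a0_beta = a0_alpha * min(1,
#' a0_slope * t_isi + a0_intercept)` (relative contraction growing
#' linearly with the interval and saturating at 1 near `t_isi` = 0.3 s)
#' and `a1_beta = a1_ratio * a1_alpha`; time constants unchanged. The
#' shifted-sum model is then evaluated and noise added.
#'
#' @param alpha [response_params()] of the first flash.
#' @param t_isi Inter-stimulus interval, s.
#' @param cfg [sim_config()].
#' @param a0_slope,a0_intercept,a1_ratio Attenuation-rule constants.
#' @return An [org_trace()] with the generating [two_flash_params()] in
#'   `meta$truth`.
#' @export
simulate_two_flash_trace <- function(alpha, t_isi, cfg = sim_config(),
                                     a0_slope = 2.3, a0_intercept = 0.31,
                                     a1_ratio = 0.85) {
  stopifnot(inherits(alpha, "org_params"), t_isi >= 0)
  beta <- .attenuated_beta(alpha, t_isi, a0_slope, a0_intercept, a1_ratio)
  tf <- two_flash_params(alpha, beta, t_isi)
  t <- .sim_grid(cfg)
  y <- .add_noise(eval_two_flash(tf, t - cfg$onset_s), cfg)
  org_trace(t = t, dopl = y, fs = cfg$fs,
            stimulus_onsets = c(cfg$onset_s, cfg$onset_s + t_isi),
            meta = list(scenario = "paired", truth = tf))
}

#' Simulate a pulse-train trace
#'
#' A shifted sum of `n` single-flash responses at fixed spacing. Each
#' flash's amplitudes are attenuated cumulatively by the paired-flash
#' rule applied to the elapsed time since the previous flash, so
#' contractions diminish down the train until they sink below the noise
#' floor. (The cumulative rule is a generator convention; no quantitative
#' train-attenuation rule is claimed by the measurements.)
#'
#' @param base [response_params()] of the first flash.
#' @param n Number of flashes, >= 1.
#' @param interval Onset-to-onset spacing within the train, s (default
#'   0.05).
#' @param cfg [sim_config()].
#' @param a0_slope,a0_intercept,a1_ratio Attenuation-rule constants.
#' @return An [org_trace()] with per-flash generating parameters in
#'   `meta$truth` (a list of `org_params`).
#' @export
simulate_pulse_train_trace <- function(base, n, interval = 0.05,
                                       cfg = sim_config(), a0_slope = 2.3,
                                       a0_intercept = 0.31, a1_ratio = 0.85) {
  stopifnot(inherits(base, "org_params"), n >= 1, interval > 0)
  flashes <- vector("list", n)
  flashes[[1]] <- base
  if (n > 1) for (k in 2:n)
    flashes[[k]] <- .attenuated_beta(flashes[[k - 1]], interval,
                                     a0_slope, a0_intercept, a1_ratio)
  t <- .sim_grid(cfg)
  onsets <- cfg$onset_s + (seq_len(n) - 1) * interval
  y <- Reduce(`+`, Map(function(p, on) eval_single_flash(p, t - on),
                       flashes, onsets))
  y <- .add_noise(y, cfg)
  org_trace(t = t, dopl = y, fs = cfg$fs, stimulus_onsets = onsets,
            meta = list(scenario = "train", truth = flashes))
}

#' Simulate a flash-on-background trace
#'
#' Single-flash response plus the ungated linear ramp `m * t` (ramp time
#' base: 0 at flash onset, so the ramp is negative before onset), plus
#' noise.
#'
#' @param flash [response_params()].
#' @param m Background elongation slope, nm/s.
#' @param cfg [sim_config()].
#' @return An [org_trace()].
#' @export
simulate_background_trace <- function(flash, m, cfg = sim_config()) {
  stopifnot(inherits(flash, "org_params"))
  bp <- background_params(flash, m)
  t <- .sim_grid(cfg)
  y <- .add_noise(eval_background(bp, t - cfg$onset_s), cfg)
  org_trace(t = t, dopl = y, fs = cfg$fs, stimulus_onsets = cfg$onset_s,
            meta = list(scenario = "background", truth = bp))
}

#' Simulate a complex subvolume series encoding a trace
#'
#' Forward model inverse to [extract_trace()]: each A-scan gets a fixed
#' random ISOS phase; the COST phase adds the encoded phase
#' `dPhi(t) = dOPL(t) * 4 pi / lambda` (wrapping arises naturally from
#' the complex representation). Circular complex Gaussian noise is added
#' at the requested amplitude SNR (`Inf` = noiseless).
#'
#' @param trace [org_trace()] to encode.
#' @param amplitude_snr Ratio of signal amplitude to RMS complex noise
#'   magnitude; `Inf` for noiseless.
#' @param wavelength_nm Imaging wavelength, nm (default 850).
#' @param n_ascans Number of A-scans per subvolume (default 9).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A [cone_series()].
#' @export
simulate_subvolume_series <- function(trace, amplitude_snr = Inf,
                                      wavelength_nm = 850, n_ascans = 9,
                                      seed = NULL) {
  stopifnot(inherits(trace, "org_trace"), amplitude_snr > 0, n_ascans >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_t <- length(trace$t)
  psi <- runif(n_ascans, -pi, pi)                 # static per-A-scan phase
  dphi <- trace$dopl * 4 * pi / wavelength_nm     # encoded phase, rad
  isos <- exp(1i * matrix(psi, n_t, n_ascans, byrow = TRUE))
  cost <- isos * exp(1i * dphi)                   # recycled down columns
  if (is.finite(amplitude_snr)) {
    sd_q <- 1 / (amplitude_snr * sqrt(2))         # per-quadrature SD
    noise <- function() matrix(complex(real = rnorm(n_t * n_ascans, 0, sd_q),
                                       imaginary = rnorm(n_t * n_ascans, 0, sd_q)),
                               n_t, n_ascans)
    isos <- isos + noise()
    cost <- cost + noise()
  }
  cone_series(isos = isos, cost = cost, fs = trace$fs,
              wavelength_nm = wavelength_nm,
              stimulus_onsets = trace$stimulus_onsets)
}
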