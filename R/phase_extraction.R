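# Conversion of per-cone complex OCT samples to OPL traces.
#
# For each cone and timepoint, the phase difference between the COST and
# ISOS reflections is estimated as the angle of the vector sum of the
# per-A-scan products A_i * conj(B_i) (A = COST, B = ISOS) over the
# A-scans spanning the cone center. Summing before taking the angle
# weights each A-scan by its signal magnitude and rejects phase common to
# the two surfaces. Phase maps to OPL as dOPL = dPhi * lambda / (4 pi).

#' Per-cone complex subvolume series
#'
#' Complex ISOS and COST samples for one cone, indexed
#' `[timepoint, a_scan]` (default nine A-scans spanning the cone center).
#'
#' @param isos,cost Complex matrices `[timepoint, a_scan]` of equal
#'   shape.
#' @param fs Volume rate, Hz; > 0.
#' @param wavelength_nm Imaging center wavelength, nm (default 850).
#' @param stimulus_onsets Stimulus onset times, s.
#' @return An object of class `org_cone_series`.
#' @export
cone_series <- function(isos, cost, fs, wavelength_nm = 850,
                        stimulus_onsets = numeric(0)) {
  stopifnot(is.matrix(isos), is.matrix(cost), is.complex(isos) || is.numeric(isos),
            is.complex(cost) || is.numeric(cost))
  if (!all(dim(isos) == dim(cost))) stop("isos and cost shapes must match")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (wavelength_nm <= 0) stop("wavelength_nm must be > 0")
  structure(list(isos = isos + 0i, cost = cost + 0i, fs = as.numeric(fs),
                 wavelength_nm = as.numeric(wavelength_nm),
                 stimulus_onsets = as.numeric(stimulus_onsets)),
            class = "org_cone_series")
}

#' Wrapped ISOS-COST phase difference per timepoint
#'
#' `dPhi(t) = Arg( sum_i COST_i(t) * Conj(ISOS_i(t)) )` over the A-scans
#' of the subvolume. Timepoints whose vector sum has magnitude below
#' `1e-12` times the series mean magnitude have no defined phase and are
#' flagged (`NA` phase).
#'
#' @param series [cone_series()].
#' @return List with `phase` (rad, in (-pi, pi], `NA` where flagged) and
#'   `flagged` (logical).
#' @export
phase_difference_series <- function(series) {
  stopifnot(inherits(series, "org_cone_series"))
  prod <- series$cost * Conj(series$isos)
  vsum <- rowSums(prod)
  tol <- 1e-12 * mean(Mod(vsum))
  flagged <- Mod(vsum) < tol | !is.finite(Mod(vsum))
  phase <- Arg(vsum)
  phase[flagged] <- NA_real_
  list(phase = phase, flagged = flagged)
}

# map x into (-pi, pi]
.wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Temporally unwrap a wrapped phase sequence
#'
#' Successive frame-to-frame differences are mapped into `(-pi, pi]` and
#' cumulatively summed (first sample preserved), assuming the true
#' inter-frame phase change never exceeds pi in magnitude. OPL excursions
#' beyond lambda/4 (~212.5 nm at 850 nm) wrap the raw phase, so
#' unwrapping is required for large responses. `NA` (flagged) samples are
#' bridged: they stay `NA` and the unwrap offset is carried across them
#' from the last valid sample.
#'
#' @param wrapped Phase sequence, rad.
#' @return Unwrapped phase sequence, rad (same length, `NA` preserved).
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.numeric(wrapped))
  out <- rep(NA_real_, length(wrapped))
  last_val <- NA_real_   # unwrapped value at the last valid sample
  last_raw <- NA_real_
  for (i in seq_along(wrapped)) {
    if (is.na(wrapped[i])) next
    if (is.na(last_val)) {
      out[i] <- wrapped[i]
    } else {
      out[i] <- last_val + .wrap_phase(wrapped[i] - last_raw)
    }
    last_val <- out[i]
    last_raw <- wrapped[i]
  }
  out
}

#' Convert a phase difference to an OPL change
#'
#' `dOPL = dPhi * lambda / (4 pi)`: the factor 4 pi (rather than 2 pi)
#' accounts for the double pass of the probe light through the outer
#' segment.
#'
#' @param dphi Phase difference(s), rad.
#' @param wavelength_nm Imaging wavelength, nm; > 0.
#' @return OPL change, nm.
#' @export
phase_to_opl <- function(dphi, wavelength_nm = 850) {
  stopifnot(is.numeric(dphi))
  if (wavelength_nm <= 0) stop("wavelength_nm must be > 0")
  dphi * wavelength_nm / (4 * pi)
}

#' Extract an OPL trace from a complex subvolume series
#'
#' Pipeline: vector-sum phase difference, temporal unwrapping, phase to
#' OPL conversion, then zero-referencing to the mean of the baseline
#' window (default: all samples before the first stimulus onset).
#'
#' @param series [cone_series()].
#' @param baseline_window Length-2 numeric `c(start, end)` in s, or
#'   `NULL` for all pre-onset samples.
#' @return An [org_trace()]; flagged samples are `NA` and recorded in
#'   `meta$flagged`.
#' @export
extract_trace <- function(series, baseline_window = NULL) {
  stopifnot(inherits(series, "org_cone_series"))
  n <- nrow(series$isos)
  t <- (seq_len(n) - 1) / series$fs
  pd <- phase_difference_series(series)
  dphi <- unwrap_phase(pd$phase)
  dopl <- phase_to_opl(dphi, series$wavelength_nm)
  if (is.null(baseline_window)) {
    if (!length(series$stimulus_onsets))
      stop("no stimulus onsets: pass baseline_window explicitly")
    base_idx <- t < series$stimulus_onsets[1]
  } else {
    stopifnot(length(baseline_window) == 2L)
    base_idx <- t >= baseline_window[1] & t < baseline_window[2]
  }
  base_idx <- base_idx & !is.na(dopl)
  if (!any(base_idx)) stop("baseline window contains no valid samples")
  dopl <- dopl - mean(dopl[base_idx])
  org_trace(t = t, dopl = dopl, fs = series$fs,
            stimulus_onsets = series$stimulus_onsets,
            meta = list(flagged = pd$flagged,
                        wavelength_nm = series$wavelength_nm))
}
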