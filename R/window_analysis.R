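# Observation-window sensitivity: how truncating the post-onset record
# perturbs the fitted parameters, expressed as a percentage error against
# the full-window (reference) estimate.

#' Truncation sweep of the observation window
#'
#' Fits the single-flash model to truncated copies of the trace (all
#' pre-onset samples plus `window` seconds after onset) and reports, for
#' each parameter, the percentage error
#' `PE = |p - p_ref| / |p_ref| * 100` against the estimate from the
#' longest (reference) window. Fits that fail on short windows are
#' flagged and their PE left `NA`.
#'
#' @param trace [org_trace()].
#' @param windows Post-onset window durations, s, strictly increasing;
#'   default `seq(0.3, <post-onset duration>, by = 0.05)`. The longest
#'   window is the reference.
#' @param onset Flash onset, s; defaults to the trace's first onset.
#' @param threshold PE threshold (%) used by [minimum_window()] (default
#'   10).
#' @param ... Passed to [fit_single_flash()].
#' @return An object of class `org_window_sweep`: `windows`, `pe`
#'   (matrix window x parameter, %), `estimates`, `reference_window`,
#'   `reference_params`, `threshold`, `min_window_at_threshold`.
#' @export
truncation_sweep <- function(trace, windows = NULL, onset = NULL,
                             threshold = 10, ...) {
  stopifnot(inherits(trace, "org_trace"))
  onset <- .first_onset(trace, onset)
  post <- max(trace$t) - onset
  if (is.null(windows)) windows <- seq(0.3, post, by = 0.05)
  windows <- sort(unique(as.numeric(windows)))
  if (max(windows) > post + 1e-9)
    stop("longest window exceeds the post-onset record duration")

  par_names <- c("a0", "a1", "tau_a", "tau_b")
  est <- matrix(NA_real_, length(windows), 4,
                dimnames = list(NULL, par_names))
  ok <- logical(length(windows))
  for (i in seq_along(windows)) {
    keep <- trace$t <= onset + windows[i] + 1e-9
    sub <- org_trace(t = trace$t[keep], dopl = trace$dopl[keep],
                     fs = trace$fs, stimulus_onsets = trace$stimulus_onsets)
    f <- tryCatch(fit_single_flash(sub, onset = onset, ...),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged && !isTRUE(f$flags$degenerate)) {
      est[i, ] <- f$params[par_names]
      ok[i] <- TRUE
    }
  }
  ref_i <- length(windows)
  if (!ok[ref_i]) stop("reference (longest) window fit failed")
  ref <- est[ref_i, ]
  pe <- 100 * abs(sweep(est, 2, ref, "-")) / rep(abs(ref), each = nrow(est))
  pe[ref_i, ] <- 0   # by definition

  sweep_obj <- structure(list(windows = windows, pe = pe, estimates = est,
                              fit_ok = ok, reference_window = windows[ref_i],
                              reference_params = ref, threshold = threshold),
                         class = "org_window_sweep")
  sweep_obj$min_window_at_threshold <- minimum_window(sweep_obj, threshold)
  sweep_obj
}

#' Minimum observation window at a PE threshold
#'
#' For each parameter, the smallest window from which the percentage
#' error stays below `threshold` at every subsequent window through the
#' reference (a sustained criterion, conservative against transient dips
#' below threshold). Parameters that never sustain sub-threshold error
#' are reported `NA`.
#'
#' @param sweep A [truncation_sweep()] result.
#' @param threshold PE threshold, % (default the sweep's).
#' @return Named numeric vector of minimum windows, s (`NA` = not
#'   achieved).
#' @export
minimum_window <- function(sweep, threshold = NULL) {
  stopifnot(inherits(sweep, "org_window_sweep"))
  if (is.null(threshold)) threshold <- sweep$threshold
  apply(sweep$pe, 2, function(pe) {
    below <- pe < threshold & !is.na(pe)
    # last window NOT sustained-below determines the minimum
    ok_from <- rev(cumprod(rev(below))) == 1
    if (!any(ok_from)) return(NA_real_)
    sweep$windows[which(ok_from)[1]]
  })
}

#' @export
print.org_window_sweep <- function(x, ...) {
  cat(sprintf("Observation-window sweep: %d windows in [%g, %g] s (reference %g s)\n",
              length(x$windows), min(x$windows), max(x$windows),
              x$reference_window))
  cat(sprintf("Minimum window at PE < %g%%:\n", x$threshold))
  print(signif(x$min_window_at_threshold, 3))
  invisible(x)
}
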