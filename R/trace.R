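#' ORG trace: a uniformly sampled OPL time series
#'
#' @param t Sample times, s; strictly increasing and uniform (spacing
#'   `1/fs` to within 1e-9 s). If `NULL`, constructed as
#'   `(seq_along(dopl) - 1) / fs`.
#' @param dopl OPL change per sample, nm (`NA` allowed for flagged
#'   samples).
#' @param fs Sampling rate, Hz; > 0.
#' @param stimulus_onsets Stimulus onset times, s (same time base as `t`).
#' @param meta Free-form provenance list.
#' @return An object of class `org_trace`.
#' @examples
#' tr <- org_trace(dopl = rep(0, 400), fs = 400, stimulus_onsets = 0.2)
#' @export
org_trace <- function(t = NULL, dopl, fs, stimulus_onsets = numeric(0),
                      meta = list()) {
  stopifnot(is.numeric(dopl), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(t)) t <- (seq_along(dopl) - 1) / fs
  t <- as.numeric(t)
  if (length(t) != length(dopl))
    stop("t and dopl must have equal length")
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("t must be strictly increasing")
    bad <- which(abs(dt - 1 / fs) > 1e-9)
    if (length(bad))
      stop(sprintf("non-uniform time grid at index %d (spacing %.3g s, expected %.3g s)",
                   bad[1] + 1L, dt[bad[1]], 1 / fs))
  }
  structure(list(t = t, dopl = as.numeric(dopl), fs = as.numeric(fs),
                 stimulus_onsets = as.numeric(stimulus_onsets), meta = meta),
            class = "org_trace")
}

#' @export
print.org_trace <- function(x, ...) {
  cat(sprintf("ORG trace: %d samples at %g Hz (%.3f s), %d stimulus onset(s)\n",
              length(x$t), x$fs, diff(range(x$t)), length(x$stimulus_onsets)))
  if (length(x$stimulus_onsets))
    cat("  onsets (s):", paste(signif(x$stimulus_onsets, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.org_trace <- function(x, ...) {
  data.frame(time_s = x$t, dopl_nm = x$dopl)
}

# first onset, or error
.first_onset <- function(trace, onset = NULL) {
  if (!is.null(onset)) return(onset)
  if (!length(trace$stimulus_onsets))
    stop("trace has no stimulus onset; pass `onset` explicitly")
  trace$stimulus_onsets[1]
}
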