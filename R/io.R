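# File formats: traces as two-column CSV (time_s, dopl_nm) with an
# optional JSON sidecar holding the sampling rate, stimulus onsets and
# provenance; cone subvolume series as long-format CSV of complex
# components; fit reports as JSON validated against the schema shipped in
# inst/schema/.

#' Write an ORG trace to CSV (with JSON sidecar)
#'
#' Writes columns `time_s`, `dopl_nm` at full double precision, plus a
#' sidecar `<path>.json` carrying `fs_hz`, `stimulus_onsets_s` and
#' `meta` so that [read_trace()] round-trips losslessly.
#'
#' @param trace [org_trace()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "org_trace"))
  df <- data.frame(time_s = format(trace$t, digits = 17),
                   dopl_nm = format(trace$dopl, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- trace$meta
    meta <- meta[vapply(meta, function(x) is.atomic(x) || is.list(x), logical(1))]
    jsonlite::write_json(
      list(fs_hz = trace$fs, stimulus_onsets_s = trace$stimulus_onsets),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an ORG trace from CSV
#'
#' Expects columns `time_s` and `dopl_nm`; reads `fs_hz` and
#' `stimulus_onsets_s` from the `<path>.json` sidecar when present,
#' otherwise infers `fs` from the median time step. `NaN`/`NA` OPL
#' values are preserved and their indices recorded in `meta$na_index`.
#' A non-uniform time grid is an error naming the offending index.
#'
#' @param path CSV path.
#' @param fs Sampling rate override, Hz.
#' @param stimulus_onsets Onset override, s.
#' @return An [org_trace()].
#' @export
read_trace <- function(path, fs = NULL, stimulus_onsets = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "dopl_nm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("trace file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(fs)) fs <- sc$fs_hz
    if (is.null(stimulus_onsets)) stimulus_onsets <- sc$stimulus_onsets_s
  }
  if (is.null(fs)) fs <- 1 / median(diff(df$time_s))
  if (is.null(stimulus_onsets)) stimulus_onsets <- numeric(0)
  na_idx <- which(!is.finite(df$dopl_nm))
  org_trace(t = df$time_s, dopl = df$dopl_nm, fs = fs,
            stimulus_onsets = stimulus_onsets,
            meta = if (length(na_idx)) list(na_index = na_idx) else list())
}

#' Write a cone subvolume series to CSV
#'
#' Long format, one row per (timepoint, A-scan):
#' `time_index, a_scan, isos_re, isos_im, cost_re, cost_im`, plus a JSON
#' sidecar with `fs_hz`, `wavelength_nm`, `stimulus_onsets_s`.
#'
#' @param series [cone_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cone_series <- function(series, path) {
  stopifnot(inherits(series, "org_cone_series"))
  n_t <- nrow(series$isos); n_a <- ncol(series$isos)
  df <- data.frame(
    time_index = rep(seq_len(n_t), times = n_a),
    a_scan = rep(seq_len(n_a), each = n_t),
    isos_re = format(as.vector(Re(series$isos)), digits = 17),
    isos_im = format(as.vector(Im(series$isos)), digits = 17),
    cost_re = format(as.vector(Re(series$cost)), digits = 17),
    cost_im = format(as.vector(Im(series$cost)), digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs_hz = series$fs, wavelength_nm = series$wavelength_nm,
         stimulus_onsets_s = series$stimulus_onsets),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cone subvolume series from CSV
#'
#' @param path CSV path written by [write_cone_series()].
#' @return A [cone_series()].
#' @export
read_cone_series <- function(path) {
  df <- read.csv(path)
  need <- c("time_index", "a_scan", "isos_re", "isos_im", "cost_re", "cost_im")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("cone series file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("cone series sidecar not found: ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  n_t <- max(df$time_index); n_a <- max(df$a_scan)
  ord <- order(df$a_scan, df$time_index)
  df <- df[ord, ]
  isos <- matrix(complex(real = df$isos_re, imaginary = df$isos_im), n_t, n_a)
  cost <- matrix(complex(real = df$cost_re, imaginary = df$cost_im), n_t, n_a)
  cone_series(isos = isos, cost = cost, fs = sc$fs_hz,
              wavelength_nm = sc$wavelength_nm,
              stimulus_onsets = if (is.null(sc$stimulus_onsets_s)) numeric(0)
                                else sc$stimulus_onsets_s)
}

#' Convert a fit to a serializable report
#'
#' @param fit An `org_fit`.
#' @return A list matching the fit-report JSON schema shipped at
#'   `system.file("schema", "fit-report.schema.json", package = "coneorg")`.
#' @export
as_fit_report <- function(fit) {
  stopifnot(inherits(fit, "org_fit"))
  list(model_id = fit$model_id,
       params = as.list(fit$params),
       ci_low = as.list(fit$ci_low),
       ci_high = as.list(fit$ci_high),
       r_squared = fit$r_squared,
       rms_nm = fit$rms_nm,
       rms_late_nm = fit$rms_late_nm,
       flags = list(converged = fit$converged,
                    degenerate = isTRUE(fit$flags$degenerate),
                    reliable = as.list(fit$flags$reliable)),
       n_points = fit$n_points,
       weights_applied = fit$weights_applied)
}

#' Validate a fit report against the shipped schema
#'
#' Structural validation (required fields present, types sane) against
#' the JSON schema in `inst/schema/`.
#'
#' @param report A list (e.g. from [as_fit_report()] or parsed JSON).
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_fit_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "fit-report.schema.json", package = "coneorg"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("fit report is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (!(is.character(report$model_id) && length(report$model_id) == 1L))
    stop("model_id must be a single string")
  for (f in c("params", "ci_low", "ci_high"))
    if (!is.list(report[[f]]) || is.null(names(report[[f]])))
      stop(f, " must be a named mapping")
  for (f in c("rms_nm", "n_points"))
    if (!is.numeric(report[[f]])) stop(f, " must be numeric")
  invisible(TRUE)
}
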