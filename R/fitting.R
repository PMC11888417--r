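# Constrained, weighted least-squares estimation of the response models.
#
# All fits use bounded Levenberg-Marquardt (trust-region) minimization of
# the weighted residual sum of squares, with rate constants constrained to
# (1e-6, Inf) s^-1 so the response cannot diverge as t -> Inf. Because the
# rapid contraction spans only a few samples at ~400 Hz and would otherwise
# contribute 1-3% of the SSE, squared residuals inside a short window after
# each onset are multiplied by a contraction weight (default 10).
# 95% confidence bounds come from the local linearization at the optimum
# (Jacobian-based covariance, t-distribution with n - p dof).

.TAU_MIN <- 1e-6

#' Contraction weights for a residual vector
#'
#' Returns the per-sample weight applied to *squared* residuals: `factor`
#' inside `[onset, onset + window]` for every onset, 1 elsewhere. Scaling
#' `factor` by k scales the weighted-SSE contribution of the contraction
#' region by exactly k.
#'
#' @param t Sample times, s.
#' @param onsets Stimulus onset time(s), s.
#' @param factor Weight multiplier (default 10).
#' @param window Weighted-window duration after each onset, s (default
#'   0.025, i.e. 10 samples at 400 Hz -- covers the 5-8 ms contraction
#'   with margin).
#' @return Numeric weight vector, same length as `t`.
#' @export
contraction_weights <- function(t, onsets = 0, factor = 10, window = 0.025) {
  stopifnot(is.numeric(t), factor > 0, window >= 0)
  w <- rep(1, length(t))
  for (on in onsets) w[t >= on & t <= on + window] <- factor
  w
}

# central-difference Jacobian of model(par) wrt par
.num_jacobian <- function(model, par) {
  n <- length(model(par))
  J <- matrix(NA_real_, n, length(par))
  for (j in seq_along(par)) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (model(pp) - model(pm)) / (2 * h)
  }
  J
}

# Bounded LM fit of y ~ model(par) with weights w on squared residuals.
# Returns par, se, ci at `level`, convergence flag and fitted values.
.lm_fit <- function(y, model, par0, lower, upper, w, level = 0.95) {
  sw <- sqrt(w)
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) sw * (y - model(p)),
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-14, ptol = 1e-14))
  par <- res$par
  n <- length(y); p <- length(par)
  dof <- max(n - p, 1L)
  yhat <- model(par)
  # The contraction weights are emphasis weights, not inverse variances:
  # under homoscedastic noise the covariance of the weighted-LS estimator
  # is the sandwich sigma^2 (J'WJ)^-1 J'W^2J (J'WJ)^-1, with sigma^2
  # estimated from the unweighted residuals. Reduces to the usual
  # formula when all weights are 1.
  sigma2 <- sum((y - yhat)^2) / dof
  J <- .num_jacobian(model, par)
  JW <- J * w
  cov <- tryCatch({
    A <- solve(crossprod(J, JW))
    sigma2 * A %*% crossprod(JW) %*% A
  }, error = function(e) NULL)
  degenerate_ci <- is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)
  se <- if (degenerate_ci) rep(NA_real_, p) else sqrt(diag(cov))
  tq <- qt(1 - (1 - level) / 2, dof)
  list(par = par, se = setNames(se, names(par)),
       ci_low = par - tq * se, ci_high = par + tq * se,
       converged = res$info %in% c(1, 2, 3, 4),
       degenerate_ci = degenerate_ci, yhat = yhat, n = n, dof = dof)
}

# apply the (a1, tau_a, tau_b) -> (-a1, tau_b, tau_a) identity to a fit
# block so tau_a >= tau_b; `idx` names the a1/tau_a/tau_b entries.
.canonicalize_fit <- function(f, idx) {
  if (f$par[idx["tau_a"]] >= f$par[idx["tau_b"]]) return(f)
  swp <- function(v) {
    tmp <- v[idx["tau_a"]]; v[idx["tau_a"]] <- v[idx["tau_b"]]; v[idx["tau_b"]] <- tmp
    v
  }
  f$par <- swp(f$par); f$se <- swp(f$se)
  lo <- swp(f$ci_low); hi <- swp(f$ci_high)
  # negate a1: interval flips
  a1 <- idx["a1"]
  f$par[a1] <- -f$par[a1]
  new_lo <- -hi[a1]; new_hi <- -lo[a1]
  f$ci_low <- lo; f$ci_high <- hi
  f$ci_low[a1] <- new_lo; f$ci_high[a1] <- new_hi
  f
}

.new_org_fit <- function(model_id, lmres, trace_t_rel, y, weights_desc,
                         reliable = NULL, degenerate = FALSE,
                         late_from = 0.5) {
  gof <- .gof(trace_t_rel, y, lmres$yhat, late_from = late_from)
  structure(list(
    model_id = model_id,
    params = lmres$par,
    se = lmres$se,
    ci_low = lmres$ci_low,
    ci_high = lmres$ci_high,
    r_squared = gof$r_squared,
    rms_nm = gof$rms_nm,
    rms_late_nm = gof$rms_late_nm,
    weights_applied = weights_desc,
    converged = lmres$converged,
    n_points = lmres$n,
    flags = list(degenerate = degenerate || lmres$degenerate_ci,
                 constant_trace = gof$constant,
                 reliable = reliable),
    fitted = lmres$yhat,
    t_rel = trace_t_rel,
    data = y
  ), class = "org_fit")
}

.gof <- function(t_rel, y, yhat, late_from = 0.5) {
  r <- y - yhat
  ss_tot <- sum((y - mean(y))^2)
  late <- t_rel >= late_from
  list(r_squared = if (ss_tot > 0) 1 - sum(r^2) / ss_tot else NA_real_,
       rms_nm = sqrt(mean(r^2)),
       rms_late_nm = if (any(late)) sqrt(mean(r[late]^2)) else NA_real_,
       constant = ss_tot == 0)
}

#' Goodness of fit of a model evaluation against a trace
#'
#' Unweighted R^2 (`1 - SSE/SST`), the RMS residual over the whole record,
#' and the RMS residual restricted to `t - onset >= late_from` (default
#' 0.5 s). The late-window RMS allows fair comparison of models that do
#' not represent the initial contraction.
#'
#' @param trace [org_trace()].
#' @param yhat Model evaluation at the trace sample times, nm.
#' @param onset Flash onset, s; defaults to the trace's first stimulus
#'   onset.
#' @param late_from Start of the late window, s after onset.
#' @return List with `r_squared` (NA with `constant = TRUE` for a
#'   constant trace), `rms_nm`, `rms_late_nm`, `constant`.
#' @export
goodness_of_fit <- function(trace, yhat, onset = NULL, late_from = 0.5) {
  stopifnot(inherits(trace, "org_trace"), length(yhat) == length(trace$dopl))
  onset <- .first_onset(trace, onset)
  ok <- is.finite(trace$dopl) & is.finite(yhat)
  .gof(trace$t[ok] - onset, trace$dopl[ok], yhat[ok], late_from = late_from)
}

# prepare (t_rel, y, drop-NA) for a fit; optional pre-onset zero-reference
.fit_data <- function(trace, onset, baseline = TRUE) {
  ok <- is.finite(trace$dopl)
  t_rel <- trace$t[ok] - onset
  y <- trace$dopl[ok]
  if (baseline && any(t_rel < 0)) y <- y - mean(y[t_rel < 0])
  list(t_rel = t_rel, y = y)
}

.default_reliability <- c(a0 = 0, a1 = 1.0, tau_a = 1.0, tau_b = 2.85)

#' Fit the single-flash response model to a trace
#'
#' Weighted, bounded trust-region least squares of the four-parameter
#' biexponential model. Squared residuals within `weight_window` after
#' onset are multiplied by `weight_factor` so the few contraction samples
#' are captured accurately. Rate constants are bounded below by 1e-6
#' s^-1. Fitted parameters are reported in canonical orientation
#' (`tau_a >= tau_b`); 95% confidence bounds come from the Jacobian-based
#' covariance at the optimum.
#'
#' The trace is zero-referenced to the mean of its pre-onset samples when
#' `baseline = TRUE` (default). Non-convergence is reported through the
#' `converged` flag rather than an error, so batches over many cones keep
#' running; an all-constant trace yields a zero-amplitude fit flagged
#' `degenerate`.
#'
#' Per-parameter reliability flags mark estimates whose post-onset
#' observation window is shorter than `reliability_thresholds` (s):
#' slow-recovery estimates in particular need multi-second windows.
#'
#' @param trace [org_trace()].
#' @param onset Flash onset, s; defaults to the trace's first stimulus
#'   onset.
#' @param weight_factor Contraction weight multiplier (default 10).
#' @param weight_window Contraction window after onset, s (default 0.025).
#' @param baseline Zero-reference to the pre-onset mean?
#' @param reliability_thresholds Named vector of minimum post-onset window
#'   durations (s) per parameter.
#' @return An object of class `org_fit`; see [goodness_of_fit()] for the
#'   fit-quality fields.
#' @examples
#' p <- response_params(-36.4, 200.8, 9.5, 0.07)
#' tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 0))
#' fit <- fit_single_flash(tr)
#' fit$params
#' @export
fit_single_flash <- function(trace, onset = NULL, weight_factor = 10,
                             weight_window = 0.025, baseline = TRUE,
                             reliability_thresholds = .default_reliability) {
  stopifnot(inherits(trace, "org_trace"))
  onset <- .first_onset(trace, onset)
  d <- .fit_data(trace, onset, baseline)
  if (sum(d$t_rel >= 0) < 8L) stop("need at least 8 post-onset samples")
  post_window <- max(d$t_rel)
  reliable <- post_window >= reliability_thresholds[c("a0", "a1", "tau_a", "tau_b")]
  names(reliable) <- c("a0", "a1", "tau_a", "tau_b")

  if (sd(d$y) == 0) {
    # constant (e.g. all-zero) trace: zero-amplitude fit, degenerate CIs
    par <- c(a0 = 0, a1 = 0, tau_a = 5, tau_b = 0.1)
    lmres <- list(par = par, se = setNames(rep(NA_real_, 4), names(par)),
                  ci_low = setNames(rep(NA_real_, 4), names(par)),
                  ci_high = setNames(rep(NA_real_, 4), names(par)),
                  converged = TRUE, degenerate_ci = TRUE,
                  yhat = rep(d$y[1], length(d$y)), n = length(d$y),
                  dof = length(d$y) - 4L)
    return(.new_org_fit("single_flash", lmres, d$t_rel, d$y,
                        sprintf("x%g in [onset, onset+%g s]", weight_factor,
                                weight_window),
                        reliable = reliable, degenerate = TRUE))
  }

  early <- d$y[d$t_rel >= 0 & d$t_rel <= 0.05]
  a0_init <- if (length(early)) min(early) else min(d$y)
  a1_init <- max(d$y) - a0_init
  par0 <- c(a0 = a0_init, a1 = a1_init, tau_a = 5, tau_b = 0.1)
  model <- function(p) {
    out <- numeric(length(d$t_rel))
    on <- d$t_rel >= 0
    tt <- d$t_rel[on]
    out[on] <- p[["a0"]] + p[["a1"]] * (-exp(-p[["tau_a"]] * tt) +
                                          exp(-p[["tau_b"]] * tt))
    out
  }
  w <- contraction_weights(d$t_rel, onsets = 0, factor = weight_factor,
                           window = weight_window)
  lmres <- .lm_fit(d$y, model, par0,
                   lower = c(a0 = -Inf, a1 = -Inf, tau_a = .TAU_MIN, tau_b = .TAU_MIN),
                   upper = rep(Inf, 4), w = w)
  lmres <- .canonicalize_fit(lmres, c(a1 = "a1", tau_a = "tau_a", tau_b = "tau_b"))
  .new_org_fit("single_flash", lmres, d$t_rel, d$y,
               sprintf("x%g in [onset, onset+%g s]", weight_factor, weight_window),
               reliable = reliable)
}

#' Fit the shifted-sum paired-flash model to a trace
#'
#' Joint bounded least-squares fit of all eight parameters (four per
#' flash). Contraction weighting is applied after both onsets. Each
#' flash's parameter block is canonicalized independently. Reliability
#' flags use each flash's own observation window: the first flash is
#' observed cleanly only for `t_isi` before the second begins, and the
#' second from its onset to the end of the record.
#'
#' @inheritParams fit_single_flash
#' @param t_isi Inter-stimulus (onset-to-onset) interval, s; > 0.
#' @return An `org_fit` with parameters named `*_alpha` and `*_beta`.
#' @export
fit_two_flash <- function(trace, t_isi, onset = NULL, weight_factor = 10,
                          weight_window = 0.025, baseline = TRUE,
                          reliability_thresholds = .default_reliability) {
  stopifnot(inherits(trace, "org_trace"))
  if (!is.numeric(t_isi) || t_isi <= 0) stop("t_isi must be > 0")
  onset <- .first_onset(trace, onset)
  d <- .fit_data(trace, onset, baseline)
  if (max(d$t_rel) <= t_isi) stop("trace must cover both flash onsets")

  early <- d$y[d$t_rel >= 0 & d$t_rel <= min(t_isi, 0.05)]
  a0_init <- if (length(early)) min(early) else min(d$y)
  a1_init <- max(d$y) - a0_init
  par0 <- c(a0_alpha = a0_init, a1_alpha = 0.6 * a1_init,
            tau_a_alpha = 5, tau_b_alpha = 0.1,
            a0_beta = 0.7 * a0_init, a1_beta = 0.4 * a1_init,
            tau_a_beta = 5, tau_b_beta = 0.1)
  model <- function(p) {
    f <- function(tt, a0, a1, ta, tb) {
      out <- numeric(length(tt)); on <- tt >= 0
      out[on] <- a0 + a1 * (-exp(-ta * tt[on]) + exp(-tb * tt[on]))
      out
    }
    f(d$t_rel, p[["a0_alpha"]], p[["a1_alpha"]], p[["tau_a_alpha"]], p[["tau_b_alpha"]]) +
      f(d$t_rel - t_isi, p[["a0_beta"]], p[["a1_beta"]], p[["tau_a_beta"]], p[["tau_b_beta"]])
  }
  w <- contraction_weights(d$t_rel, onsets = c(0, t_isi),
                           factor = weight_factor, window = weight_window)
  lower <- rep(-Inf, 8); upper <- rep(Inf, 8)
  names(lower) <- names(upper) <- names(par0)
  lower[c("tau_a_alpha", "tau_b_alpha", "tau_a_beta", "tau_b_beta")] <- .TAU_MIN
  lmres <- .lm_fit(d$y, model, par0, lower, upper, w)
  lmres <- .canonicalize_fit(lmres, c(a1 = "a1_alpha", tau_a = "tau_a_alpha",
                                      tau_b = "tau_b_alpha"))
  lmres <- .canonicalize_fit(lmres, c(a1 = "a1_beta", tau_a = "tau_a_beta",
                                      tau_b = "tau_b_beta"))

  win_alpha <- t_isi
  win_beta <- max(d$t_rel) - t_isi
  th <- reliability_thresholds[c("a0", "a1", "tau_a", "tau_b")]
  reliable <- c(win_alpha >= th, win_beta >= th)
  names(reliable) <- names(par0)

  fit <- .new_org_fit("two_flash", lmres, d$t_rel, d$y,
                      sprintf("x%g after both onsets (window %g s)",
                              weight_factor, weight_window),
                      reliable = reliable)
  fit$t_isi <- t_isi
  fit
}

#' Fit the flash-on-background model to a trace
#'
#' Joint fit of the four flash parameters plus the background ramp slope
#' `m`. The ramp is active over the whole record, so the pre-onset
#' samples (at least ~0.1 s of them) identify `m` partly on their own.
#' The trace is *not* zero-referenced to the pre-onset mean by default:
#' the ramp runs before onset, and referencing would fold part of it into
#' an un-modeled offset.
#'
#' @inheritParams fit_single_flash
#' @param baseline Zero-reference to the pre-onset mean? Default `FALSE`
#'   for this model (see Details).
#' @return An `org_fit` with parameters `a0`, `a1`, `tau_a`, `tau_b`,
#'   `m`.
#' @export
fit_background <- function(trace, onset = NULL, weight_factor = 10,
                           weight_window = 0.025, baseline = FALSE,
                           reliability_thresholds = .default_reliability) {
  stopifnot(inherits(trace, "org_trace"))
  onset <- .first_onset(trace, onset)
  d <- .fit_data(trace, onset, baseline)
  if (sum(d$t_rel < 0) < 2L)
    stop("fit_background needs pre-onset samples to identify the ramp")

  pre <- d$t_rel < 0
  m_init <- unname(coef(lm(d$y[pre] ~ d$t_rel[pre]))[2])
  if (!is.finite(m_init)) m_init <- 0
  resid0 <- d$y - m_init * d$t_rel
  early <- resid0[d$t_rel >= 0 & d$t_rel <= 0.05]
  a0_init <- if (length(early)) min(early) else min(resid0)
  par0 <- c(a0 = a0_init, a1 = max(resid0) - a0_init, tau_a = 5, tau_b = 0.1,
            m = m_init)
  model <- function(p) {
    out <- p[["m"]] * d$t_rel
    on <- d$t_rel >= 0
    tt <- d$t_rel[on]
    out[on] <- out[on] + p[["a0"]] +
      p[["a1"]] * (-exp(-p[["tau_a"]] * tt) + exp(-p[["tau_b"]] * tt))
    out
  }
  w <- contraction_weights(d$t_rel, onsets = 0, factor = weight_factor,
                           window = weight_window)
  lmres <- .lm_fit(d$y, model, par0,
                   lower = c(a0 = -Inf, a1 = -Inf, tau_a = .TAU_MIN,
                             tau_b = .TAU_MIN, m = -Inf),
                   upper = rep(Inf, 5), w = w)
  lmres <- .canonicalize_fit(lmres, c(a1 = "a1", tau_a = "tau_a", tau_b = "tau_b"))
  post_window <- max(d$t_rel)
  reliable <- c(post_window >= reliability_thresholds[c("a0", "a1", "tau_a", "tau_b")],
                m = TRUE)
  names(reliable) <- c("a0", "a1", "tau_a", "tau_b", "m")
  .new_org_fit("background", lmres, d$t_rel, d$y,
               sprintf("x%g in [onset, onset+%g s]", weight_factor, weight_window),
               reliable = reliable)
}

# model-specific setup for the alternative parameterizations
.alt_setup <- function(model_id, d) {
  ymax <- max(d$y)
  switch(model_id,
    magenta = list(par0 = c(a0 = min(d$y), a1 = ymax - min(d$y), tau_a = 5, tau_b = 0.1),
                   lower = c(-Inf, -Inf, .TAU_MIN, .TAU_MIN), weighted = TRUE),
    green   = list(par0 = c(a1 = ymax, tau_a = 5, tau_b = 0.1, t0 = 0.02),
                   lower = c(-Inf, .TAU_MIN, .TAU_MIN, 0), weighted = TRUE),
    red     = list(par0 = c(a1 = ymax, tau_a = 2),
                   lower = c(-Inf, .TAU_MIN), weighted = FALSE),
    blue    = list(par0 = c(a1 = ymax, tau_a = 5, tau_b = 0.1),
                   lower = c(-Inf, .TAU_MIN, .TAU_MIN), weighted = FALSE),
    cyan    = list(par0 = c(a0 = ymax / 2, a1 = ymax / 2, tau_a = 1.5, tau_b = 3),
                   lower = c(-Inf, -Inf, .TAU_MIN, .TAU_MIN), weighted = FALSE))
}

#' Fit one alternative single-flash parameterization
#'
#' Contraction weighting is applied only to models that represent the
#' contraction (magenta, green); the contraction-free red, blue and cyan
#' models are fitted unweighted, and should be compared on the
#' late-window RMS (`rms_late_nm`).
#'
#' @inheritParams fit_single_flash
#' @param model_id One of `"magenta"`, `"green"`, `"red"`, `"blue"`,
#'   `"cyan"` (see [alt_model_spec()]).
#' @return An `org_fit`.
#' @export
fit_alternative <- function(trace, model_id, onset = NULL, weight_factor = 10,
                            weight_window = 0.025, baseline = TRUE) {
  stopifnot(inherits(trace, "org_trace"))
  model_id <- match.arg(model_id, c("magenta", "green", "red", "blue", "cyan"))
  onset <- .first_onset(trace, onset)
  d <- .fit_data(trace, onset, baseline)
  setup <- .alt_setup(model_id, d)
  model <- function(p) {
    spec <- do.call(alt_model_spec, c(list(model_id = model_id),
                                      as.list(pmax(p, setup$lower))))
    eval_alternative(spec, d$t_rel)
  }
  w <- if (setup$weighted)
    contraction_weights(d$t_rel, 0, weight_factor, weight_window)
  else rep(1, length(d$t_rel))
  lower <- setNames(setup$lower, names(setup$par0))
  lmres <- .lm_fit(d$y, model, setup$par0, lower,
                   rep(Inf, length(setup$par0)), w)
  if (all(c("tau_a", "tau_b") %in% names(lmres$par)) && model_id != "cyan")
    lmres <- .canonicalize_fit(lmres, c(a1 = "a1", tau_a = "tau_a", tau_b = "tau_b"))
  .new_org_fit(model_id, lmres, d$t_rel, d$y,
               if (setup$weighted)
                 sprintf("x%g in [onset, onset+%g s]", weight_factor, weight_window)
               else "unweighted")
}

#' Fit and compare alternative single-flash models on one trace
#'
#' Fits each requested model and tabulates full-window and late-window
#' RMS residuals so contraction-free models can be compared fairly.
#'
#' @inheritParams fit_alternative
#' @param model_ids Models to fit.
#' @return A list with `fits` (named list of `org_fit`) and `table`
#'   (data.frame with model, n_params, r_squared, rms_nm, rms_late_nm,
#'   converged).
#' @export
compare_models <- function(trace, model_ids = c("magenta", "green", "red",
                                                "blue", "cyan"),
                           onset = NULL, weight_factor = 10,
                           weight_window = 0.025) {
  fits <- lapply(model_ids, function(id)
    fit_alternative(trace, id, onset = onset, weight_factor = weight_factor,
                    weight_window = weight_window))
  names(fits) <- model_ids
  tab <- data.frame(
    model = model_ids,
    n_params = vapply(fits, function(f) length(f$params), integer(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    rms_nm = vapply(fits, function(f) f$rms_nm, numeric(1)),
    rms_late_nm = vapply(fits, function(f) f$rms_late_nm, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    row.names = NULL)
  list(fits = fits, table = tab)
}

#' Ratios of second-flash to first-flash parameter estimates
#'
#' For each of the four parameter pairs of a paired-flash fit, the ratio
#' `beta/alpha` and its propagated standard uncertainty
#' `|ratio| * sqrt((sigma_alpha/alpha)^2 + (sigma_beta/beta)^2)`,
#' assuming independence, with per-parameter sigma recovered from the 95%
#' confidence interval width (`(ci_high - ci_low) / (2 * 1.96)`). A ratio
#' is flagged reliable only when both of its operands are.
#'
#' @param fit A [fit_two_flash()] result with finite confidence bounds.
#' @return data.frame with columns `name`, `ratio`, `sigma`, `reliable`.
#' @export
response_ratios <- function(fit) {
  stopifnot(inherits(fit, "org_fit"))
  if (fit$model_id != "two_flash")
    stop("response_ratios requires a two-flash fit")
  out <- lapply(c("a0", "a1", "tau_a", "tau_b"), function(nm) {
    a <- fit$params[[paste0(nm, "_alpha")]]
    b <- fit$params[[paste0(nm, "_beta")]]
    if (abs(a) < 1e-12)
      stop(sprintf("alpha estimate of %s is (near) zero; ratio undefined", nm))
    sig_a <- (fit$ci_high[[paste0(nm, "_alpha")]] -
                fit$ci_low[[paste0(nm, "_alpha")]]) / (2 * 1.96)
    sig_b <- (fit$ci_high[[paste0(nm, "_beta")]] -
                fit$ci_low[[paste0(nm, "_beta")]]) / (2 * 1.96)
    ratio <- b / a
    data.frame(name = nm, ratio = ratio,
               sigma = abs(ratio) * sqrt((sig_a / a)^2 + (sig_b / b)^2),
               reliable = isTRUE(fit$flags$reliable[[paste0(nm, "_alpha")]]) &&
                          isTRUE(fit$flags$reliable[[paste0(nm, "_beta")]]))
  })
  do.call(rbind, out)
}

#' Linear trend of parameter ratios against inter-stimulus interval
#'
#' Ordinary least squares of ratio on `t_isi`; `t_unity`, the interval at
#' which the ratio line reaches 1, is `(1 - intercept) / slope`.
#'
#' @param t_isi Inter-stimulus intervals, s (at least two distinct
#'   values).
#' @param ratio Corresponding beta/alpha ratios.
#' @return List with `slope` (1/s), `intercept`, `t_unity` (s; `NA` with
#'   `t_unity_defined = FALSE` when the trend is flat).
#' @export
ratio_trend <- function(t_isi, ratio) {
  stopifnot(is.numeric(t_isi), is.numeric(ratio),
            length(t_isi) == length(ratio))
  if (length(t_isi) < 2L) stop("need at least 2 points")
  if (length(unique(t_isi)) < 2L) stop("t_isi values must not be identical")
  fit <- lm(ratio ~ t_isi)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  flat <- abs(slope) < 1e-12
  list(slope = slope, intercept = intercept,
       t_unity = if (flat) NA_real_ else (1 - intercept) / slope,
       t_unity_defined = !flat)
}

#' @export
print.org_fit <- function(x, ...) {
  cat(sprintf("ORG model fit (%s), %d points%s\n", x$model_id, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$params, ci_low = x$ci_low, ci_high = x$ci_high)
  print(signif(tab, 5))
  cat(sprintf("R^2 = %.4f, RMS = %.3f nm, late RMS = %.3f nm (weights: %s)\n",
              x$r_squared, x$rms_nm, x$rms_late_nm, x$weights_applied))
  invisible(x)
}
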