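test_that("noiseless single-flash traces are recovered to high precision", {
  p <- exemplar_params()
  tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 0))
  fit <- fit_single_flash(tr)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params, c(-36.4, 200.8, 9.5, 0.07)), 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$rms_nm, 1e-6)
})

test_that("noisy single-flash fits have high R^2 and sub-noise-floor RMS", {
  p <- exemplar_params()
  tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 10, seed = 1))
  fit <- fit_single_flash(tr)
  # R^2 should sit near the signal-to-total variance ratio for sigma = 10
  signal <- eval_single_flash(p, tr$t - 0.2)
  r2_expected <- var(signal) / (var(signal) + 100)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(fit$r_squared, r2_expected, tolerance = 0.02)
  expect_lt(fit$rms_nm, 22)
  # parameters land near the generating values
  expect_lt(rel_err(fit$params[c("a0", "a1", "tau_a")],
                    c(-36.4, 200.8, 9.5)), 0.25)
})

test_that("constant traces give a degenerate zero-amplitude fit, not an error", {
  tr <- org_trace(dopl = rep(0, 1200), fs = 400, stimulus_onsets = 0.2)
  fit <- fit_single_flash(tr)
  expect_true(fit$flags$degenerate)
  expect_equal(unname(fit$params["a1"]), 0)
  expect_true(is.na(fit$r_squared))
  expect_true(all(is.na(fit$ci_low)))
})

test_that("contraction weighting scales the region's objective contribution exactly", {
  t <- seq(-0.2, 2.8, by = 1 / 400)
  resid <- sin(seq_along(t))  # fixed residual vector
  in_region <- t >= 0 & t <= 0.025
  for (k in c(1, 3, 10)) {
    w <- contraction_weights(t, onsets = 0, factor = 10 * k, window = 0.025)
    w_base <- contraction_weights(t, onsets = 0, factor = 10, window = 0.025)
    contrib <- sum((w * resid^2)[in_region])
    contrib_base <- sum((w_base * resid^2)[in_region])
    expect_equal(contrib, k * contrib_base)
    # outside the region the objective is untouched
    expect_equal(sum((w * resid^2)[!in_region]),
                 sum(resid[!in_region]^2))
  }
})

test_that("round-trip recovery holds across random parameter draws", {
  for (q in draw_params(12, seed = 42)) {
    tr <- simulate_single_flash_trace(q, sim_config(noise_sigma_nm = 0))
    fit <- fit_single_flash(tr)
    expect_lt(rel_err(fit$params, c(q$a0, q$a1, q$tau_a, q$tau_b)), 1e-3)
    # canonical orientation
    expect_gte(fit$params[["tau_a"]], fit$params[["tau_b"]])
    expect_gte(fit$params[["a1"]], 0)
  }
})

test_that("95% CIs cover the generating amplitudes at near-nominal rate", {
  p <- exemplar_params()
  truth <- c(a0 = -36.4, a1 = 200.8)
  hits <- matrix(NA, 120, 2, dimnames = list(NULL, names(truth)))
  for (s in seq_len(nrow(hits))) {
    tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 10,
                                                    seed = s))
    fit <- fit_single_flash(tr)
    hits[s, ] <- fit$ci_low[names(truth)] <= truth &
      truth <= fit$ci_high[names(truth)]
  }
  expect_gte(mean(hits[, "a0"]), 0.85)
  expect_gte(mean(hits[, "a1"]), 0.85)
})

test_that("two-flash fits recover both responses and flag the null flash", {
  p <- exemplar_params()
  tr <- simulate_two_flash_trace(p, 0.3, sim_config(noise_sigma_nm = 0))
  fit <- fit_two_flash(tr, 0.3)
  truth <- with(tr$meta$truth, c(alpha$a0, alpha$a1, alpha$tau_a, alpha$tau_b,
                                 beta$a0, beta$a1, beta$tau_a, beta$tau_b))
  expect_lt(rel_err(fit$params, truth), 1e-2)
  expect_error(fit_two_flash(tr, t_isi = 0), "t_isi")

  # alpha-only trace: fitted beta amplitudes statistically zero
  noise_cfg <- sim_config(noise_sigma_nm = 5, seed = 21)
  tr1 <- simulate_single_flash_trace(p, noise_cfg)
  fit1 <- fit_two_flash(tr1, 0.3)
  for (nm in c("a0_beta", "a1_beta"))
    expect_true(fit1$ci_low[[nm]] <= 0 && 0 <= fit1$ci_high[[nm]])
})

test_that("mean fitted contraction ratio tracks the generating attenuation", {
  p <- exemplar_params()
  t_isi <- 0.2
  gen_ratio <- min(1, 2.3 * t_isi + 0.31)
  ratios <- vapply(1:60, function(s) {
    tr <- simulate_two_flash_trace(p, t_isi,
                                   sim_config(noise_sigma_nm = 10, seed = s))
    fit <- fit_two_flash(tr, t_isi)
    fit$params[["a0_beta"]] / fit$params[["a0_alpha"]]
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - gen_ratio), 2 * se + 0.02)
})

test_that("background fits recover the flash parameters and ramp slope", {
  p <- exemplar_params()
  tr <- simulate_background_trace(p, 20, sim_config(noise_sigma_nm = 0))
  fit <- fit_background(tr)
  expect_lt(rel_err(fit$params, c(-36.4, 200.8, 9.5, 0.07, 20)), 1e-3)

  # m = 0 traces: the slope CI covers zero at near-nominal rate
  cover <- vapply(1:40, function(s) {
    tr0 <- simulate_background_trace(p, 0, sim_config(noise_sigma_nm = 5,
                                                      seed = s))
    fit0 <- fit_background(tr0)
    fit0$ci_low[["m"]] <= 0 && 0 <= fit0$ci_high[["m"]]
  }, logical(1))
  expect_gte(mean(cover), 0.8)

  # pure ramp: linear-regression limit
  zero <- response_params(0, 0, 5, 0.1)
  trr <- simulate_background_trace(zero, 12.5, sim_config(noise_sigma_nm = 0))
  fitr <- fit_background(trr)
  expect_equal(fitr$params[["m"]], 12.5, tolerance = 1e-6)
})

test_that("goodness of fit reports R^2 and full/late RMS correctly", {
  p <- exemplar_params()
  tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 0))
  yhat <- eval_single_flash(p, tr$t - 0.2)
  g <- goodness_of_fit(tr, yhat)
  expect_equal(g$r_squared, 1)
  expect_equal(g$rms_nm, 0)
  # residuals all equal to c -> RMS = |c|
  g2 <- goodness_of_fit(tr, yhat - 3)
  expect_equal(g2$rms_nm, 3)
  expect_equal(g2$rms_late_nm, 3)
  # hand-computed residual vector on a short trace
  tr3 <- org_trace(dopl = c(1, 2, 3, 4), fs = 1, stimulus_onsets = 0)
  g3 <- goodness_of_fit(tr3, c(1, 1, 1, 1), onset = 0)
  expect_equal(g3$rms_nm, sqrt(mean(c(0, 1, 2, 3)^2)))
  # constant trace: R^2 undefined and flagged
  trc <- org_trace(dopl = rep(2, 10), fs = 1, stimulus_onsets = 0)
  gc <- goodness_of_fit(trc, rep(0, 10))
  expect_true(is.na(gc$r_squared))
  expect_true(gc$constant)
})

test_that("ratio uncertainty follows the independence propagation formula", {
  fake <- structure(list(
    model_id = "two_flash",
    params = c(a0_alpha = -30, a1_alpha = 200, tau_a_alpha = 9, tau_b_alpha = 0.07,
               a0_beta = -30, a1_beta = 200, tau_a_beta = 9, tau_b_beta = 0.07),
    ci_low = NULL, ci_high = NULL,
    flags = list(reliable = c(a0_alpha = TRUE, a1_alpha = TRUE,
                              tau_a_alpha = TRUE, tau_b_alpha = FALSE,
                              a0_beta = TRUE, a1_beta = TRUE,
                              tau_a_beta = TRUE, tau_b_beta = FALSE))),
    class = "org_fit")
  # equal estimates with relative sigma 0.1 each -> ratio 1, sigma sqrt(2)*0.1
  sig <- abs(fake$params) * 0.1
  fake$ci_low <- fake$params - 1.96 * sig
  fake$ci_high <- fake$params + 1.96 * sig
  rr <- response_ratios(fake)
  expect_equal(rr$ratio, rep(1, 4))
  expect_equal(rr$sigma, rep(sqrt(2) * 0.1, 4), tolerance = 1e-12)
  expect_equal(rr$reliable, c(TRUE, TRUE, TRUE, FALSE))
  # zero-width CIs -> zero sigma
  fake$ci_low <- fake$ci_high <- fake$params
  expect_equal(response_ratios(fake)$sigma, rep(0, 4))
  # near-zero alpha is an error
  fake$params["a0_alpha"] <- 1e-14
  expect_error(response_ratios(fake), "zero")
})

test_that("ratio trend line recovers slope and unity-crossing time", {
  t_isi <- c(0.015, 0.1, 0.2, 0.3)
  tr <- ratio_trend(t_isi, 2.3 * t_isi + 0.31)
  expect_equal(tr$slope, 2.3)
  expect_equal(tr$t_unity, 0.3, tolerance = 1e-12)
  # constant ratios: flat trend, unity time undefined
  flat <- ratio_trend(t_isi, rep(0.9, 4))
  expect_false(flat$t_unity_defined)
  expect_true(is.na(flat$t_unity))
  expect_error(ratio_trend(rep(0.1, 3), 1:3), "identical")
  # noisy line: mean slope within 2 SE of the generator
  set.seed(9)
  slopes <- replicate(300, {
    x <- c(0.015, 0.1, 0.2, 0.3)
    ratio_trend(x, 2.3 * x + 0.31 + rnorm(4, 0, 0.05))$slope
  })
  expect_lt(abs(mean(slopes) - 2.3), 2 * sd(slopes) / sqrt(300))
})

test_that("fit reports serialize and validate against the shipped schema", {
  p <- exemplar_params()
  tr <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 10, seed = 2))
  fit <- fit_single_flash(tr)
  report <- as_fit_report(fit)
  expect_true(validate_fit_report(report))
  expect_error(validate_fit_report(report[setdiff(names(report), "rms_nm")]),
               "rms_nm")
  # round trip through JSON keeps the required structure
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  expect_true(validate_fit_report(jsonlite::read_json(path)))
})
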