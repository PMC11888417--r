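test_that("single-flash model is gated at onset and equals a0 there", {
  p <- exemplar_params()
  expect_identical(eval_single_flash(p, -0.05), 0)
  expect_equal(eval_single_flash(p, 0), -36.4)
  # holds for arbitrary valid parameters
  for (q in draw_params(20, seed = 11)) {
    expect_identical(eval_single_flash(q, c(-1, -1e-9)), c(0, 0))
    expect_equal(eval_single_flash(q, 0), q$a0)
  }
  expect_error(eval_single_flash(p, NaN), "finite")
})

test_that("single-flash closed form matches a frozen hand evaluation", {
  # -36.4 + 200.8 * (-exp(-9.5) + exp(-0.07)) at t = 1 s
  expect_equal(eval_single_flash(exemplar_params(), 1.0), 150.8096,
               tolerance = 1e-6)
})

test_that("parameterization degeneracy (a1, tau_a, tau_b) == (-a1, tau_b, tau_a)", {
  t <- seq(-0.2, 3, by = 0.01)
  for (q in draw_params(10, seed = 5)) {
    q_alt <- response_params(q$a0, -q$a1, q$tau_b, q$tau_a)
    expect_equal(eval_single_flash(q, t), eval_single_flash(q_alt, t))
  }
})

test_that("canonicalize_params enforces tau_a >= tau_b without changing the curve", {
  q <- response_params(-20, -100, 0.05, 8)
  qc <- canonicalize_params(q)
  expect_gte(qc$tau_a, qc$tau_b)
  expect_equal(qc$a1, 100)
  t <- seq(0, 2, by = 0.01)
  expect_equal(eval_single_flash(qc, t), eval_single_flash(q, t))
})

test_that("elongation rate matches finite differences and vanishes at the peak", {
  p <- exemplar_params()
  expect_identical(eval_rate(response_params(-10, 0, 9.5, 0.07), 0.1), 0)
  expect_error(eval_rate(p, 0), "t > 0")
  tm <- derived_metrics(p)$t_max
  expect_equal(eval_rate(p, tm), 0, tolerance = 1e-9)
  # central finite differences of the model, step 1e-6 s
  h <- 1e-6
  for (t in c(0.01, 0.05, 0.3, 1, 3)) {
    fd <- (eval_single_flash(p, t + h) - eval_single_flash(p, t - h)) / (2 * h)
    expect_equal(eval_rate(p, t), fd, tolerance = 1e-4)
  }
})

test_that("derived metrics: closed-form t_max, symmetry, degenerate limit", {
  p <- exemplar_params()
  dm <- derived_metrics(p)
  expect_equal(dm$t_max, 0.5207372, tolerance = 1e-6)
  expect_equal(dm$t_max, grid_tmax_oracle(p), tolerance = 1.0001e-5)
  expect_equal(dm$dopl_max, eval_single_flash(p, dm$t_max), tolerance = 1e-9)
  expect_false(dm$degenerate)
  # symmetric under rate exchange
  d1 <- derived_metrics(response_params(-10, 100, 4, 0.2))
  d2 <- derived_metrics(response_params(-10, 100, 0.2, 4))
  expect_equal(d1$t_max, d2$t_max)
  # analytic limit of the 0/0 form at tau_a == tau_b
  dd <- derived_metrics(response_params(-10, 100, 1, 1))
  expect_true(dd$degenerate)
  expect_equal(dd$t_max, 1.0)
  expect_equal(dd$dopl_max, eval_single_flash(response_params(-10, 100, 1, 1),
                                              dd$t_max), tolerance = 1e-9)
})

test_that("two-flash model reduces to superposition of single flashes", {
  p <- exemplar_params()
  zero <- response_params(0, 0, 9.5, 0.07)
  t <- seq(-0.2, 3, by = 0.01)
  # null second flash
  tf <- two_flash_params(p, zero, 0.3)
  expect_equal(eval_two_flash(tf, t), eval_single_flash(p, t))
  # before onset
  expect_identical(eval_two_flash(tf, c(-0.5, -0.01)), c(0, 0))
  # coincident identical flashes double the response
  tf0 <- two_flash_params(p, p, 0)
  expect_equal(eval_two_flash(tf0, t), 2 * eval_single_flash(p, t))
  expect_equal(eval_two_flash(tf0, 0), 2 * p$a0)
  expect_error(two_flash_params(p, p, -0.1), ">= 0")
})

test_that("background model adds an ungated ramp to the flash response", {
  p <- exemplar_params()
  t <- seq(-0.2, 3, by = 0.01)
  expect_equal(eval_background(background_params(p, 0), t),
               eval_single_flash(p, t))
  zero <- response_params(0, 0, 1, 1)
  expect_equal(eval_background(background_params(zero, 10), 0.5), 5)
  # ramp runs before onset while the flash is gated off
  expect_equal(eval_background(background_params(p, 10), -0.1), -1)
})

test_that("alternative models satisfy their defining identities", {
  t <- seq(0, 3, by = 0.01)
  green <- alt_model_spec("green", a1 = 150, tau_a = 9.5, tau_b = 0.07,
                          t0 = 0.04)
  expect_equal(eval_alternative(green, 0.04), 0)
  red <- alt_model_spec("red", a1 = 180, tau_a = 6)
  expect_equal(eval_alternative(red, 1e4), 180, tolerance = 1e-8)
  # cyan with a1 = 0 collapses to red with amplitude a0
  cyan <- alt_model_spec("cyan", a0 = 180, a1 = 0, tau_a = 6, tau_b = 0.1)
  expect_equal(eval_alternative(cyan, t), eval_alternative(red, t))
  # magenta is the primary model
  mag <- alt_model_spec("magenta", a0 = -36.4, a1 = 200.8, tau_a = 9.5,
                        tau_b = 0.07)
  expect_equal(eval_alternative(mag, t), eval_single_flash(exemplar_params(), t))
  # blue is the offset-free two-exponential
  blue <- alt_model_spec("blue", a1 = 200.8, tau_a = 9.5, tau_b = 0.07)
  expect_equal(eval_alternative(blue, t),
               eval_single_flash(exemplar_params(), t) + 36.4)
  expect_error(alt_model_spec("yellow", a1 = 1, tau_a = 1), "arg")
  expect_error(alt_model_spec("green", a1 = 1, tau_a = 1, tau_b = 1, t0 = -1),
               "t0")
})

test_that("en-face intensity is a bounded cosine of the elongation phase", {
  p <- exemplar_params()
  # a1 = 0: constant c1 + c2 cos(phi0)
  flat <- response_params(-10, 0, 9.5, 0.07)
  ef <- enface_params(c1 = 5, c2 = 2, n = 1, lambda_nm = 850, phi0 = 0.3)
  t <- seq(0, 3, by = 0.01)
  expect_equal(eval_enface_intensity(ef, flat, t),
               rep(5 + 2 * cos(0.3), length(t)))
  # bounded in [c1 - c2, c1 + c2]
  I <- eval_enface_intensity(enface_params(1, 0.5, 1.38, 850, 0.1), p, t)
  expect_true(all(I >= 1 - 0.5 - 1e-12 & I <= 1 + 0.5 + 1e-12))
  # elongation term equal to lambda/4 makes the argument pi -> c1 - c2
  tm <- derived_metrics(p)$t_max
  g <- -exp(-9.5 * tm) + exp(-0.07 * tm)
  scaled <- response_params(p$a0, 212.5 / g, 9.5, 0.07)
  ef0 <- enface_params(c1 = 3, c2 = 1, n = 1, lambda_nm = 850, phi0 = 0)
  expect_equal(eval_enface_intensity(ef0, scaled, tm), 3 - 1, tolerance = 1e-9)
  expect_error(enface_params(1, 1, lambda_nm = -850), "lambda")
})
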