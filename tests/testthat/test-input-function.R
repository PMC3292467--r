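test_that("evaluate_input matches the closed form", {
  m <- input_function_model(1, 0)
  expect_equal(evaluate_input(m, 100), 1)
  m2 <- input_function_model(2, 0.5)
  expect_equal(evaluate_input(m2, 2), 2 * exp(-1))
  m3 <- input_function_model(c(1, 2), c(0.1, 1), delay_t0 = 5)
  expect_equal(evaluate_input(m3, c(0, 4.99)), c(0, 0))
  tt <- c(5, 6, 20)
  expect_equal(evaluate_input(m3, tt),
               exp(-0.1 * (tt - 5)) + 2 * exp(-1 * (tt - 5)))
})

test_that("input model construction is validated", {
  expect_error(input_function_model(c(1, 1, 1, 1), rep(0.1, 4)),
               class = "petkin_invalid_input")
  expect_error(input_function_model(-1, 0.1), class = "petkin_invalid_input")
  expect_error(input_function_model(1, -0.1), class = "petkin_invalid_input")
  expect_error(input_function_model(1, c(0.1, 0.2)),
               class = "petkin_invalid_input")
})

test_that("generate_input_curve returns analytic frame means when noiseless", {
  s <- default_schedule()
  const <- generate_input_curve(input_function_model(1, 0), s, noise_level = 0)
  expect_equal(const$values, rep(1, 28))

  lam <- 0.1
  curve <- generate_input_curve(input_function_model(1, lam), s,
                                noise_level = 0)
  a <- s$frame_start_s / 60
  b <- (s$frame_start_s + s$frame_duration_s) / 60
  analytic <- (exp(-lam * a) - exp(-lam * b)) / (lam * (b - a))
  expect_equal(curve$values, analytic, tolerance = 1e-12)
})

test_that("generate_input_curve is seed-deterministic and nonnegative", {
  s <- default_schedule()
  m <- default_input_spec()
  c1 <- generate_input_curve(m, s, noise_level = 0.3, seed = 7)
  c2 <- generate_input_curve(m, s, noise_level = 0.3, seed = 7)
  c3 <- generate_input_curve(m, s, noise_level = 0.3, seed = 8)
  expect_identical(c1$values, c2$values)
  expect_false(identical(c1$values, c3$values))
  expect_true(all(c1$values >= 0))
})

test_that("frame-noise variance scales inversely with frame duration", {
  # constant curve, value 1: var of a frame ~ (sigma)^2 * 30 / duration
  s <- frame_schedule(c(0, 30), c(30, 300))
  m <- input_function_model(1, 0)
  sims <- vapply(1:800, function(i)
    generate_input_curve(m, s, noise_level = 0.05, seed = i)$values,
    numeric(2))
  v <- apply(sims, 1, var)
  expect_equal(v[1], 0.05^2, tolerance = 0.15)
  expect_equal(v[1] / v[2], 10, tolerance = 0.25)
})

test_that("exponential fits round-trip noiseless curves and select the right order", {
  s <- default_schedule()
  f1 <- fit_input_exponentials(
    generate_input_curve(input_function_model(10, 0.3), s, noise_level = 0))
  expect_length(f1$amplitudes, 1L)
  expect_equal(f1$amplitudes, 10, tolerance = 1e-3)
  expect_equal(f1$rates, 0.3, tolerance = 1e-3)

  f2 <- fit_input_exponentials(
    generate_input_curve(input_function_model(c(10, 1), c(3, 0.05)), s,
                         noise_level = 0))
  expect_length(f2$amplitudes, 2L)
  expect_equal(f2$amplitudes, c(10, 1), tolerance = 0.01)
  expect_equal(f2$rates, c(3, 0.05), tolerance = 0.01)

  f3 <- fit_input_exponentials(
    generate_input_curve(default_input_spec(scale = 2.4), s, noise_level = 0))
  expect_length(f3$amplitudes, 3L)
  expect_equal(f3$rates, c(6, 0.4, 0.02), tolerance = 0.01)
})

test_that("a constant blood curve is fitted as one term with zero rate", {
  s <- default_schedule()
  fc <- fit_input_exponentials(
    generate_input_curve(input_function_model(5, 0), s, noise_level = 0))
  expect_length(fc$amplitudes, 1L)
  expect_equal(fc$amplitudes, 5, tolerance = 1e-6)
  expect_equal(fc$rates, 0)
})

test_that("fit invariants: term count bounded, rates nonnegative, AICc table", {
  s <- default_schedule()
  x <- generate_input_curve(default_input_spec(scale = 2.4), s,
                            noise_level = 0.05, seed = 3)
  for (mt in 1:3) {
    f <- fit_input_exponentials(x, max_terms = mt)
    expect_lte(length(f$amplitudes), mt)
    expect_true(all(f$rates >= 0))
    expect_equal(nrow(f$aicc_table), mt)
  }
})

test_that("pre-peak frames are interpolated by the fitted model object", {
  s <- default_schedule()
  # rising then decaying curve: peak in frame 5
  vals <- c(1, 4, 8, 12, 15, 14 * exp(-0.3 * (0:22)))[1:28]
  f <- fit_input_exponentials(tac(s, vals))
  expect_gt(f$fit_start_min, 0)
  expect_equal(nrow(f$prepeak), 4L)
  # before the window: interpolates the measured values, not the exponentials
  expect_equal(evaluate_input(f, f$prepeak$t_min[2]), 4, tolerance = 1e-6)
})

test_that("too few post-peak frames raises a typed error", {
  s <- frame_schedule(c(0, 30, 60), rep(30, 3))
  expect_error(fit_input_exponentials(tac(s, c(1, 5, 3))),
               class = "petkin_if_too_few_frames")
})
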