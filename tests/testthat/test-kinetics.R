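pB <- kinetic_params(0.3506, 0.5216, 0.1177, 0.1005, 0.0903)  # group-B medians
pR <- kinetic_params(0.2728, 0.5721, 0.1180, 0.0442, 0.0574)  # group-R medians

test_that("impulse response reduces correctly in limiting cases", {
  tt <- c(0, 0.5, 2, 10, 60)
  p0 <- suppressWarnings(kinetic_params(0.4, 0, 0, 0, 0.05))
  expect_equal(impulse_response(p0, tt), rep(0.4, 5))
  p1 <- kinetic_params(0.4, 0.3, 0, 0, 0.05)
  expect_equal(impulse_response(p1, tt), 0.4 * exp(-0.3 * tt))
  expect_equal(impulse_response(pB, 0), pB$K1)
  expect_error(impulse_response(pB, -1), class = "petkin_invalid_input")
})

test_that("analytic impulse response matches the ODE oracle to 1e-6", {
  sets <- random_params(20, seed = 11, include_degenerate = TRUE)
  tt <- c(1, 5, 30, 60)
  oracle <- ode_irf(sets, tt, h = 0.002)
  for (i in seq_along(sets)) {
    h_an <- impulse_response(as_kp(sets[[i]]), tt)
    expect_lt(max(abs(h_an - oracle[i, ]) /
                    pmax(abs(oracle[i, ]), 1e-12)), 1e-6)
  }
})

test_that("impulse response is continuous across the confluent limit", {
  # k3 -> 0 with k2 = k4 drives alpha1 -> alpha2
  base <- list(K1 = 0.3, k2 = 0.25, k4 = 0.25, VB = 0.08)
  tt <- c(0.5, 5, 30)
  h_exact0 <- impulse_response(as_kp(c(base, k3 = 0)), tt)
  for (k3 in c(1e-12, 1e-9, 1e-7)) {
    h_near <- impulse_response(as_kp(c(base, k3 = k3)), tt)
    expect_equal(h_near, h_exact0, tolerance = 1e-5)
  }
})

test_that("influx follows the printed formula and its bounds", {
  # group-B mean rates; direct arithmetic gives 0.0760, close to the
  # published group-mean binding potential 0.0765
  expect_equal(influx(0.3717, 0.4808, 0.1235),
               0.3717 * 0.1235 / (0.4808 + 0.1235))
  expect_equal(round(influx(0.3717, 0.4808, 0.1235), 4), 0.076)
  expect_equal(influx(0.5, 0.3, 0), 0)
  expect_equal(influx(0.5, 0, 0.2), 0.5)  # no washout: everything trapped
  expect_error(influx(0.5, 0, 0), class = "petkin_invalid_input")
})

test_that("influx is monotone and bounded by K1 over random draws", {
  sets <- random_params(50, seed = 5)
  for (p in sets) {
    ki <- influx(p$K1, p$k2, p$k3)
    expect_gte(ki, 0)
    expect_lte(ki, p$K1)
    eps <- 1e-3
    expect_gte(influx(p$K1 + eps, p$k2, p$k3), ki)
    expect_gte(influx(p$K1, p$k2, p$k3 + eps), ki)
    expect_lte(influx(p$K1, p$k2 + eps, p$k3), ki)
  }
})

test_that("macro parameters: RBP identity, k3/k4 alternative, homogeneity", {
  m <- macro_params(pB)
  expect_equal(m$rbp, 0.3506 * 0.1177 / (0.5216 + 0.1177))
  expect_equal(m$rbp, 0.06455, tolerance = 1e-4)
  expect_equal(m$bp_alt, 0.1177 / 0.1005)
  m0 <- macro_params(kinetic_params(0.3, 0.4, 0, 0.1, 0.05))
  expect_equal(m0$rbp, 0)
  expect_equal(m0$bp_alt, 0)
  p2 <- pB; p2$K1 <- 2 * pB$K1
  m2 <- macro_params(p2)
  expect_equal(m2$rbp, 2 * m$rbp)
  expect_equal(m2$bp_alt, m$bp_alt)
  mk40 <- macro_params(suppressWarnings(kinetic_params(0.3, 0.4, 0.1, 0, 0.05)))
  expect_true(is.na(mk40$bp_alt))
})

test_that("simulate_tac handles degenerate inputs exactly", {
  s <- default_schedule()
  zero <- simulate_tac(pB, input_function_model(0, 1), s)
  expect_equal(zero$values, rep(0, 28))
  pure_blood <- simulate_tac(
    suppressWarnings(kinetic_params(0, 0.1, 0.1, 0.1, 0.5)),
    input_function_model(2, 0), s)
  expect_equal(pure_blood$values, rep(1, 28))
})

test_that("simulate_tac matches the ODE + quadrature oracle within 0.1%", {
  s <- default_schedule()
  m <- default_input_spec(scale = 2.4)
  sets <- random_params(8, seed = 21, include_degenerate = TRUE)
  oracle <- ode_tac_frame_means(sets, m, s, h = 1e-3)
  for (i in seq_along(sets)) {
    sim <- simulate_tac(as_kp(sets[[i]]), m, s)
    expect_lt(max(abs(sim$values - oracle[i, ]) / pmax(oracle[i, ], 1e-12)),
              1e-3)
  }
})

test_that("simulate_tac is linear in the input amplitude", {
  s <- default_schedule()
  m1 <- default_input_spec(scale = 1)
  m3 <- default_input_spec(scale = 3)
  expect_equal(simulate_tac(pB, m3, s)$values,
               3 * simulate_tac(pB, m1, s)$values, tolerance = 1e-12)
})

test_that("fit_2tcm round-trips noiseless median-parameter curves within 1%", {
  s <- default_schedule()
  cases <- list(list(p = pB, scale = 2.394891), list(p = pR, scale = 1.454849))
  for (cs in cases) {
    m <- default_input_spec(scale = cs$scale)
    fit <- fit_2tcm(simulate_tac(cs$p, m, s), m)
    for (nm in c("K1", "k2", "k3", "k4", "VB"))
      expect_lt(abs(fit$params[[nm]] - cs$p[[nm]]) / cs$p[[nm]], 0.01)
    expect_true(fit$accepted)
    expect_gte(fit$n_starts_converged, 1L)
    expect_lt(fit$wrss, 1e-6)
  }
})

test_that("a pure-blood TAC fits with K1 near zero", {
  s <- default_schedule()
  m <- default_input_spec(scale = 2)
  cp_means <- generate_input_curve(m, s, noise_level = 0)$values
  y <- tac(s, 0.3 * cp_means)  # exactly VB * Cp with VB = 0.3
  fit <- fit_2tcm(y, m)
  expect_lt(fit$params$K1, 1e-3)
  expect_equal(fit$params$VB, 0.3, tolerance = 0.01)
  expect_true(fit$accepted)
})

test_that("fit_2tcm rejects degenerate inputs", {
  s <- default_schedule()
  m <- default_input_spec()
  expect_error(fit_2tcm(tac(s, rep(0, 28)), m), class = "petkin_degenerate_tac")
  s10 <- frame_schedule(seq(0, 240, by = 30), rep(30, 9))
  expect_error(fit_2tcm(tac(s10, rep(1, 9)), m), class = "petkin_invalid_input")
})

test_that("kinetic parameter validation and acceptance rule", {
  expect_error(kinetic_params(NA, 0.1, 0.1, 0.1, 0.1),
               class = "petkin_invalid_input")
  expect_error(kinetic_params(0.1, -0.2, 0.1, 0.1, 0.1),
               class = "petkin_invalid_input")
  expect_warning(kinetic_params(1.2, 0.1, 0.1, 0.1, 0.1))
  expect_true(params_accepted(pB))
  expect_false(params_accepted(list(K1 = 1.2, k2 = .1, k3 = .1, k4 = .1,
                                    VB = .1)))
  expect_false(params_accepted(list(K1 = .2, k2 = .1, k3 = .1, k4 = .1,
                                    VB = 0)))
})
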