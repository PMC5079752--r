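test_that("pulse-chase weighting normalizes constriction depth", {
  rel <- as_relative_trace(0:3, c(1, 0.8, 0.6, 0.8))
  om <- omega_from_pulse_chase(rel, max_lag = 3)
  expect_equal(om$weights, c(0, 0.5, 1, 0.5))
  expect_equal(om$peak_lag, 2L)

  expect_error(omega_from_pulse_chase(as_relative_trace(0:3, rep(1, 4)),
                                      max_lag = 3), "no constriction")
  # dilation beyond baseline clips to zero before normalizing
  om2 <- omega_from_pulse_chase(as_relative_trace(0:3, c(1.1, 0.9, 0.5, 1.2)),
                                max_lag = 3)
  expect_equal(om2$weights, c(0, 0.2, 1, 0))
})

test_that("temporal weighting validates its invariants", {
  expect_error(temporal_weighting(0:2, c(0, 0.5, 0.9)), "maximum is exactly 1")
  expect_error(temporal_weighting(c(0, 2, 3), c(0, 1, 0.5)), "consecutive")
  expect_error(temporal_weighting(0:2, c(-0.1, 1, 0.5)), ">= 0")
  om <- temporal_weighting(0:30, c(rep(0.5, 6), 1, rep(0.2, 24)))
  expect_equal(om$peak_lag, 6L)
})

test_that("the recursion reproduces a hand-worked example", {
  om <- temporal_weighting(0:2, c(0, 1, 0.5))
  drc <- function(lux) ifelse(lux >= 10, 0.4, 0.8)
  s <- simulate_feedback(drc, om, env_lux = 20, horizon = 3)
  expect_equal(s$retinal_lux_t, c(20, 8, 14))
  expect_equal(s$rpa_t, c(1, 0.4, 0.7))
})

test_that("inert and dark inputs leave the pupil open", {
  om <- temporal_weighting(0:5, c(0, 0.5, 1, 0.8, 0.5, 0.2))
  s_inert <- simulate_feedback(function(lux) rep(1, length(lux)), om,
                               env_lux = 100, horizon = 20)
  expect_equal(s_inert$rpa_t, rep(1, 20))
  expect_equal(s_inert$retinal_lux_t, rep(100, 20))

  I <- 10^seq(-3, 3, length.out = 7)
  drc <- fit_intensity_response(I, oracle_sigmoid(I, 1, 0.05, 1, -1))
  s_dark <- simulate_feedback(drc, om, env_lux = 0, horizon = 20)
  expect_equal(s_dark$rpa_t, rep(1, 20))
})

test_that("production recursion matches the brute-force nested-loop oracle", {
  lib <- default_genotype_library()
  om <- omega_from_pulse_chase(generate_pulse_chase(lib$wildtype, noise_sd = 0))
  I <- 10^seq(-3, 3, length.out = 7)
  drc <- fit_intensity_response(
    I, oracle_sigmoid(I, 1, 0.05, 0.53, -1))
  alpha <- function(lux) predict_rpa(drc, lux)
  for (env in default_sweep_intensities()) {
    prod <- simulate_feedback(drc, om, env, horizon = 60)
    orac <- oracle_feedback(alpha, om$weights, env, 60)
    expect_lt(max(abs(prod$rpa_t - orac$rpa)), 1e-12)
    expect_lt(max(abs(prod$retinal_lux_t - orac$lux)), 1e-9 * max(1, env))
  }
})

test_that("feedback only relaxes the pupil relative to open loop", {
  lib <- default_genotype_library()
  om <- omega_from_pulse_chase(generate_pulse_chase(lib$wildtype, noise_sd = 0))
  I <- 10^seq(-3, 3, length.out = 7)
  drc <- fit_intensity_response(I, oracle_sigmoid(I, 1, 0.05, 0.53, -1))
  for (env in c(0.01, 1, 100, 1e4)) {
    s <- simulate_feedback(drc, om, env, horizon = 120)
    expect_true(all(s$rpa_t >= s$openloop_plateau - 1e-12))
    expect_true(all(s$rpa_t <= 1 + 1e-12))
    expect_true(all(s$retinal_lux_t <= env + 1e-12))
  }
})

test_that("packets set the pupil by max, never by summation", {
  om <- temporal_weighting(0:10, c(0, 0.3, 0.7, 1, rep(0.6, 7)))
  I <- 10^seq(-2, 3, length.out = 6)
  drc <- fit_intensity_response(I, oracle_sigmoid(I, 1, 0.1, 5, -1))
  s <- simulate_feedback(drc, om, 50, horizon = 80)
  max_depth <- max(1 - predict_rpa(drc, s$retinal_lux_t))
  expect_true(all(1 - s$rpa_t <= max_depth + 1e-12))
  # the packet-matrix view agrees with the reported trace
  M <- feedback_packet_matrix(s, om)
  col_min <- apply(M, 2, min, na.rm = TRUE)
  expect_equal(col_min, s$rpa_t)
})

test_that("the simulation is deterministic", {
  lib <- default_genotype_library()
  om <- omega_from_pulse_chase(generate_pulse_chase(lib$wildtype, noise_sd = 0))
  I <- 10^seq(-3, 3, length.out = 7)
  drc <- fit_intensity_response(I, oracle_sigmoid(I, 1, 0.05, 0.53, -1))
  a <- simulate_feedback(drc, om, 10, horizon = 120)
  b <- simulate_feedback(drc, om, 10, horizon = 120)
  expect_identical(a$rpa_t, b$rpa_t)
  expect_identical(a$retinal_lux_t, b$retinal_lux_t)
})

test_that("intensity sweep saturates at both extremes and shifts EC50 up", {
  lib <- default_genotype_library()
  om <- omega_from_pulse_chase(generate_pulse_chase(lib$wildtype, noise_sd = 0))
  I <- 10^seq(-3, 3, length.out = 7)
  drc <- fit_intensity_response(I, oracle_sigmoid(I, 1, 0.05, 0.53, -1))
  sw <- feedback_intensity_sweep(drc, om, horizon = 200)
  expect_equal(nrow(sw$summary), 9)
  dm <- sw$summary$decay_magnitude
  interior_max <- max(dm[2:8])
  expect_lte(dm[1], interior_max)
  expect_lte(dm[9], interior_max)
  # feedback can only reduce apparent sensitivity over time
  expect_gte(ec50_lux(sw$ec50_end), ec50_lux(sw$ec50_early) - 1e-9)
})
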