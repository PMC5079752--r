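test_that("the default library encodes the printed anchors", {
  lib <- default_genotype_library()
  expect_equal(lib$wildtype$transient$ec50, 0.53)
  expect_equal(log(2) / lib$wildtype$transient$k, 1.1)
  expect_equal(lib$wildtype$sustained$ec50, 7.9)
  expect_equal(log(2) / lib$iprgc_glutamate_ko$transient$k, 4.8)
  expect_equal(log(2) / lib$iprgc_pacap_ko$transient$k, 1.1)
  # melanopsin KO: wild-type transient, no sustained constriction
  expect_equal(lib$melanopsin_ko$transient$ec50, 0.53)
  expect_null(lib$melanopsin_ko$sustained)
  expect_length(lib, 9)
})

test_that("noiseless traces follow the genotype model", {
  lib <- default_genotype_library()
  dark <- generate_trace(lib$wildtype, 0, duration = 30, dt = 1, noise_sd = 0)
  expect_true(all(relative_trace(dark)$rpa == 1))

  bright <- generate_trace(lib$wildtype, 1e7, duration = 30, dt = 0.5,
                           noise_sd = 0)
  endpoint <- transient_endpoint(relative_trace(bright))
  expect_lt(abs(endpoint - lib$wildtype$transient$bottom), 1e-6)

  # generator/fitter round trip on the transient segment
  tr <- generate_trace(lib$wildtype, 1000, duration = 30, dt = 0.1,
                       noise_sd = 0)
  fit <- fit_one_phase(relative_trace(tr))
  expect_equal(fit$k, lib$wildtype$transient$k, tolerance = 1e-6)
})

test_that("traces include a dark baseline and respect the rpa bounds", {
  lib <- default_genotype_library()
  tr <- generate_trace(lib$wildtype, 10, duration = 30, dt = 0.5, seed = 3)
  expect_gte(sum(tr$times < 0), 3)
  rpa <- tr$areas / lib$wildtype$baseline_area
  expect_true(all(rpa >= 0.02 - 1e-12))
  expect_true(all(rpa <= 1 + 4 * lib$wildtype$noise_sd + 1e-12))
})

test_that("identical seeds reproduce identical datasets", {
  lib <- default_genotype_library()
  a <- generate_trace(lib$wildtype, 10, duration = 30, dt = 0.5, seed = 42)
  b <- generate_trace(lib$wildtype, 10, duration = 30, dt = 0.5, seed = 42)
  expect_identical(a$areas, b$areas)
  c1 <- generate_cohort(lib$wildtype, 10^(0:3), n_per_genotype = 2,
                        base_seed = 99)
  c2 <- generate_cohort(lib$wildtype, 10^(0:3), n_per_genotype = 2,
                        base_seed = 99)
  expect_identical(c1, c2)
  c3 <- generate_cohort(lib$wildtype, 10^(0:3), n_per_genotype = 2,
                        base_seed = 100)
  expect_false(identical(c1$transient_rpa, c3$transient_rpa))
})

test_that("a noiseless cohort returns exact model endpoints", {
  lib <- default_genotype_library()
  wt <- lib$wildtype
  co <- generate_cohort(wt, intensities = 100, n_per_genotype = 1,
                        base_seed = 1, noise_sd = 0)
  expect_equal(nrow(co), 1)
  rel <- relative_trace(generate_trace(wt, 100, duration = 30, dt = 0.5,
                                       noise_sd = 0))
  expect_equal(co$transient_rpa, transient_endpoint(rel), tolerance = 1e-9)
  expect_equal(co$sustained_rpa, model_trace(wt, 100, c(0, 3600))$rpa[2],
               tolerance = 1e-9)
})

test_that("pulse-chase profiles peak at 6 s and normalize exactly", {
  lib <- default_genotype_library()
  pc <- generate_pulse_chase(lib$wildtype, noise_sd = 0)
  om <- omega_from_pulse_chase(pc)
  expect_equal(om$peak_lag, 6L)
  expect_equal(max(om$weights), 1)
  expect_lt(om$weights[1], 1e-12)  # constriction lags light
  expect_length(pc$times, 31)
})

test_that("cohorts recover the generating EC50s through the full pipeline", {
  lib <- default_genotype_library()
  wt <- lib$wildtype
  intens <- 10^seq(-2, 5)
  set.seed(21)
  res <- vapply(1:10, function(r) {
    co <- generate_cohort(wt, intens, n_per_genotype = 6,
                          base_seed = 3000 + r)
    per_mouse <- split(co, co$mouse_id)
    tfit <- vapply(per_mouse, function(d)
      fit_intensity_response(d$intensity_lux, d$transient_rpa)$log_ec50,
      numeric(1))
    sfit <- vapply(per_mouse, function(d)
      fit_intensity_response(d$intensity_lux, d$sustained_rpa)$log_ec50,
      numeric(1))
    c(t = 10^mean(tfit), s = 10^mean(sfit))
  }, numeric(2))
  geo_t <- exp(mean(log(res["t", ])))
  geo_s <- exp(mean(log(res["s", ])))
  expect_lt(abs(log10(geo_t / wt$transient$ec50)), log10(1.2))
  expect_lt(abs(log10(geo_s / wt$sustained$ec50)), log10(1.2))
  # the transient-to-sustained sensitivity shift is reproduced
  expect_true(all(res["s", ] > res["t", ]))
})
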