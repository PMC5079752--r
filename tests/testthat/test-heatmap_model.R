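# Sigmoid fits with known plateaus, built from exact curve data.
fit_known <- function(bottom, ec50 = 1, hill = -1) {
  I <- 10^seq(-3, 3, length.out = 7)
  fit_intensity_response(I, oracle_sigmoid(I, 1, bottom, ec50, hill),
                         constrain_bottom = FALSE)
}

test_that("transient matrices start open and relax to the plateau", {
  curve <- fit_known(0.2)
  m <- build_transient_matrix(curve, k_rapid = 0.6301)
  expect_equal(unname(m$values[1, ]), rep(1, length(m$log10_lux)))
  # asymptote at long time
  m_long <- build_transient_matrix(curve, 0.6301, time_s = c(0, 1000))
  expect_equal(unname(m_long$values[2, ]),
               predict_rpa(curve, 10^m_long$log10_lux), tolerance = 1e-6)
  # half-life midpoint: plateau 0.2 at saturating light, t = 1.1 s
  m_sat <- build_transient_matrix(curve, 0.6301, time_s = c(0, 1.1),
                                  log10_lux = c(5, 6))
  expect_equal(m_sat$values[2, 2], 0.6, tolerance = 1e-4)
  expect_error(build_transient_matrix(curve, -1), "> 0")
})

test_that("sustained matrices start from the transient plateau at 30 s", {
  trans <- fit_known(0.2)
  sust <- fit_known(0.9)
  flat_rate <- fit_decay_rate_vs_intensity(rep(log(2) / 4, 3))
  m <- build_sustained_matrix(trans, sust, flat_rate)
  expect_equal(unname(m$values[1, ]), predict_rpa(trans, 10^m$log10_lux))
  # no decay when the plateaus coincide
  same <- build_sustained_matrix(trans, trans, flat_rate)
  expect_true(all(abs(sweep(same$values, 2, same$values[1, ])) < 1e-12))
  # half-life midpoint: 0.2 -> 0.9 with half-life 4 min, at 30 s + 4 min
  m2 <- build_sustained_matrix(trans, sust, flat_rate,
                               time_s = c(30, 30 + 240), log10_lux = c(5, 6))
  expect_equal(m2$values[2, 2], 0.55, tolerance = 1e-4)
  # boundary consistency with the transient matrix
  k_rapid <- 0.6301
  tm <- build_transient_matrix(trans, k_rapid)
  expect_true(all(abs(m$values[1, ] - tm$values[31, ]) <=
                    exp(-30 * k_rapid) + 1e-12))
})

test_that("matrix averaging is cellwise and grid-checked", {
  mk <- function(v) pupil_matrix(matrix(v, 2, 2), c(0, 1), c(0, 1), "g")
  a <- mk(c(1, 0.4, 0.5, 0.2)); b <- mk(c(0.8, 0.2, 0.3, 0.2))
  avg <- average_matrices(list(a, b))
  expect_equal(avg$values, matrix(c(0.9, 0.3, 0.4, 0.2), 2, 2))
  expect_equal(average_matrices(list(a, a))$values, a$values)
  expect_equal(average_matrices(list(b, a))$values, avg$values)
  c_bad <- pupil_matrix(matrix(0.5, 2, 2), c(0, 2), c(0, 1), "g")
  expect_error(average_matrices(list(a, c_bad)), "grids")
})

test_that("necessity, sufficiency and contribution follow their algebra", {
  grids <- list(t = c(0, 1, 2), l = c(0, 1))
  mk <- function(v, g = "x") pupil_matrix(matrix(v, 3, 2), grids$t, grids$l, g)
  wt <- mk(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7), "wildtype")

  expect_true(all(necessity_map(wt, wt)$values == 0))
  full <- necessity_map(wt, mk(rep(1, 6), "ko"))
  expect_equal(full$values, 1 - wt$values)
  expect_equal(necessity_map(mk(rep(0.2, 6)), mk(rep(0.7, 6)))$values[1, 1], 0.5)

  expect_true(all(sufficiency_map(mk(rep(1, 6)))$values == 0))
  expect_equal(sufficiency_map(wt)$values, 1 - wt$values)
  expect_equal(sufficiency_map(mk(rep(0.35, 6)))$values[2, 2], 0.65)

  n <- necessity_map(wt, mk(c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9), "ko"))
  s <- sufficiency_map(mk(c(0.9, 0.4, 0.6, 0.3, 0.8, 0.2), "ko"))
  cm <- contribution_map(n, s)
  expect_equal(cm$values, pmax(n$values, s$values))

  # random maps: contribution dominates both inputs cellwise
  set.seed(5)
  for (i in 1:10) {
    ko <- mk(runif(6, 0.1, 1), "ko")
    only <- mk(runif(6, 0.1, 1), "ko")
    cm <- contribution_map(necessity_map(wt, ko), sufficiency_map(only))
    expect_true(all(cm$values >= necessity_map(wt, ko)$values - 1e-12))
    expect_true(all(cm$values >= sufficiency_map(only)$values - 1e-12))
    expect_true(all(cm$values >= 0 & cm$values <= 1))
  }

  # neurotransmitter panel: contribution from necessity alone
  nt <- contribution_map(n)
  expect_true(nt$necessity_only)
  expect_equal(nt$values, n$values)
})

test_that("a worse knockout never lowers its necessity map", {
  grids <- list(t = 0:3, l = c(0, 1, 2))
  wt <- pupil_matrix(matrix(runif(12, 0.1, 0.6), 4, 3), grids$t, grids$l)
  set.seed(9)
  ko1 <- matrix(runif(12, 0.3, 0.9), 4, 3)
  bump <- matrix(runif(12, 0, 0.1), 4, 3)
  ko2 <- pmin(ko1 + bump, 1)
  n1 <- necessity_map(wt, pupil_matrix(ko1, grids$t, grids$l, "ko"))
  n2 <- necessity_map(wt, pupil_matrix(ko2, grids$t, grids$l, "ko"))
  expect_true(all(n2$values >= n1$values - 1e-12))
})

test_that("cone decay adjustment relaxes depth after the minimum", {
  lib <- default_genotype_library()
  tt <- seq(0, 30, 1)
  li <- c(1, 2, 3)
  vals <- vapply(li, function(l) model_trace(lib$cone_only, 10^l, tt)$rpa,
                 numeric(length(tt)))
  m <- pupil_matrix(vals, tt, li, "cone_only")

  expect_equal(apply_cone_decay_adjustment(m, 0)$values, m$values)

  rate <- 0.2
  adj <- apply_cone_decay_adjustment(m, rate)
  for (j in seq_along(li)) {
    i_min <- which.min(m$values[, j])
    expect_lt(i_min, length(tt))  # interior minimum: adjustment is active
    expect_true(all(adj$values[, j] >= min(m$values[, j]) - 1e-12))
    expect_true(all(adj$values[, j] >= m$values[, j] - 1e-12))
    # one half-life past the minimum, depth is half the unadjusted depth
    t_half <- m$time_s[i_min] + log(2) / rate
    i_half <- which.min(abs(m$time_s - t_half))
    if (abs(m$time_s[i_half] - t_half) < 1e-9) {
      expect_equal(1 - adj$values[i_half, j],
                   (1 - m$values[i_half, j]) / 2, tolerance = 1e-9)
    }
  }
})

test_that("RGB composition rounds channels and rejects collisions", {
  grids <- list(t = 0:1, l = c(0, 1))
  mk_map <- function(v) {
    rpa <- pmax(1 - v, 1e-9)  # rpa must stay positive; map still rounds to v
    sufficiency_map(pupil_matrix(matrix(rpa, 2, 2), grids$t, grids$l, "c"),
                    component = "c")
  }
  black <- compose_rgb(list(mk_map(0), mk_map(0), mk_map(0)))
  expect_true(all(black == 0L))
  red <- compose_rgb(list(mk_map(1)), channels = "red")
  expect_true(all(red[, , 1] == 255L) && all(red[, , 2:3] == 0L))
  purple <- compose_rgb(list(mk_map(0.5), mk_map(0.5)),
                        channels = c("red", "blue"))
  expect_true(all(purple[, , 1] == 128L) && all(purple[, , 2] == 0L) &&
                all(purple[, , 3] == 128L))
  expect_error(compose_rgb(list(mk_map(1), mk_map(1)),
                           channels = c("red", "red")), "duplicate")
  # PNG round trip
  path <- tempfile(fileext = ".png")
  write_heatmap_png(purple, path)
  back <- png::readPNG(path)
  expect_equal(dim(back), c(2, 2, 3))
  expect_equal(unique(as.vector(round(back * 255))), c(128, 0))
})
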