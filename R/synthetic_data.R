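# Synthetic pupillometry: genotype-parameterized trace generator with the
# statistical structure the analyses assume, so every stage of the pipeline
# is testable without animal data. The generated shape is (a) one-phase
# association from a fully open pupil to an intensity-dependent transient
# plateau, (b) from 30 s on, one-phase decay toward an intensity-dependent
# sustained plateau at an intensity-dependent rate, (c) additive Gaussian
# measurement noise on relative pupil area.

#' Construct a genotype specification for the synthetic generator
#'
#' @param name Genotype label.
#' @param transient List with `ec50` (lux), `hill`, `bottom` (plateau rpa
#'   at saturating light), `k` (constriction rate, 1/s), `onset_delay` (s).
#' @param sustained List with `ec50` (lux), `hill`, `bottom`,
#'   `rate_at_1lux` and `rate_at_100lux` (decay rates, 1/min),
#'   `log_midpoint`, `slope`; or NULL for genotypes with no sustained
#'   constriction (the sustained plateau is 1 at every intensity).
#' @param noise_sd Gaussian noise SD on relative pupil area.
#' @param baseline_area Dark pupil area (pixels) used to emit raw areas.
#' @param redilation_rate Within-transient re-dilation rate (1/s) for
#'   genotypes whose constriction decays inside the 30-s window (cone-only);
#'   0 disables it.
#' @param pulsatile List with `amplitude` and `period` (s) for sinusoidal
#'   modulation of sustained constriction depth (glutamate-knockout
#'   dynamics); NULL disables it.
#' @param sustained_decay_rate Decay rate (1/min) toward a fully open pupil
#'   for `sustained = NULL` genotypes (melanopsin knockout loses
#'   constriction with a ~4-min half-life).
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, transient, sustained = NULL,
                          noise_sd = 0.03, baseline_area = 1000,
                          redilation_rate = 0, pulsatile = NULL,
                          sustained_decay_rate = log(2) / 4) {
  stopifnot(transient$ec50 > 0, transient$k > 0, transient$onset_delay >= 0,
            transient$bottom >= 0, transient$bottom <= 1, noise_sd >= 0,
            baseline_area > 0, redilation_rate >= 0)
  if (!is.null(sustained))
    stopifnot(sustained$ec50 > 0, sustained$rate_at_1lux > 0,
              sustained$rate_at_100lux > 0,
              sustained$bottom >= 0, sustained$bottom <= 1)
  structure(list(name = name, transient = transient, sustained = sustained,
                 noise_sd = noise_sd, baseline_area = baseline_area,
                 redilation_rate = redilation_rate, pulsatile = pulsatile,
                 sustained_decay_rate = sustained_decay_rate),
            class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat(sprintf("Genotype spec: %s\n", x$name))
  cat(sprintf("  transient: EC50 %g lux, k %.4g /s (half-life %.3g s), bottom %g\n",
              x$transient$ec50, x$transient$k, log(2) / x$transient$k,
              x$transient$bottom))
  if (is.null(x$sustained)) {
    cat("  sustained: none (plateau 1 at all intensities)\n")
  } else {
    cat(sprintf("  sustained: EC50 %g lux, decay %.3g-%.3g /min, bottom %g\n",
                x$sustained$ec50, x$sustained$rate_at_1lux,
                x$sustained$rate_at_100lux, x$sustained$bottom))
  }
  invisible(x)
}

#' Default genotype library
#'
#' Nine genotype specifications spanning the photoreceptor and
#' neurotransmitter panels. Wild-type anchors: transient EC50 0.53 lux
#' with a 1.1-s constriction half-life; sustained EC50 7.9 lux with decay
#' half-lives of 2 min at 1 lux and 5 min at 100 lux. The
#' ipRGC-glutamate knockout's transient half-life is 4.8 s and its
#' sustained dynamics pulsatile; the ipRGC-PACAP knockout has a wild-type
#' transient (1.1 s) but an attenuated sustained response. Genotypes
#' without printed parameters are encoded qualitatively: cone knockout is
#' wild-type-like; melanopsin knockout has no sustained constriction
#' (lost with a ~4-min half-life); the cone-only line re-dilates within
#' 30 s; the melanopsin-only line constricts slowly with a 3-s onset
#' delay.
#'
#' @return A named list of [genotype_spec()] objects.
#' @export
default_genotype_library <- function() {
  wt_sus <- list(ec50 = 7.9, hill = -1, bottom = 0.05,
                 rate_at_1lux = log(2) / 2, rate_at_100lux = log(2) / 5,
                 log_midpoint = 1, slope = 1)
  specs <- list(
    wildtype = genotype_spec(
      "wildtype",
      transient = list(ec50 = 0.53, hill = -1, bottom = 0.05,
                       k = log(2) / 1.1, onset_delay = 0),
      sustained = wt_sus),
    rod_ko = genotype_spec(
      "rod_ko",
      transient = list(ec50 = 53, hill = -1, bottom = 0.05,
                       k = log(2) / 1.1, onset_delay = 0),
      sustained = modifyList(wt_sus, list(ec50 = 250))),
    cone_ko = genotype_spec(
      "cone_ko",
      transient = list(ec50 = 0.53, hill = -1, bottom = 0.05,
                       k = log(2) / 1.1, onset_delay = 0),
      sustained = wt_sus),
    melanopsin_ko = genotype_spec(
      "melanopsin_ko",
      transient = list(ec50 = 0.53, hill = -1, bottom = 0.05,
                       k = log(2) / 1.1, onset_delay = 0),
      sustained = NULL, sustained_decay_rate = log(2) / 4),
    rod_only = genotype_spec(
      "rod_only",
      transient = list(ec50 = 2, hill = -1, bottom = 0.25,
                       k = log(2) / 1.5, onset_delay = 0),
      sustained = modifyList(wt_sus, list(ec50 = 50, bottom = 0.4))),
    cone_only = genotype_spec(
      "cone_only",
      transient = list(ec50 = 100, hill = -1, bottom = 0.30,
                       k = log(2) / 1.0, onset_delay = 0),
      sustained = NULL, redilation_rate = 0.08,
      sustained_decay_rate = log(2) / 0.5),
    melanopsin_only = genotype_spec(
      "melanopsin_only",
      transient = list(ec50 = 800, hill = -1, bottom = 0.30,
                       k = log(2) / 5, onset_delay = 3),
      sustained = modifyList(wt_sus, list(ec50 = 300, bottom = 0.2))),
    iprgc_glutamate_ko = genotype_spec(
      "iprgc_glutamate_ko",
      transient = list(ec50 = 30, hill = -1, bottom = 0.15,
                       k = log(2) / 4.8, onset_delay = 0),
      sustained = modifyList(wt_sus, list(ec50 = 15, bottom = 0.15)),
      pulsatile = list(amplitude = 0.15, period = 300)),
    iprgc_pacap_ko = genotype_spec(
      "iprgc_pacap_ko",
      transient = list(ec50 = 0.53, hill = -1, bottom = 0.05,
                       k = log(2) / 1.1, onset_delay = 0),
      sustained = modifyList(wt_sus,
                             list(ec50 = 500, bottom = 0.3,
                                  rate_at_1lux = log(2) / 5,
                                  rate_at_100lux = log(2) / 5))))
  specs
}

# Noiseless model rpa for one genotype at one intensity, vectorized over t
# (t >= 0, seconds after light onset). Sustained decay starts at 30 s.
.model_rpa <- function(spec, intensity, t) {
  tr <- spec$transient
  p_t <- if (intensity == 0) 1 else
    .sigmoid_rpa(log10(intensity), 1, tr$bottom, log10(tr$ec50), tr$hill)
  d <- tr$onset_delay
  y <- ifelse(t < d, 1, p_t + (1 - p_t) * exp(-tr$k * (t - d)))
  if (spec$redilation_rate > 0)
    y <- 1 - (1 - y) * exp(-spec$redilation_rate * pmax(t - d, 0))

  late <- t >= 30
  if (any(late)) {
    y30 <- {
      v <- p_t + (1 - p_t) * exp(-tr$k * (30 - d))
      if (spec$redilation_rate > 0)
        v <- 1 - (1 - v) * exp(-spec$redilation_rate * (30 - d))
      v
    }
    if (is.null(spec$sustained)) {
      p_s <- 1
      k_min <- spec$sustained_decay_rate
    } else {
      su <- spec$sustained
      p_s <- if (intensity == 0) 1 else
        .sigmoid_rpa(log10(intensity), 1, su$bottom, log10(su$ec50), su$hill)
      li <- pmin(pmax(if (intensity == 0) 0 else log10(intensity), 0), 2)
      k_min <- .sigmoid_rate(li, su$rate_at_1lux, su$rate_at_100lux,
                             su$log_midpoint, su$slope)
    }
    y[late] <- p_s + (y30 - p_s) * exp(-(k_min / 60) * (t[late] - 30))
    if (!is.null(spec$pulsatile)) {
      pu <- spec$pulsatile
      mod <- 1 + pu$amplitude * sin(2 * pi * (t[late] - 30) / pu$period)
      y[late] <- 1 - (1 - y[late]) * mod
    }
  }
  pmin(pmax(y, 0.02), 1)
}

.baseline_times <- function(dt) {
  tb <- seq(-3, -dt, by = dt)
  if (length(tb) < 3) tb <- c(-3, -2, -1)
  tb
}

# Deterministic per-unit seed stream derived from one base seed.
.derive_seed <- function(base, i) {
  (as.numeric(base) * 7919 + as.numeric(i) * 104729) %% 2147483629 + 1
}

#' Generate a synthetic pupil trace
#'
#' Emits a raw-area [pupil_trace()] for one genotype at one intensity:
#' at least three dark-baseline samples, then the genotype's noiseless
#' response model plus additive Gaussian noise, floored at a relative
#' pupil area of 0.02 and converted to areas via the spec's baseline
#' area. Identical seeds give bit-identical traces.
#'
#' @param spec A [genotype_spec()].
#' @param intensity Stimulus illuminance (lux, >= 0).
#' @param duration Length of the lit segment (s).
#' @param dt Sampling interval (s).
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @param noise_sd Override for the spec's noise SD (0 for noiseless).
#' @param mouse_id Identifier stored on the trace.
#' @return A [pupil_trace()].
#' @export
generate_trace <- function(spec, intensity, duration = 30, dt = 0.5,
                           seed = NULL, noise_sd = spec$noise_sd,
                           mouse_id = "synthetic") {
  stopifnot(inherits(spec, "genotype_spec"), duration > 0, dt > 0,
            intensity >= 0)
  tb <- .baseline_times(dt)
  tp <- seq(0, duration, by = dt)
  rpa <- c(rep(1, length(tb)), .model_rpa(spec, intensity, tp))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
    rpa <- rpa + stats::rnorm(length(rpa), 0, noise_sd)
  }
  rpa <- pmin(pmax(rpa, 0.02), 1 + 4 * noise_sd)
  pupil_trace(mouse_id, spec$name, intensity, c(tb, tp),
              rpa * spec$baseline_area)
}

#' Generate a cohort of per-mouse endpoints (and optionally traces)
#'
#' Emulates the per-mouse intensity-response design: every mouse is tested
#' at every intensity under a 30-s transient protocol (endpoint: minimum
#' relative pupil area at 5 s or 30 s, extracted through
#' [relative_trace()] and [transient_endpoint()]) and a 60-min sustained
#' protocol (endpoint: relative pupil area at 3600 s). The response model
#' is evaluated at the protocol time points only.
#'
#' @param specs A list of [genotype_spec()] (or a single spec).
#' @param intensities Test illuminances (lux, > 0).
#' @param n_per_genotype Mice per genotype.
#' @param base_seed Integer seed; all per-mouse noise streams derive from
#'   it deterministically.
#' @param noise_sd Optional override of each spec's noise SD.
#' @return A data.frame with columns `genotype`, `mouse_id`,
#'   `intensity_lux`, `transient_rpa`, `sustained_rpa`.
#' @export
generate_cohort <- function(specs, intensities, n_per_genotype = 6,
                            base_seed = 1, noise_sd = NULL) {
  if (inherits(specs, "genotype_spec")) specs <- list(specs)
  stopifnot(n_per_genotype >= 1, all(intensities > 0))
  rows <- vector("list", length(specs) * n_per_genotype * length(intensities))
  r <- 0; unit <- 0
  for (spec in specs) {
    sd_use <- if (is.null(noise_sd)) spec$noise_sd else noise_sd
    for (m in seq_len(n_per_genotype)) {
      mouse <- sprintf("%s_m%02d", spec$name, m)
      for (I in intensities) {
        unit <- unit + 1
        set.seed(.derive_seed(base_seed, unit))
        # transient protocol: baseline + samples at 5 s and 30 s
        tb <- c(-3, -2, -1)
        rpa_tr <- c(rep(1, 3), .model_rpa(spec, I, c(5, 30)))
        if (sd_use > 0) rpa_tr <- rpa_tr + stats::rnorm(5, 0, sd_use)
        rpa_tr <- pmin(pmax(rpa_tr, 0.02), 1 + 4 * sd_use)
        tr <- pupil_trace(mouse, spec$name, I, c(tb, 5, 30),
                          rpa_tr * spec$baseline_area)
        t_end <- transient_endpoint(relative_trace(tr))
        # sustained protocol: baseline + sample at 60 min
        rpa_su <- c(rep(1, 3), .model_rpa(spec, I, 3600))
        if (sd_use > 0) rpa_su <- rpa_su + stats::rnorm(4, 0, sd_use)
        rpa_su <- pmin(pmax(rpa_su, 0.02), 1 + 4 * sd_use)
        su <- pupil_trace(mouse, spec$name, I, c(tb, 3600),
                          rpa_su * spec$baseline_area)
        s_end <- relative_trace(su)$rpa[4]
        r <- r + 1
        rows[[r]] <- data.frame(genotype = spec$name, mouse_id = mouse,
                                intensity_lux = I, transient_rpa = t_end,
                                sustained_rpa = s_end,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows[seq_len(r)])
}

#' Generate a synthetic 1-s pulse-chase profile
#'
#' One second of light to a dark-adapted pupil, constriction followed for
#' 30 s: the profile rises to peak constriction at a 6-s lag and then
#' decays, sampled at integer lags 0-30 s. The noiseless profile has zero
#' constriction at lag 0 (constriction lags light) and normalizes to a
#' maximum weight of exactly 1 at the peak.
#'
#' @param spec A [genotype_spec()] (supplies the noise SD).
#' @param seed Integer seed (used only when noise is added).
#' @param peak_lag Lag of maximum constriction (s).
#' @param depth Constriction depth at the peak (rpa units).
#' @param shape Shape exponent of the gamma-like profile.
#' @param noise_sd Override for the spec's noise SD.
#' @return A [as_relative_trace()] over lags 0-30 s.
#' @export
generate_pulse_chase <- function(spec, seed = NULL, peak_lag = 6,
                                 depth = 0.6, shape = 2,
                                 noise_sd = spec$noise_sd) {
  stopifnot(inherits(spec, "genotype_spec"), peak_lag > 0,
            depth > 0, depth < 1)
  lag <- 0:30
  g <- (lag / peak_lag)^shape * exp(shape * (1 - lag / peak_lag))
  rpa <- 1 - depth * g
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
    rpa <- rpa + stats::rnorm(length(rpa), 0, noise_sd)
  }
  rpa <- pmin(pmax(rpa, 0.02), 1 + 4 * noise_sd)
  as_relative_trace(lag, rpa, mouse_id = "pulse_chase",
                    genotype = spec$name, intensity = NA_real_)
}

#' Noiseless model curves for a genotype (for plotting and round-trips)
#'
#' @param spec A [genotype_spec()].
#' @param intensity Illuminance (lux).
#' @param times Times (s, >= 0).
#' @return A [as_relative_trace()] of the noiseless response model.
#' @export
model_trace <- function(spec, intensity, times) {
  as_relative_trace(times, .model_rpa(spec, intensity, times),
                    genotype = spec$name, intensity = intensity)
}
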