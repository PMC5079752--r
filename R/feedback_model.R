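# Negative-feedback model of pupillary-light-response decay.
#
# The pupil attenuates its own input: retinal illuminance is environmental
# illuminance scaled by pupil area. The model discretizes light into 1-s
# packets; a packet arriving at second s drives constriction over the next
# L seconds with depth (1 - drc(lux_s)) shaped by the pulse-chase weighting
# omega. Packets do not summate (zero-summation assumption): at any time the
# pupil adopts the single deepest constriction on offer, which maximizes
# feedback and so bounds its contribution to decay from above.

#' Temporal weighting of a light packet's effect on constriction
#'
#' @param lags Integer lags in seconds, `0:L`.
#' @param weights Weights in [0, 1], one per lag, with `max(weights) == 1`.
#' @return An object of class `temporal_weighting` with `lags`, `weights`
#'   and `peak_lag` (the argmax lag).
#' @export
temporal_weighting <- function(lags, weights) {
  lags <- as.integer(lags)
  if (!identical(lags, seq(0L, max(lags))))
    stop("`lags` must be the consecutive integers 0..L")
  if (length(weights) != length(lags)) stop("length mismatch")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(max(weights) - 1) > 1e-12)
    stop("weights must be normalized so the maximum is exactly 1")
  structure(list(lags = lags, weights = as.numeric(weights),
                 peak_lag = lags[which.max(weights)]),
            class = "temporal_weighting")
}

#' @export
print.temporal_weighting <- function(x, ...) {
  cat(sprintf("Temporal weighting over lags 0..%d s, peak at %d s\n",
              max(x$lags), x$peak_lag))
  invisible(x)
}

#' Derive the temporal weighting from a 1-s pulse-chase trace
#'
#' A dark-adapted pupil is given one second of light and its constriction
#' followed for `max_lag` seconds. The constriction profile, normalized to
#' the maximum constriction achieved (empirically at the 6-s time point),
#' weights how a packet of light influences pupil size at later seconds.
#'
#' @param rel A [relative_trace()] of the post-pulse response, with samples
#'   covering integer lags `0..max_lag` (nearest-sample matching within
#'   0.5 s).
#' @param max_lag Largest lag in seconds (default 30).
#' @return A [temporal_weighting()].
#' @export
omega_from_pulse_chase <- function(rel, max_lag = 30) {
  stopifnot(inherits(rel, "relative_trace"))
  lags <- 0:max_lag
  rpa <- vapply(lags, function(l) {
    i <- which.min(abs(rel$times - l))
    if (abs(rel$times[i] - l) > 0.5)
      stop("no sample within 0.5 s of lag ", l, " s")
    rel$rpa[i]
  }, numeric(1))
  depth <- pmax(1 - rpa, 0)
  if (max(depth) <= 0)
    stop("no constriction in the pulse-chase trace; cannot normalize")
  temporal_weighting(lags, depth / max(depth))
}

.as_drc_fun <- function(drc) {
  if (inherits(drc, "sigmoid_fit")) return(function(lux) predict_rpa(drc, lux))
  if (is.function(drc)) return(drc)
  if (is.data.frame(drc)) {  # tabulated dose-response, interpolated in log lux
    stopifnot(all(c("intensity_lux", "rpa") %in% names(drc)))
    li <- log10(drc$intensity_lux); v <- drc$rpa
    return(function(lux) stats::approx(li, v, xout = log10(pmax(lux, 1e-300)),
                                       rule = 2)$y)
  }
  stop("`drc` must be a sigmoid_fit, a function, or a tabulated data.frame")
}

#' Simulate pupillary negative feedback at one environmental intensity
#'
#' Runs the per-second packet recursion: at t = 1 the full environmental
#' illuminance reaches the retina; each second's packet carries a
#' constriction depth `1 - drc(lux_t)` spread over subsequent seconds by
#' the temporal weighting; retinal illuminance at each later second is the
#' environmental illuminance attenuated by the single deepest constriction
#' driven by any previous packet (no summation across packets). The
#' reported trace is the per-second pupil size under that same
#' maximum-constriction rule.
#'
#' @param drc The dose-response mapping lux to relative pupil area in
#'   (0, 1]: a [fit_intensity_response()] result, a function, or a
#'   data.frame with columns `intensity_lux` and `rpa`.
#' @param omega A [temporal_weighting()].
#' @param env_lux Environmental illuminance (lux, >= 0).
#' @param horizon Simulation length in seconds (default 956).
#' @return An object of class `feedback_sim` with per-second vectors
#'   `rpa_t` and `retinal_lux_t`, plus `decay_magnitude`
#'   (`rpa` at the horizon minus the minimum `rpa`), `openloop_plateau`
#'   (`drc(env_lux)`), `env_lux` and `horizon`.
#' @export
simulate_feedback <- function(drc, omega, env_lux, horizon = 956) {
  stopifnot(inherits(omega, "temporal_weighting"))
  if (env_lux < 0) stop("env_lux must be >= 0")
  if (horizon < 1) stop("horizon must be >= 1")
  alpha <- .as_drc_fun(drc)
  chk <- function(v) {
    if (any(v <= 0) || any(v > 1 + 1e-12))
      stop("drc must return relative pupil area in (0, 1]")
    pmin(v, 1)
  }
  w <- omega$weights
  L <- max(omega$lags)

  depth <- numeric(horizon)
  lux <- numeric(horizon)
  lux[1] <- env_lux
  depth[1] <- 1 - chk(alpha(lux[1]))
  if (horizon >= 2) {
    for (t in 2:horizon) {
      s <- max(1, t - L):(t - 1)
      C <- max(depth[s] * w[t - s + 1])
      lux[t] <- (1 - C) * env_lux
      depth[t] <- 1 - chk(alpha(lux[t]))
    }
  }
  rpa <- vapply(seq_len(horizon), function(t) {
    s <- max(1, t - L):t
    1 - max(depth[s] * w[t - s + 1])
  }, numeric(1))

  structure(
    list(env_lux = env_lux, horizon = horizon, rpa_t = rpa,
         retinal_lux_t = lux, depth_t = depth,
         decay_magnitude = rpa[horizon] - min(rpa),
         openloop_plateau = chk(alpha(env_lux))),
    class = "feedback_sim")
}

#' @export
print.feedback_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Negative-feedback simulation at %g lux over %d s\n",
              x$env_lux, x$horizon))
  cat(sprintf("  open-loop plateau %s, min rpa %s, end rpa %s\n",
              format(x$openloop_plateau, digits = digits),
              format(min(x$rpa_t), digits = digits),
              format(x$rpa_t[x$horizon], digits = digits)))
  cat(sprintf("  feedback-driven decay magnitude %s\n",
              format(x$decay_magnitude, digits = digits)))
  invisible(x)
}

#' @export
plot.feedback_sim <- function(x, ...) {
  graphics::plot(seq_len(x$horizon), x$rpa_t, type = "l",
                 xlab = "time (s)", ylab = "relative pupil area",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$openloop_plateau, lty = 3)
  invisible(x)
}

#' Packet matrix view of a feedback simulation
#'
#' Debugging view equivalent to the recursion's bookkeeping: entry (s, t)
#' is the pupil size driven at second t by the packet that arrived at
#' second s (NA outside the packet's lag window). Column minima reproduce
#' `rpa_t`.
#'
#' @param sim A [simulate_feedback()] result.
#' @param omega The weighting used in the simulation.
#' @return A `horizon` x `horizon` matrix.
#' @export
feedback_packet_matrix <- function(sim, omega) {
  stopifnot(inherits(sim, "feedback_sim"), inherits(omega, "temporal_weighting"))
  h <- sim$horizon; L <- max(omega$lags); w <- omega$weights
  M <- matrix(NA_real_, h, h)
  for (s in seq_len(h)) {
    t_idx <- s:min(h, s + L)
    M[s, t_idx] <- 1 - sim$depth_t[s] * w[t_idx - s + 1]
  }
  M
}

#' Sweep the feedback model across intensities
#'
#' Runs [simulate_feedback()] at each intensity and summarizes the
#' feedback-driven decay. Apparent sensitivity with and without the decay
#' is quantified by fitting intensity-response curves to the early minimum
#' pupil size and to the horizon-end pupil size.
#'
#' @inheritParams simulate_feedback
#' @param intensities Illuminances to simulate (lux). The default is the
#'   nine-step ladder 0.0001 to 10,000 lux.
#' @return An object of class `feedback_sweep`: a `summary` data.frame
#'   (intensity, open-loop plateau, min/end rpa, decay magnitude), the
#'   per-intensity `sims`, and `ec50_early` / `ec50_end` sigmoid fits
#'   (NULL when fewer than four positive intensities are swept).
#' @export
feedback_intensity_sweep <- function(drc, omega,
                                     intensities = 10^seq(-4, 4),
                                     horizon = 956) {
  if (any(intensities < 0)) stop("intensities must be >= 0")
  sims <- lapply(intensities, function(I)
    simulate_feedback(drc, omega, I, horizon))
  summary <- data.frame(
    intensity_lux = intensities,
    openloop_plateau = vapply(sims, `[[`, numeric(1), "openloop_plateau"),
    min_rpa = vapply(sims, function(s) min(s$rpa_t), numeric(1)),
    end_rpa = vapply(sims, function(s) s$rpa_t[s$horizon], numeric(1)),
    decay_magnitude = vapply(sims, `[[`, numeric(1), "decay_magnitude"))

  pos <- summary$intensity_lux > 0
  fit_or_null <- function(y) {
    if (sum(pos) < 4) return(NULL)
    tryCatch(fit_intensity_response(summary$intensity_lux[pos], y[pos],
                                    constrain_bottom = FALSE),
             error = function(e) NULL)
  }
  structure(list(summary = summary, sims = sims,
                 ec50_early = fit_or_null(summary$min_rpa),
                 ec50_end = fit_or_null(summary$end_rpa)),
            class = "feedback_sweep")
}

#' @export
print.feedback_sweep <- function(x, digits = 4, ...) {
  cat("Negative-feedback intensity sweep\n")
  print(x$summary, digits = digits)
  if (!is.null(x$ec50_early))
    cat(sprintf("EC50 (early minimum): %s lux; EC50 (horizon end): %s lux\n",
                format(ec50_lux(x$ec50_early), digits = digits),
                format(ec50_lux(x$ec50_end), digits = digits)))
  invisible(x)
}
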