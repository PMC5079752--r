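# One- and two-phase exponential kinetics of pupil constriction and decay.
# The one-phase association Y(t) = plateau + (y0 - plateau) * exp(-k t)
# covers both constriction (y0 = 1 falling to a plateau) and decay of
# constriction (plateau above y0); half-life = ln 2 / k.

.one_phase <- function(t, y0, plateau, k, t_offset = 0) {
  ifelse(t < t_offset, y0, plateau + (y0 - plateau) * exp(-k * (t - t_offset)))
}

#' Fit a one-phase exponential to a constriction/decay time course
#'
#' Fits \eqn{Y(t) = plateau + (y_0 - plateau) e^{-k (t - t_0)}} for
#' \eqn{t \ge t_0} (with \eqn{Y = y_0} before the offset) to the post-onset
#' samples of a relative trace by bounded Levenberg-Marquardt least
#' squares. The offset accommodates genotypes whose constriction lags light
#' onset (e.g. a melanopsin-only response fitted with a 3-s delay).
#'
#' @param rel A [relative_trace()] (or [as_relative_trace()]) object.
#' @param t_offset Delay in seconds before the exponential starts; samples
#'   earlier than the offset are modeled at `y0`.
#' @return An object of class `kinetic_fit` with elements `y0`, `plateau`,
#'   `k` (1/s on a trace timed in seconds), `t_offset`, `kind`
#'   (`"one_phase"`), `half_life` and `rss`; `k_at_bound` flags a rate
#'   pinned at the box constraint.
#' @seealso [fit_two_phase()], [half_life()]
#' @export
fit_one_phase <- function(rel, t_offset = 0) {
  stopifnot(inherits(rel, "relative_trace"))
  post <- rel$times >= 0
  t <- rel$times[post]; y <- rel$rpa[post]
  if (length(t) < 4) stop("need >= 4 post-onset samples")
  if (stats::sd(y) < 1e-12)
    stop("degenerate fit: trace is constant, no kinetics to estimate")

  y0_0 <- y[1]
  plat_0 <- mean(y[t >= stats::quantile(t, 0.8)])
  k_lo <- 1e-4; k_hi <- 100
  dt_med <- stats::median(diff(t))
  k_starts <- unique(pmin(pmax(c(1 / max(t), 0.1, 1, 1 / dt_med), k_lo), k_hi))

  resid_fn <- function(p)
    y - .one_phase(t, p["y0"], p["plateau"], p["k"], t_offset)
  best <- NULL
  for (k0 in k_starts) {
    res <- try(minpack.lm::nls.lm(
      par = c(y0 = y0_0, plateau = plat_0, k = k0),
      lower = c(0, 0, k_lo), upper = c(2, 2, k_hi), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- res$deviance
    if (is.null(best) || rss < best$rss) {
      cf <- res$par
      best <- list(y0 = unname(cf["y0"]), plateau = unname(cf["plateau"]),
                   k = unname(cf["k"]), rss = rss)
      if (rss < 1e-16) break
    }
  }
  if (is.null(best)) stop("one-phase fit failed to converge")
  structure(
    list(y0 = best$y0, plateau = best$plateau, k = best$k,
         t_offset = t_offset, kind = "one_phase",
         half_life = log(2) / best$k, rss = best$rss,
         k_at_bound = best$k <= k_lo * 1.01 || best$k >= k_hi * 0.99,
         n = length(t), data = data.frame(time_s = t, rpa = y)),
    class = "kinetic_fit")
}

#' Fit a two-phase (bi-exponential) time course
#'
#' Fits \eqn{Y(t) = plateau + A_1 e^{-k_1 t} + A_2 e^{-k_2 t}} with spans
#' free in sign, which permits non-monotone traces that constrict and then
#' re-dilate within the recording window (a cone-driven response decays
#' within 30 s). If the two-phase fit does not beat the nested one-phase
#' fit by a relative RSS tolerance, the one-phase fit is returned with
#' `reduced_from_two_phase = TRUE`.
#'
#' @param rel A relative trace.
#' @param rel_tol Minimum fractional RSS improvement over the one-phase fit
#'   required to accept the extra phase.
#' @return A `kinetic_fit` of kind `"two_phase"` (fields `plateau`, `a1`,
#'   `k`, `a2`, `k2`, with `k > k2`, and `span_fraction = |a1|/(|a1|+|a2|)`),
#'   or the one-phase fit flagged as reduced.
#' @export
fit_two_phase <- function(rel, rel_tol = 0.01) {
  stopifnot(inherits(rel, "relative_trace"))
  post <- rel$times >= 0
  t <- rel$times[post]; y <- rel$rpa[post]
  if (length(t) < 6) stop("need >= 6 post-onset samples")
  one <- fit_one_phase(rel)

  k_pairs <- list(c(1, 0.1), c(0.5, 0.05), c(2, 0.2), c(0.2, 0.02),
                  c(one$k * 3, one$k / 3))
  plat_0 <- mean(y[t >= stats::quantile(t, 0.8)])
  resid_fn <- function(p)
    y - (p["plateau"] + p["a1"] * exp(-p["k1"] * t) +
           p["a2"] * exp(-p["k2"] * t))
  best <- NULL
  for (kp in k_pairs) {
    res <- try(minpack.lm::nls.lm(
      par = c(plateau = plat_0, a1 = y[1] - plat_0, a2 = 0,
              k1 = kp[1], k2 = kp[2]),
      lower = c(0, -2, -2, 1e-4, 1e-5), upper = c(2, 2, 2, 100, 100),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- res$deviance
    if (is.null(best) || rss < best$rss) {
      cf <- as.list(res$par)
      best <- c(cf, rss = rss)
      if (rss < 1e-16) break
    }
  }
  improved <- !is.null(best) &&
    best$rss < one$rss * (1 - rel_tol) - 1e-12
  if (!improved) {
    one$reduced_from_two_phase <- TRUE
    return(one)
  }
  # canonical order: k is the faster rate
  if (best$k1 < best$k2) {
    best[c("k1", "k2")] <- best[c("k2", "k1")]
    best[c("a1", "a2")] <- best[c("a2", "a1")]
  }
  structure(
    list(y0 = best$plateau + best$a1 + best$a2, plateau = best$plateau,
         a1 = best$a1, a2 = best$a2, k = best$k1, k2 = best$k2,
         t_offset = 0, kind = "two_phase",
         half_life = log(2) / best$k1,
         span_fraction = abs(best$a1) / (abs(best$a1) + abs(best$a2)),
         rss = best$rss, n = length(t),
         data = data.frame(time_s = t, rpa = y)),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  if (x$kind == "one_phase") {
    cat("One-phase exponential fit\n")
    cat(sprintf("  y0 %s, plateau %s, k %s /s (half-life %s s)",
                format(x$y0, digits = digits),
                format(x$plateau, digits = digits),
                format(x$k, digits = digits),
                format(x$half_life, digits = digits)))
    if (x$t_offset != 0) cat(sprintf(", offset %g s", x$t_offset))
    if (isTRUE(x$reduced_from_two_phase))
      cat("\n  (two-phase fit reduced to one phase)")
    if (isTRUE(x$k_at_bound)) cat("\n  warning: rate pinned at bound")
  } else {
    cat("Two-phase exponential fit\n")
    cat(sprintf("  plateau %s + %s exp(-%s t) + %s exp(-%s t)",
                format(x$plateau, digits = digits),
                format(x$a1, digits = digits), format(x$k, digits = digits),
                format(x$a2, digits = digits), format(x$k2, digits = digits)))
  }
  cat(sprintf("\n  RSS %s over n = %d points\n",
              format(x$rss, digits = 3), x$n))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  if (object$kind == "one_phase")
    c(y0 = object$y0, plateau = object$plateau, k = object$k,
      t_offset = object$t_offset)
  else
    c(plateau = object$plateau, a1 = object$a1, k = object$k,
      a2 = object$a2, k2 = object$k2)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s
       else if (is.data.frame(newdata)) newdata$time_s else newdata
  if (object$kind == "one_phase")
    .one_phase(t, object$y0, object$plateau, object$k, object$t_offset)
  else
    object$plateau + object$a1 * exp(-object$k * t) +
      object$a2 * exp(-object$k2 * t)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$rpa - predict(object, object$data$time_s)
}

#' @export
plot.kinetic_fit <- function(x, n = 300, ...) {
  graphics::plot(x$data$time_s, x$data$rpa, xlab = "time (s)",
                 ylab = "relative pupil area", ...)
  tt <- seq(min(x$data$time_s), max(x$data$time_s), length.out = n)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Half-life of an exponential rate
#'
#' @param k Rate constant(s), > 0; the half-life is in the time unit of
#'   `1/k` (seconds for a per-second rate, minutes for a per-minute rate).
#' @return `ln 2 / k`.
#' @export
half_life <- function(k) {
  if (inherits(k, "kinetic_fit")) k <- k$k
  if (any(k <= 0)) stop("rate constant must be > 0")
  log(2) / k
}

#' Fit the sustained decay rate as a function of intensity
#'
#' The decay rate of sustained pupil constriction changes with intensity;
#' a sigmoid in log10 lux is fitted through rates measured at 1, 10 and
#' 100 lux, with its top and bottom constrained to the 1-lux and 100-lux
#' rates respectively. Evaluation outside 1-100 lux clamps to the nearer
#' plateau rather than extrapolating.
#'
#' @param rates Either a numeric vector `c(r1, r10, r100)` of positive
#'   decay rates (1/min) at 1, 10 and 100 lux, or a data.frame with
#'   columns `lux` and `rate`.
#' @return An object of class `decay_rate_curve` with `top_rate` (rate at
#'   1 lux), `bottom_rate` (rate at 100 lux), `log_midpoint`, `slope`.
#' @seealso [predict.decay_rate_curve()]
#' @export
fit_decay_rate_vs_intensity <- function(rates) {
  if (is.data.frame(rates)) {
    rates <- rates[order(rates$lux), ]
    if (!isTRUE(all.equal(rates$lux, c(1, 10, 100))))
      stop("rates must be measured at 1, 10 and 100 lux")
    rates <- rates$rate
  }
  if (length(rates) != 3 || any(rates <= 0))
    stop("need three positive rates (at 1, 10 and 100 lux)")
  r1 <- rates[1]; r10 <- rates[2]; r100 <- rates[3]

  if (abs(r1 - r100) < 1e-12) {
    return(structure(list(top_rate = r1, bottom_rate = r100,
                          log_midpoint = 1, slope = 1, rss = (r10 - r1)^2),
                     class = "decay_rate_curve"))
  }
  obj <- function(p) {
    pred <- .sigmoid_rate(c(0, 1, 2), r1, r100, p[1], p[2])
    sum((pred - c(r1, r10, r100))^2)
  }
  best <- NULL
  for (s0 in c(0.5, 1, 2, 4)) {
    res <- try(stats::optim(c(1, s0), obj, method = "L-BFGS-B",
                            lower = c(0, 0.05), upper = c(2, 20)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("decay-rate curve fit failed")
  structure(list(top_rate = r1, bottom_rate = r100,
                 log_midpoint = best$par[1], slope = best$par[2],
                 rss = best$value),
            class = "decay_rate_curve")
}

# top at low intensity, bottom at high; slope > 0
.sigmoid_rate <- function(log10_I, top, bottom, log_mid, slope) {
  bottom + (top - bottom) / (1 + 10^((log10_I - log_mid) * slope))
}

#' Evaluate a decay-rate-vs-intensity curve
#'
#' @param object A `decay_rate_curve`.
#' @param newdata Illuminance in lux (vectorized); values outside
#'   [1, 100] lux are clamped to the fitted range before evaluation.
#' @param ... Unused.
#' @return Decay rates in the unit the curve was fitted in (1/min).
#' @export
predict.decay_rate_curve <- function(object, newdata, ...) {
  li <- log10(pmax(newdata, .Machine$double.xmin))
  out <- .sigmoid_rate(li, object$top_rate, object$bottom_rate,
                       object$log_midpoint, object$slope)
  out[li <= 0] <- object$top_rate     # below the 1-lux plateau
  out[li >= 2] <- object$bottom_rate  # above the 100-lux plateau
  lo <- min(object$top_rate, object$bottom_rate)
  hi <- max(object$top_rate, object$bottom_rate)
  pmin(pmax(out, lo), hi)
}

#' @export
print.decay_rate_curve <- function(x, digits = 4, ...) {
  cat("Sustained decay rate vs intensity (sigmoid in log10 lux)\n")
  cat(sprintf("  rate at 1 lux %s /min, at 100 lux %s /min\n",
              format(x$top_rate, digits = digits),
              format(x$bottom_rate, digits = digits)))
  cat(sprintf("  log10 midpoint %s, slope %s\n",
              format(x$log_midpoint, digits = digits),
              format(x$slope, digits = digits)))
  invisible(x)
}
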