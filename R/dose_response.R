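# Variable-slope sigmoid in log10 dose:
#   rpa(I) = bottom + (top - bottom) / (1 + 10^((log_ec50 - log10 I) * hill))
# hill < 0 gives constriction (rpa falling with intensity).
.sigmoid_rpa <- function(log10_I, top, bottom, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - log10_I) * hill))
}

#' Fit a constrained variable-slope intensity-response curve
#'
#' Fits relative pupil area against stimulus illuminance with the
#' four-parameter logistic in log10 dose,
#' \deqn{rpa(I) = bottom + (top - bottom) / (1 + 10^{(\log_{10} EC_{50} - \log_{10} I)\,h}),}
#' by bounded Levenberg-Marquardt least squares with multiple starts. The
#' top is constrained to 1.0 (a fully open pupil in the dark) and the
#' bottom to [0, 0.10] so that EC50 values are comparable across genotypes;
#' for genotypes that never constrict below 0.10 the bottom constraint can
#' be dropped, either explicitly or automatically.
#'
#' @param intensity Illuminance values in lux (> 0), or a data.frame with
#'   columns `intensity_lux` (or `intensity`) and `rpa`.
#' @param rpa Relative pupil area at each intensity (ignored when
#'   `intensity` is a data.frame).
#' @param constrain_bottom Bound the bottom to [0, 0.10] (default TRUE);
#'   when FALSE the bottom is free in [0, 1].
#' @param constrain_top Fix the top at 1.0 (default TRUE).
#' @param auto_fallback When the constrained bottom pins at 0.10 and the
#'   data never fall below 0.10, automatically refit with a free bottom.
#' @return An object of class `sigmoid_fit` with elements `top`, `bottom`,
#'   `log_ec50`, `hill_slope`, `constrained_top`, `constrained_bottom`,
#'   `rss`, `n`, and the fitted data.
#' @seealso [ec50_lux()], [predict_rpa()], [group_ec50_summary()]
#' @export
fit_intensity_response <- function(intensity, rpa = NULL,
                                   constrain_bottom = TRUE,
                                   constrain_top = TRUE,
                                   auto_fallback = TRUE) {
  if (is.data.frame(intensity)) {
    df <- intensity
    icol <- if ("intensity_lux" %in% names(df)) "intensity_lux" else "intensity"
    rpa <- df$rpa
    intensity <- df[[icol]]
  }
  keep <- intensity > 0
  intensity <- intensity[keep]; rpa <- rpa[keep]
  if (length(unique(intensity)) < 4)
    stop("need >= 4 distinct positive intensities to fit a sigmoid")
  if (any(rpa <= 0) || any(rpa >= 1.5))
    stop("rpa values must lie in (0, 1.5)")
  li <- log10(intensity)

  fit <- .fit_sigmoid_ls(li, rpa, constrain_top, constrain_bottom)
  if (auto_fallback && constrain_bottom &&
      fit$bottom >= 0.10 - 1e-6 && min(rpa) > 0.10) {
    fit <- .fit_sigmoid_ls(li, rpa, constrain_top, constrain_bottom = FALSE)
    constrain_bottom <- FALSE
  }
  structure(
    list(top = fit$top, bottom = fit$bottom, log_ec50 = fit$log_ec50,
         hill_slope = fit$hill, constrained_top = constrain_top,
         constrained_bottom = constrain_bottom, rss = fit$rss,
         n = length(rpa),
         data = data.frame(intensity_lux = intensity, rpa = rpa)),
    class = "sigmoid_fit")
}

# Bounded Levenberg-Marquardt least squares (residual interface) with a
# heuristic start plus a small multistart over the Hill slope and midpoint;
# returns the best-RSS solution.
.fit_sigmoid_ls <- function(li, rpa, constrain_top, constrain_bottom) {
  b_hi <- if (constrain_bottom) 0.10 else 1.0
  b0 <- min(max(min(rpa), 0), b_hi)
  # heuristic midpoint: log-intensity where rpa crosses halfway down
  half <- (max(rpa) + min(rpa)) / 2
  ord <- order(li)
  cross <- li[ord][which.min(abs(rpa[ord] - half))]
  starts_hill <- c(-1, -0.5, -2)
  starts_mid <- unique(c(cross, stats::median(li)))
  lower_mid <- min(li) - 3; upper_mid <- max(li) + 3

  resid_fn <- if (constrain_top) {
    function(p) rpa - .sigmoid_rpa(li, 1.0, p["bottom"], p["log_ec50"],
                                   p["hill"])
  } else {
    function(p) rpa - .sigmoid_rpa(li, p["top"], p["bottom"], p["log_ec50"],
                                   p["hill"])
  }
  best <- NULL
  for (h0 in starts_hill) for (m0 in starts_mid) {
    p0 <- c(bottom = b0, log_ec50 = m0, hill = h0)
    lo <- c(0, lower_mid, -10); hi <- c(b_hi, upper_mid, 10)
    if (!constrain_top) {
      p0 <- c(top = 1.0, p0); lo <- c(0.5, lo); hi <- c(1.5, hi)
    }
    res <- try(minpack.lm::nls.lm(
      par = p0, lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- res$deviance
    if (is.null(best) || rss < best$rss) {
      cf <- res$par
      best <- list(top = if (constrain_top) 1.0 else unname(cf["top"]),
                   bottom = unname(cf["bottom"]),
                   log_ec50 = unname(cf["log_ec50"]),
                   hill = unname(cf["hill"]), rss = rss)
      if (rss < 1e-14) break  # exact data: no further starts needed
    }
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from any start; ",
         "check the intensity coverage of the data")
  if (best$bottom > best$top) stop("degenerate fit: bottom exceeds top")
  best
}

#' @export
print.sigmoid_fit <- function(x, digits = 4, ...) {
  cat("Variable-slope intensity-response fit\n")
  cat(sprintf("  top        %s\n",
              format(x$top, digits = digits)),
      sprintf(" bottom     %s%s\n", format(x$bottom, digits = digits),
              if (x$constrained_bottom) "  (constrained to [0, 0.10])" else ""),
      sprintf(" log10 EC50 %s  (EC50 = %s lux)\n",
              format(x$log_ec50, digits = digits),
              format(ec50_lux(x), digits = digits)),
      sprintf(" Hill slope %s\n", format(x$hill_slope, digits = digits)),
      sprintf(" RSS %s over n = %d points\n",
              format(x$rss, digits = 3), x$n), sep = "")
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    log_ec50 = object$log_ec50, hill_slope = object$hill_slope)
}

#' Half-maximal intensity of a sigmoid fit, in lux
#'
#' @param fit A [fit_intensity_response()] result.
#' @return `10^log_ec50`, the illuminance of half-maximal constriction.
#' @export
ec50_lux <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  10^fit$log_ec50
}

#' Evaluate a fitted intensity-response curve
#'
#' Returns the curve's relative pupil area at the given illuminance;
#' `intensity = 0` returns the top (a fully open pupil). Output is clamped
#' to (0, top].
#'
#' @param fit A `sigmoid_fit`.
#' @param intensity Illuminance in lux (>= 0); vectorized.
#' @return Relative pupil area values.
#' @export
predict_rpa <- function(fit, intensity) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (any(intensity < 0)) stop("intensity must be >= 0")
  out <- ifelse(intensity == 0, fit$top,
                .sigmoid_rpa(log10(pmax(intensity, .Machine$double.xmin)),
                             fit$top, fit$bottom, fit$log_ec50, fit$hill_slope))
  pmin(pmax(out, .Machine$double.eps), fit$top)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict_rpa(object, object$data$intensity_lux))
  if (is.data.frame(newdata)) {
    icol <- if ("intensity_lux" %in% names(newdata)) "intensity_lux" else "intensity"
    newdata <- newdata[[icol]]
  }
  predict_rpa(object, newdata)
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$data$rpa - predict_rpa(object, object$data$intensity_lux)
}

#' @export
plot.sigmoid_fit <- function(x, n = 200, ...) {
  rng <- range(log10(x$data$intensity_lux))
  li <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n)
  graphics::plot(log10(x$data$intensity_lux), x$data$rpa,
                 xlab = "log10 intensity (lux)", ylab = "relative pupil area",
                 ylim = c(0, max(1, x$data$rpa)), ...)
  graphics::lines(li, .sigmoid_rpa(li, x$top, x$bottom, x$log_ec50,
                                   x$hill_slope))
  graphics::abline(v = x$log_ec50, lty = 3)
  invisible(x)
}

#' Log-scale summary of EC50 values across fits
#'
#' EC50 values are log-normally distributed across animals, so group
#' statistics are computed on log10 EC50; the geometric-mean EC50 is
#' `10^mean(log10 EC50)`.
#'
#' @param fits A list of `sigmoid_fit` objects (a single fit is accepted).
#' @return A list with `log_mean`, `log_sd`, `n` and `geo_mean_ec50` (lux).
#' @export
group_ec50_summary <- function(fits) {
  if (inherits(fits, "sigmoid_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no fits supplied")
  le <- vapply(fits, function(f) {
    stopifnot(inherits(f, "sigmoid_fit")); f$log_ec50
  }, numeric(1))
  list(log_mean = mean(le),
       log_sd = if (length(le) > 1) stats::sd(le) else 0,
       n = length(le),
       geo_mean_ec50 = 10^mean(le))
}
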