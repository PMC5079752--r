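# Model-generated time x intensity pupil matrices and the
# necessity/sufficiency/contribution algebra over them.

#' Default grids for pupil matrices
#'
#' Transient time runs 0-30 s in 1-s steps; sustained 30 s-3600 s in 5-s
#' steps; intensity spans 0.001-100,000 lux in 0.25 log10 steps.
#' @name default_grids
NULL

#' @rdname default_grids
#' @export
default_time_grid <- function(phase = c("transient", "sustained")) {
  switch(match.arg(phase),
         transient = seq(0, 30, by = 1),
         sustained = seq(30, 3600, by = 5))
}

#' @rdname default_grids
#' @export
default_intensity_grid <- function() seq(-3, 5, by = 0.25)

#' Construct a pupil matrix
#'
#' @param values Numeric matrix of relative pupil areas in (0, 1], rows
#'   indexed by `time_s`, columns by `log10_lux`.
#' @param time_s Strictly increasing time grid (s).
#' @param log10_lux Strictly increasing log10-intensity grid.
#' @param genotype Genotype label.
#' @param phase `"transient"` or `"sustained"`.
#' @return An object of class `pupil_matrix`.
#' @export
pupil_matrix <- function(values, time_s, log10_lux, genotype = "wildtype",
                         phase = c("transient", "sustained")) {
  phase <- match.arg(phase)
  values <- as.matrix(values)
  if (is.unsorted(time_s, strictly = TRUE) ||
      is.unsorted(log10_lux, strictly = TRUE))
    stop("grids must be strictly increasing")
  if (nrow(values) != length(time_s) || ncol(values) != length(log10_lux))
    stop("value matrix does not match the grids")
  if (any(values <= 0) || any(values > 1 + 1e-12))
    stop("relative pupil areas must lie in (0, 1]")
  structure(list(genotype = genotype, phase = phase,
                 time_s = as.numeric(time_s),
                 log10_lux = as.numeric(log10_lux),
                 values = pmin(values, 1)),
            class = "pupil_matrix")
}

#' @export
print.pupil_matrix <- function(x, ...) {
  cat(sprintf("Pupil matrix: %s, %s phase, %d times x %d intensities\n",
              x$genotype, x$phase, length(x$time_s), length(x$log10_lux)))
  cat(sprintf("  t in [%g, %g] s, log10 lux in [%g, %g], rpa in [%.3f, %.3f]\n",
              min(x$time_s), max(x$time_s), min(x$log10_lux),
              max(x$log10_lux), min(x$values), max(x$values)))
  invisible(x)
}

.same_grids <- function(a, b) {
  isTRUE(all.equal(a$time_s, b$time_s)) &&
    isTRUE(all.equal(a$log10_lux, b$log10_lux))
}

#' Build a transient-phase pupil matrix from fitted parameters
#'
#' Each cell follows the one-phase association
#' \eqn{Y(t, I) = Plateau(I) + (1 - Plateau(I)) e^{-K_{rapid} t}}: the
#' pupil starts fully open (Y0 = 1) at every intensity and constricts at
#' the single rapid rate toward the intensity-dependent plateau taken from
#' the transient intensity-response fit.
#'
#' @param plateau_curve A [fit_intensity_response()] result for the
#'   transient phase.
#' @param k_rapid Rapid constriction rate (1/s), extracted from the rapid
#'   constriction kinetics at 100 lux.
#' @param time_s,log10_lux Grids (defaults: [default_time_grid()] and
#'   [default_intensity_grid()]).
#' @param genotype Genotype label carried on the matrix.
#' @return A [pupil_matrix()] of phase `"transient"`.
#' @export
build_transient_matrix <- function(plateau_curve, k_rapid,
                                   time_s = default_time_grid("transient"),
                                   log10_lux = default_intensity_grid(),
                                   genotype = "wildtype") {
  stopifnot(inherits(plateau_curve, "sigmoid_fit"))
  if (k_rapid <= 0) stop("k_rapid must be > 0")
  plateau <- predict_rpa(plateau_curve, 10^log10_lux)
  vals <- outer(time_s, seq_along(log10_lux), function(t, j)
    plateau[j] + (1 - plateau[j]) * exp(-k_rapid * t))
  pupil_matrix(vals, time_s, log10_lux, genotype, "transient")
}

#' Build a sustained-phase pupil matrix from fitted parameters
#'
#' The sustained phase starts at 30 s from the transient plateau (Y0 of
#' the sustained association equals the rapid-phase plateau at each
#' intensity) and relaxes toward the sustained plateau at the
#' intensity-dependent decay rate.
#'
#' @param transient_plateau_curve,sustained_plateau_curve
#'   [fit_intensity_response()] results for the two phases.
#' @param k_sust A [fit_decay_rate_vs_intensity()] curve (rates in 1/min).
#' @inheritParams build_transient_matrix
#' @return A [pupil_matrix()] of phase `"sustained"`.
#' @export
build_sustained_matrix <- function(transient_plateau_curve,
                                   sustained_plateau_curve, k_sust,
                                   time_s = default_time_grid("sustained"),
                                   log10_lux = default_intensity_grid(),
                                   genotype = "wildtype") {
  stopifnot(inherits(transient_plateau_curve, "sigmoid_fit"),
            inherits(sustained_plateau_curve, "sigmoid_fit"),
            inherits(k_sust, "decay_rate_curve"))
  if (min(time_s) < 30) stop("sustained phase starts at 30 s")
  I <- 10^log10_lux
  p_t <- predict_rpa(transient_plateau_curve, I)
  p_s <- predict_rpa(sustained_plateau_curve, I)
  k_per_s <- predict(k_sust, I) / 60
  vals <- outer(time_s, seq_along(I), function(t, j)
    p_s[j] + (p_t[j] - p_s[j]) * exp(-k_per_s[j] * (t - 30)))
  pupil_matrix(vals, time_s, log10_lux, genotype, "sustained")
}

#' Cellwise average of pupil matrices
#'
#' Used to pool replicate mutant lines that silence the same photoreceptor
#' in different ways (e.g. two rod-knockout lines) into one component
#' matrix.
#'
#' @param matrices A list of [pupil_matrix()] objects on identical grids.
#' @param genotype Label for the averaged matrix.
#' @return A `pupil_matrix`.
#' @export
average_matrices <- function(matrices, genotype = "average") {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "pupil_matrix"))
    if (!.same_grids(ref, m)) stop("matrices are on different grids")
  }
  vals <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  pupil_matrix(vals, ref$time_s, ref$log10_lux, genotype, ref$phase)
}

.contribution_map <- function(values, ref, component, kind,
                              necessity_only = FALSE) {
  structure(list(component = component, kind = kind,
                 time_s = ref$time_s, log10_lux = ref$log10_lux,
                 values = pmin(pmax(values, 0), 1),
                 necessity_only = necessity_only),
            class = "contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf("%s map for %s: %d times x %d intensities, values in [%.3f, %.3f]\n",
              x$kind, x$component, length(x$time_s),
              length(x$log10_lux), min(x$values), max(x$values)))
  invisible(x)
}

#' Necessity map of a component
#'
#' How much constriction is lost when the component is knocked out:
#' `rpa_ko - rpa_wt` (equivalently wild-type constriction minus knockout
#' constriction), clamped to [0, 1]. Larger values mean the component is
#' more required at that time and intensity; because the difference is
#' taken against the wild-type response, a component that is fully
#' necessary at an intensity where wild type barely constricts still gets
#' a small value.
#'
#' @param wt Wild-type [pupil_matrix()].
#' @param ko Knockout `pupil_matrix` on the same grids.
#' @param component Component label (defaults to the knockout genotype).
#' @return A `contribution_map` of kind `"necessity"`.
#' @export
necessity_map <- function(wt, ko, component = ko$genotype) {
  stopifnot(inherits(wt, "pupil_matrix"), inherits(ko, "pupil_matrix"))
  if (!.same_grids(wt, ko)) stop("matrices are on different grids")
  .contribution_map(ko$values - wt$values, wt, component, "necessity")
}

#' Sufficiency map of a component
#'
#' The constriction achieved when only this component is functional
#' (an "-only" mutant line): `1 - rpa_only`, clamped to [0, 1].
#'
#' @param only_line [pupil_matrix()] of the corresponding "-only" genotype.
#' @param component Component label.
#' @return A `contribution_map` of kind `"sufficiency"`.
#' @export
sufficiency_map <- function(only_line, component = only_line$genotype) {
  stopifnot(inherits(only_line, "pupil_matrix"))
  .contribution_map(1 - only_line$values, only_line, component, "sufficiency")
}

#' Contribution map: cellwise max of necessity and sufficiency
#'
#' A component contributes wherever it is either required (necessity) or
#' able to drive the response on its own (sufficiency). For panels where
#' no "-only" line exists (the neurotransmitter knockouts), pass `s = NULL`
#' and the contribution is the necessity map alone, flagged
#' `necessity_only`.
#'
#' @param n Necessity `contribution_map`.
#' @param s Sufficiency `contribution_map` for the same component (or NULL).
#' @return A `contribution_map` of kind `"contribution"`.
#' @export
contribution_map <- function(n, s = NULL) {
  stopifnot(inherits(n, "contribution_map"), n$kind == "necessity")
  if (is.null(s))
    return(.contribution_map(n$values, n, n$component, "contribution",
                             necessity_only = TRUE))
  stopifnot(inherits(s, "contribution_map"), s$kind == "sufficiency")
  if (!identical(n$component, s$component))
    stop("necessity and sufficiency maps are for different components")
  if (!.same_grids(n, s)) stop("maps are on different grids")
  .contribution_map(pmax(n$values, s$values), n, n$component, "contribution")
}

#' Apply the cone-only decay adjustment
#'
#' Cone-driven constriction is not maintained: the cone-only line's
#' transient response decays within the 30-s window. To impose this on a
#' model matrix, the constriction depth after each intensity row's maximum
#' constriction (minimum rpa) is relaxed toward a fully open pupil with a
#' single rate taken from the cone-only transient response at 100 lux,
#' applied at every intensity:
#' `depth(t) -> depth(t) * exp(-rate * (t - t_min))` for `t > t_min`.
#'
#' @param cone_matrix A [pupil_matrix()].
#' @param cone_only_decay_rate Relaxation rate (1/s), > 0 (a rate of 0 in
#'   the limit leaves the matrix unchanged).
#' @param t_start Optional fixed start time (s) for the relaxation; by
#'   default each intensity uses its own time of maximum constriction.
#' @return The adjusted `pupil_matrix`.
#' @export
apply_cone_decay_adjustment <- function(cone_matrix, cone_only_decay_rate,
                                        t_start = NULL) {
  stopifnot(inherits(cone_matrix, "pupil_matrix"))
  if (cone_only_decay_rate < 0) stop("decay rate must be >= 0")
  t <- cone_matrix$time_s
  vals <- cone_matrix$values
  for (j in seq_len(ncol(vals))) {
    t_min <- if (is.null(t_start)) t[which.min(vals[, j])] else t_start
    after <- t > t_min
    depth <- 1 - vals[after, j]
    vals[after, j] <- 1 - depth * exp(-cone_only_decay_rate * (t[after] - t_min))
  }
  pupil_matrix(vals, t, cone_matrix$log10_lux, cone_matrix$genotype,
               cone_matrix$phase)
}

#' Compose contribution maps into an RGB image grid
#'
#' Each map supplies one color channel (rod red, cone green, melanopsin
#' blue in the photoreceptor panel); channel value is
#' `round(255 * contribution)` and unassigned channels are 0, so black
#' means no contribution.
#'
#' @param maps A list of up to three [contribution_map()] objects on
#'   identical grids.
#' @param channels Character vector assigning each map to `"red"`,
#'   `"green"` or `"blue"`; channels must be distinct.
#' @return An integer array `[time, intensity, 3]` of 0-255 channel
#'   values, with the grids attached as attributes.
#' @export
compose_rgb <- function(maps,
                        channels = c("red", "green", "blue")[seq_along(maps)]) {
  if (inherits(maps, "contribution_map")) maps <- list(maps)
  if (length(maps) < 1 || length(maps) > 3) stop("supply 1 to 3 maps")
  channels <- match.arg(channels, c("red", "green", "blue"),
                        several.ok = TRUE)
  if (length(channels) != length(maps)) stop("one channel per map")
  if (anyDuplicated(channels)) stop("duplicate channel assignment")
  ref <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "contribution_map"))
    if (!.same_grids(ref, m)) stop("maps are on different grids")
  }
  img <- array(0L, dim = c(length(ref$time_s), length(ref$log10_lux), 3))
  idx <- c(red = 1L, green = 2L, blue = 3L)
  for (i in seq_along(maps))
    img[, , idx[channels[i]]] <- as.integer(round(255 * maps[[i]]$values))
  attr(img, "time_s") <- ref$time_s
  attr(img, "log10_lux") <- ref$log10_lux
  img
}

#' Write an RGB composite to a PNG file
#'
#' Rows of the image are intensities (brightest at the top), columns are
#' time.
#'
#' @param img An array from [compose_rgb()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  # [time, intensity, 3] -> [intensity rows top-down, time cols, 3]
  m <- aperm(img, c(2, 1, 3))
  m <- m[rev(seq_len(dim(m)[1])), , , drop = FALSE]
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Export a pupil matrix or contribution map as a data frame
#'
#' @param x A `pupil_matrix` or `contribution_map`.
#' @param ... Unused.
#' @return A long data.frame with columns `time_s`, `log10_lux`, `value`.
#' @export
as.data.frame.pupil_matrix <- function(x, ...) {
  data.frame(time_s = rep(x$time_s, times = length(x$log10_lux)),
             log10_lux = rep(x$log10_lux, each = length(x$time_s)),
             value = as.vector(x$values))
}

#' @rdname as.data.frame.pupil_matrix
#' @export
as.data.frame.contribution_map <- function(x, ...) {
  data.frame(time_s = rep(x$time_s, times = length(x$log10_lux)),
             log10_lux = rep(x$log10_lux, each = length(x$time_s)),
             value = as.vector(x$values))
}
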