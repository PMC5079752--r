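#' Construct a pupil trace
#'
#' A `pupil_trace` holds the raw pupil-area time series for one mouse at one
#' stimulus intensity. Times are seconds relative to light onset (onset is
#' time 0); negative times are dark-baseline samples taken before the light
#' steps on.
#'
#' @param mouse_id Identifier for the animal.
#' @param genotype Genotype label.
#' @param intensity Stimulus illuminance in lux (>= 0).
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, with at least one time < 0 (the dark baseline).
#' @param areas Numeric vector of pupil areas (pixels or mm^2), all > 0,
#'   same length as `times`.
#' @return An object of class `pupil_trace`.
#' @seealso [relative_trace()], [read_trace_table()]
#' @export
pupil_trace <- function(mouse_id, genotype, intensity, times, areas) {
  times <- as.numeric(times)
  areas <- as.numeric(areas)
  if (length(times) != length(areas))
    stop("`times` and `areas` must have the same length")
  if (any(!is.finite(times)) || any(!is.finite(areas)))
    stop("`times` and `areas` must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (!any(times < 0))
    stop("a pupil trace needs at least one baseline sample (time < 0)")
  if (any(areas <= 0))
    stop("all pupil areas must be > 0 (first offending index: ",
         which(areas <= 0)[1], ")")
  if (!is.numeric(intensity) || length(intensity) != 1 || intensity < 0)
    stop("`intensity` must be a single illuminance >= 0 (lux)")
  structure(
    list(mouse_id = as.character(mouse_id),
         genotype = as.character(genotype),
         intensity = as.numeric(intensity),
         times = times, areas = areas),
    class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: mouse %s (%s) at %g lux\n",
              x$mouse_id, x$genotype, x$intensity))
  cat(sprintf("  %d samples, t in [%g, %g] s (%d baseline)\n",
              length(x$times), min(x$times), max(x$times),
              sum(x$times < 0)))
  invisible(x)
}

#' Read a table of pupil traces
#'
#' Reads a CSV of pupil-area measurements and splits it into one
#' [pupil_trace()] per (mouse, intensity) combination. The expected columns
#' are `mouse_id`, `genotype`, `intensity_lux`, `time_s`, `pupil_area`;
#' other namings can be mapped through `schema`.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the canonical column names
#'   to the columns present in the file, e.g.
#'   `c(time_s = "t", pupil_area = "area")`. Unmapped canonical names are
#'   looked up verbatim.
#' @return A list of `pupil_trace` objects, times sorted within each trace.
#' @export
read_trace_table <- function(path, schema = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("mouse_id", "genotype", "intensity_lux", "time_s", "pupil_area")
  cols <- stats::setNames(canonical, canonical)
  cols[names(schema)] <- schema
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  d <- data.frame(
    mouse_id = as.character(tab[[cols["mouse_id"]]]),
    genotype = as.character(tab[[cols["genotype"]]]),
    intensity = as.numeric(tab[[cols["intensity_lux"]]]),
    time = as.numeric(tab[[cols["time_s"]]]),
    area = as.numeric(tab[[cols["pupil_area"]]]),
    stringsAsFactors = FALSE)
  if (any(!is.finite(d$time)) || any(!is.finite(d$area)))
    stop("non-numeric time or area values in ", path)
  bad <- which(d$area <= 0)
  if (length(bad))
    stop("non-positive pupil area at data row ", bad[1])
  key <- interaction(d$mouse_id, d$intensity, drop = TRUE)
  traces <- lapply(split(d, key), function(g) {
    g <- g[order(g$time), , drop = FALSE]
    pupil_trace(g$mouse_id[1], g$genotype[1], g$intensity[1], g$time, g$area)
  })
  names(traces) <- NULL
  traces
}

#' Write relative traces to CSV
#'
#' @param rels A list of `relative_trace` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_relative_table <- function(rels, path) {
  if (inherits(rels, "relative_trace")) rels <- list(rels)
  rows <- do.call(rbind, lapply(rels, function(r)
    data.frame(mouse_id = r$mouse_id, genotype = r$genotype,
               intensity_lux = r$intensity, time_s = r$times, rpa = r$rpa,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Convert a raw trace to relative pupil area
#'
#' Relative pupil area (RPA) is the area during the stimulus divided by the
#' dark-baseline area; 1 means fully open. The baseline is the mean area
#' over all pre-onset samples (times < 0), which reduces to a single
#' pre-onset frame when only one is available.
#'
#' @param trace A [pupil_trace()].
#' @return An object of class `relative_trace` with fields `times` and
#'   `rpa`, the mean RPA over baseline times being 1 by construction.
#' @export
relative_trace <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  base_idx <- trace$times < 0
  if (!any(base_idx))
    stop("no baseline sample (time < 0) to normalize against")
  baseline <- mean(trace$areas[base_idx])
  structure(
    list(mouse_id = trace$mouse_id, genotype = trace$genotype,
         intensity = trace$intensity, times = trace$times,
         rpa = trace$areas / baseline),
    class = "relative_trace")
}

#' @export
print.relative_trace <- function(x, ...) {
  cat(sprintf("Relative pupil trace: mouse %s (%s) at %g lux\n",
              x$mouse_id, x$genotype, x$intensity))
  cat(sprintf("  %d samples, min RPA %.3f\n", length(x$times), min(x$rpa)))
  invisible(x)
}

#' Bare relative-trace constructor
#'
#' Builds a `relative_trace` directly from RPA values, for model-generated
#' or already-normalized series (pulse-chase profiles, simulator output).
#'
#' @inheritParams pupil_trace
#' @param rpa Relative pupil area values (> 0).
#' @return A `relative_trace`.
#' @export
as_relative_trace <- function(times, rpa, mouse_id = "model",
                              genotype = "model", intensity = NA_real_) {
  times <- as.numeric(times); rpa <- as.numeric(rpa)
  if (length(times) != length(rpa)) stop("length mismatch")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (any(rpa <= 0)) stop("rpa must be > 0")
  structure(list(mouse_id = mouse_id, genotype = genotype,
                 intensity = intensity, times = times, rpa = rpa),
            class = "relative_trace")
}

#' Transient-phase endpoint of a relative trace
#'
#' The transient PLR endpoint is the minimum relative pupil size at either
#' 5 s or 30 s after stimulus onset. Samples are matched to those time
#' points by nearest neighbour within `tol` seconds (video frames are not
#' perfectly regular).
#'
#' @param rel A [relative_trace()].
#' @param at Time points (s) whose minimum RPA is taken. Default `c(5, 30)`.
#' @param tol Matching tolerance in seconds.
#' @return The endpoint RPA (a single number).
#' @export
transient_endpoint <- function(rel, at = c(5, 30), tol = 0.5) {
  stopifnot(inherits(rel, "relative_trace"))
  vals <- vapply(at, function(t0) {
    i <- which.min(abs(rel$times - t0))
    if (abs(rel$times[i] - t0) > tol) NA_real_ else rel$rpa[i]
  }, numeric(1))
  if (all(is.na(vals)))
    stop("no sample within ", tol, " s of any of t = ",
         paste(at, collapse = ", "), " s")
  min(vals, na.rm = TRUE)
}
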