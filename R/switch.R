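#' Mean of a time series after an equilibration discard
#'
#' @param ts numeric vector, or a data.frame with a value column (the last
#'   column of the `*_series` outputs).
#' @param discard_fraction fraction of initial frames to drop, in [0, 1);
#'   default 0 (average over the full trajectory).
#' @return arithmetic mean of the retained values.
#' @export
series_mean <- function(ts, discard_fraction = 0) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  v <- if (is.data.frame(ts)) ts[[ncol(ts)]] else as.numeric(ts)
  drop_n <- floor(length(v) * discard_fraction)
  v <- v[seq_len(length(v)) > drop_n]
  if (!length(v)) stop("no frames left after equilibration discard")
  mean(v)
}

#' Delta of a simulation mean against the crystal baseline
#'
#' `signed` returns sim_mean - crystal_value. `magnitude_decrease` returns
#' |crystal_value| - |sim_mean| (positive when the quantity's magnitude
#' shrank relative to the crystal); the two conventions diverge when the
#' sign of the quantity itself flips.
#'
#' @param sim_mean per-simulation mean (e.g. from [series_mean()]).
#' @param crystal_value baseline computed from the crystal structure.
#' @param convention "signed" (default) or "magnitude_decrease".
#' @return the delta, same units as the inputs.
#' @export
delta_vs_crystal <- function(sim_mean, crystal_value,
                             convention = c("signed", "magnitude_decrease")) {
  convention <- match.arg(convention)
  if (convention == "signed") sim_mean - crystal_value
  else abs(crystal_value) - abs(sim_mean)
}

#' Assemble per-simulation switch points
#'
#' @param sim_id character vector of simulation labels.
#' @param delta_x structural deltas (Angstrom for distances, degrees for
#'   angles; sim mean minus crystal under the active convention).
#' @param delta_E coupling deltas (cm^-1).
#' @return data.frame of class `switch_points` with columns `sim_id`,
#'   `delta_x`, `delta_E`.
#' @export
switch_points <- function(sim_id, delta_x, delta_E) {
  stopifnot(length(sim_id) == length(delta_x),
            length(delta_x) == length(delta_E),
            all(is.finite(delta_x)), all(is.finite(delta_E)))
  out <- data.frame(sim_id = as.character(sim_id), delta_x = delta_x,
                    delta_E = delta_E, stringsAsFactors = FALSE)
  class(out) <- c("switch_points", "data.frame")
  out
}

#' Read switch points from a CSV file
#'
#' Expects columns `sim_id`, `delta_x`, `delta_E` (extra columns ignored),
#' e.g. per-simulation delta tables transcribed from supplementary material.
#'
#' @param path CSV file path.
#' @return a [switch_points()] data.frame.
#' @export
read_switch_points <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sim_id", "delta_x", "delta_E")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("switch-point CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  switch_points(d$sim_id, d$delta_x, d$delta_E)
}

#' Ensemble Pearson correlation of structural vs coupling deltas
#'
#' Fits the per-simulation (delta_x, delta_E) cloud with a least-squares
#' line and reports the Pearson coefficient. The crystal reference point
#' (0, 0) is included by default since deltas are defined against it.
#' Duplicate points are permitted.
#'
#' @param points a [switch_points()] data.frame.
#' @param include_crystal_origin add the (0, 0) crystal point (default TRUE).
#' @return object of class `EnsembleCorrelation` with fields `r`, `slope`,
#'   `intercept`, `n_points`, `include_crystal_origin`.
#' @export
ensemble_pearson <- function(points, include_crystal_origin = TRUE) {
  x <- points$delta_x; y <- points$delta_E
  if (include_crystal_origin) {
    x <- c(x, 0); y <- c(y, 0)
  }
  if (length(x) < 3L) stop("need at least 3 points for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one coordinate; Pearson r undefined")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(r = stats::cor(x, y),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_points = length(x),
                 include_crystal_origin = include_crystal_origin),
            class = "EnsembleCorrelation")
}

#' @export
print.EnsembleCorrelation <- function(x, ...) {
  cat(sprintf(
    "<EnsembleCorrelation> r = %.3f over %d points%s\n  fit: delta_E = %.4g * delta_x %+.4g\n",
    x$r, x$n_points,
    if (x$include_crystal_origin) " (crystal origin included)" else "",
    x$slope, x$intercept))
  invisible(x)
}

#' @export
coef.EnsembleCorrelation <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Within-trajectory synchronization scan
#'
#' Pairs two time-aligned series frame by frame and reports their Pearson
#' correlation for one trajectory - used to test whether two events (e.g.
#' a carotenoid tilt change and a coupling change) are synchronized within
#' a simulation. Results are per trajectory and must never be pooled across
#' simulations.
#'
#' @param ts_x,ts_y numeric vectors or `*_series` data.frames with the same
#'   frame count.
#' @return list with `r` (Pearson) and `data` (data.frame `x`, `y`).
#' @export
synchronization_scan <- function(ts_x, ts_y) {
  x <- if (is.data.frame(ts_x)) ts_x[[ncol(ts_x)]] else as.numeric(ts_x)
  y <- if (is.data.frame(ts_y)) ts_y[[ncol(ts_y)]] else as.numeric(ts_y)
  if (length(x) != length(y)) {
    stop("series are not time-aligned: lengths differ")
  }
  list(r = stats::cor(x, y), data = data.frame(x = x, y = y))
}

#' Build a machine-readable analysis report
#'
#' Collects per-simulation means, deltas, correlations and the parameters
#' used into one deterministic record; two runs on identical inputs yield
#' byte-identical JSON.
#'
#' @param config named list of analysis parameters (registry values,
#'   cutoffs, conventions).
#' @param results named non-empty list of analysis outputs (series means,
#'   switch points, `EnsembleCorrelation`s, ...).
#' @return list of class `lhc_report`.
#' @export
build_report <- function(config, results) {
  if (!length(results)) stop("no analysis results to report")
  structure(list(
    package = "lhcswitch",
    version = as.character(utils::packageVersion("lhcswitch")),
    config = config,
    results = lapply(results, function(r) {
      if (inherits(r, "EnsembleCorrelation")) unclass(r) else r
    })
  ), class = "lhc_report")
}

#' Write a report as JSON
#'
#' @param report an `lhc_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
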