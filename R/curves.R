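# Background correction, threshold-crossing times and doubling-time
# estimation from single outgrowth curves.

# Corrected ODs are floored at this value so log2 stays finite.
OD_EPS <- 1e-4

#' Curve-analysis parameters
#'
#' Thresholds governing doubling-time and time-shift estimation, all on the
#' background-corrected OD scale.
#'
#' @param od_min,od_max Lower and upper OD bounds for the steepest-slope
#'   (inflection) doubling-time search. Defaults 0.2 and 0.5, inside the
#'   instrument's reliable linear range.
#' @param dt_interval_min,dt_interval_max OD bounds for the interval
#'   doubling-time method; default to `od_min`/`od_max`.
#' @param timeshift_od OD level at which time shifts between age-points are
#'   measured (default 0.3).
#' @param dt_method Which estimator feeds the survival computation:
#'   `"interval"` (default; exact for exponentials and robust to
#'   single-sample noise) or `"inflection"`.
#' @param correction Length-2 numeric `c(a, b)`: corrected doubling time is
#'   `a * delta + b` hours. The default `c(1, 0)` is a documented no-op;
#'   supply coefficients from your own instrument calibration to use it.
#' @return An object of class `curve_params`.
#' @export
curve_params <- function(od_min = 0.2, od_max = 0.5,
                         dt_interval_min = od_min,
                         dt_interval_max = od_max,
                         timeshift_od = 0.3,
                         dt_method = c("interval", "inflection"),
                         correction = c(1, 0)) {
  dt_method <- match.arg(dt_method)
  if (!(od_min > 0 && od_max > od_min))
    stop("need 0 < od_min < od_max", call. = FALSE)
  if (!(dt_interval_min > 0 && dt_interval_max > dt_interval_min))
    stop("need 0 < dt_interval_min < dt_interval_max", call. = FALSE)
  if (!(timeshift_od > 0))
    stop("timeshift_od must be positive", call. = FALSE)
  if (length(correction) != 2L || any(!is.finite(correction)))
    stop("correction must be two finite numbers c(a, b)", call. = FALSE)
  structure(list(od_min = od_min, od_max = od_max,
                 dt_interval_min = dt_interval_min,
                 dt_interval_max = dt_interval_max,
                 timeshift_od = timeshift_od,
                 dt_method = dt_method,
                 correction = as.numeric(correction)),
            class = "curve_params")
}

#' Background-corrected OD curve
#'
#' Subtracts the background from raw readings and floors the result at a
#' small positive epsilon (1e-4) so logarithmic operations stay finite for
#' blank or dead wells.
#'
#' @param times Elapsed hours, strictly increasing.
#' @param od_raw Raw OD readings, same length as `times`.
#' @param background Background OD to subtract.
#' @return An object of class `od_curve` with elements `times`, `od_raw`,
#'   `background`, `od_corr`.
#' @export
od_curve <- function(times, od_raw, background = 0) {
  times <- as.numeric(times); od_raw <- as.numeric(od_raw)
  if (length(times) != length(od_raw))
    stop("times and od_raw must have the same length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, od_raw = od_raw,
                 background = as.numeric(background),
                 od_corr = pmax(od_raw - as.numeric(background), OD_EPS)),
            class = "od_curve")
}

#' Extract one well's corrected curve from an outgrowth run
#'
#' @param run An [outgrowth_run()].
#' @param position 1-based well column index.
#' @return An [od_curve()].
#' @export
well_curve <- function(run, position) {
  stopifnot(inherits(run, "outgrowth_run"))
  if (position < 1L || position > ncol(run$table$wells))
    stop(sprintf("well position %d outside 1-%d", position,
                 ncol(run$table$wells)), call. = FALSE)
  od_curve(run$table$times, run$table$wells[, position], run$background)
}

#' Time at which a curve first reaches an OD level
#'
#' Finds the earliest time the corrected OD reaches `level`, interpolating
#' linearly in (time, log2 OD) between the bracketing samples — growth is
#' exponential between readings, so log-linear interpolation is the natural
#' rule. A curve already at or above the level at its first sample returns
#' its first time; a curve that never reaches the level returns `NA`
#' (a dead culture or blank, not an error).
#'
#' @param curve An [od_curve()].
#' @param level Corrected-OD level, greater than the flooring epsilon.
#' @return Crossing time in hours, or `NA_real_`.
#' @export
crossing_time <- function(curve, level) {
  stopifnot(inherits(curve, "od_curve"))
  if (!(level > OD_EPS))
    stop("crossing level must exceed the OD flooring epsilon", call. = FALSE)
  od <- curve$od_corr
  if (od[1L] >= level) return(curve$times[1L])
  above <- which(od >= level)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  t0 <- curve$times[i - 1L]; t1 <- curve$times[i]
  y0 <- log2(od[i - 1L]); y1 <- log2(od[i])
  if (y1 <= y0) return(t1)  # degenerate bracket (flat in log); take the sample
  t0 + (log2(level) - y0) / (y1 - y0) * (t1 - t0)
}

#' Doubling time from the steepest log2 slope (inflection method)
#'
#' Over consecutive sample pairs whose corrected ODs both lie within
#' `[od_min, od_max]`, computes the slope of log2(OD) against time and
#' returns the reciprocal of the steepest slope. This targets the fastest
#' (exponential-phase) growth between the thresholds.
#'
#' @param curve An [od_curve()].
#' @param params A [curve_params()].
#' @return Doubling time in hours, or `NA_real_` if no consecutive pair lies
#'   within the thresholds or the steepest slope is not positive.
#' @export
doubling_time_inflection <- function(curve, params = curve_params()) {
  stopifnot(inherits(curve, "od_curve"), inherits(params, "curve_params"))
  od <- curve$od_corr
  inside <- od >= params$od_min & od <= params$od_max
  pair <- which(inside[-length(inside)] & inside[-1L])
  if (length(pair) == 0L) return(NA_real_)
  slopes <- (log2(od[pair + 1L]) - log2(od[pair])) /
    (curve$times[pair + 1L] - curve$times[pair])
  m <- max(slopes)
  if (m <= 0) return(NA_real_)
  1 / m
}

#' Doubling time from interval traversal (interval method)
#'
#' The time to traverse from `dt_interval_min` to `dt_interval_max` divided
#' by the number of doublings that traversal represents,
#' `log2(dt_interval_max / dt_interval_min)`. For a pure exponential this is
#' exact; for noisy data it averages over the whole interval and is less
#' sensitive to single-sample noise than the steepest-slope method.
#'
#' @inheritParams doubling_time_inflection
#' @return Doubling time in hours, or `NA_real_` if either bound is never
#'   reached or the traversal time is not positive.
#' @export
doubling_time_interval <- function(curve, params = curve_params()) {
  stopifnot(inherits(curve, "od_curve"), inherits(params, "curve_params"))
  t_lo <- crossing_time(curve, params$dt_interval_min)
  t_hi <- crossing_time(curve, params$dt_interval_max)
  if (is.na(t_lo) || is.na(t_hi)) return(NA_real_)
  dt <- (t_hi - t_lo) / log2(params$dt_interval_max / params$dt_interval_min)
  if (dt <= 0) return(NA_real_)
  dt
}

#' Doubling time by the configured method
#'
#' @inheritParams doubling_time_inflection
#' @param method Overrides `params$dt_method` when given.
#' @return Doubling time in hours or `NA_real_`.
#' @export
doubling_time <- function(curve, params = curve_params(), method = NULL) {
  method <- if (is.null(method)) params$dt_method else
    match.arg(method, c("interval", "inflection"))
  switch(method,
         interval = doubling_time_interval(curve, params),
         inflection = doubling_time_inflection(curve, params))
}

#' Apply an empirical affine correction to a doubling time
#'
#' `delta' = a * delta + b` with `correction = c(a, b)`. The identity
#' default `c(1, 0)` leaves estimates untouched; coefficients come from the
#' user's own calibration against an independent growth-rate measurement.
#'
#' @param delta Doubling time in hours (finite, positive).
#' @param correction Length-2 numeric `c(a, b)`.
#' @return Corrected doubling time in hours.
#' @export
apply_dt_correction <- function(delta, correction = c(1, 0)) {
  if (length(correction) != 2L || any(!is.finite(correction)))
    stop("correction must be two finite numbers c(a, b)", call. = FALSE)
  if (is.na(delta)) return(NA_real_)
  out <- correction[1L] * delta + correction[2L]
  if (out <= 0)
    stop(sprintf("corrected doubling time %.4g is not positive", out),
         call. = FALSE)
  out
}
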