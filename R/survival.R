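# Time shifts, survival fractions, survival-curve cleaning and survival
# integrals.
#
# The core conversion: after a fixed dilution into fresh medium, the OD a
# culture attains at a fixed time is proportional to the number of viable
# cells inoculated. A culture with half the viable cells reaches any given
# OD one doubling time later, so the rightward time shift dt of an
# outgrowth curve relative to the reference age-point translates into a
# survival fraction
#
#     s_n = (1/2)^(dt_n / delta_n)
#
# where delta_n is the doubling time of the reference (first age-point)
# curve of the same well.

#' Time shift between two outgrowth curves
#'
#' The rightward displacement of `curve_n` relative to `curve_ref`, measured
#' as the difference of their crossing times at a fixed corrected-OD level.
#' Grids need not match. A curve that never reaches the level (a dead
#' culture) yields `NA`; a reference curve that never reaches it is an error
#' — the experiment's baseline outgrowth failed.
#'
#' @param curve_n,curve_ref Background-corrected [od_curve()] objects.
#' @param timeshift_od Corrected-OD level at which the shift is measured.
#' @return Time shift in hours, or `NA_real_` for a dead culture.
#' @export
time_shift <- function(curve_n, curve_ref, timeshift_od = 0.3) {
  t_ref <- crossing_time(curve_ref, timeshift_od)
  if (is.na(t_ref))
    stop(sprintf(
      "reference outgrowth failed: reference curve never reaches OD %.3g",
      timeshift_od), call. = FALSE)
  t_n <- crossing_time(curve_n, timeshift_od)
  if (is.na(t_n)) return(NA_real_)
  t_n - t_ref
}

#' Survival fraction from a time shift and a doubling time
#'
#' `s = (1/2)^(dt / delta)`: each doubling time of delay corresponds to one
#' halving of the viable inoculum. An absent shift (`NA`, dead culture) maps
#' to survival 0 so downstream integrals stay defined. A negative shift
#' (curve earlier than the reference) yields a value above 1; values above 1
#' are retained here and handled by [clean_survival()].
#'
#' @param dt_shift Time shift in hours (may be `NA` for a dead culture).
#' @param delta Doubling time in hours; must be finite and positive.
#' @return Survival fraction (non-negative; can exceed 1 for negative shifts).
#' @export
survival_fraction <- function(dt_shift, delta) {
  if (length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("doubling time must be a single positive number", call. = FALSE)
  ifelse(is.na(dt_shift), 0, 0.5^(dt_shift / delta))
}

#' Clean a survival curve
#'
#' Survival relative to the reference age-point cannot truly rise, yet raw
#' estimates can: measurement noise produces small increases, and "gasping"
#' — regrowth of a few survivors late in life — produces terminal spikes.
#' Cleaning pins the first (reference) age-point at 1 and applies a running
#' minimum capped at 1, which removes both artifacts in one deterministic
#' pass and is idempotent.
#'
#' @param raw Numeric vector of raw survival fractions, first entry the
#'   reference age-point.
#' @return Cleaned survival fractions: first element 1, non-increasing,
#'   within \[0, 1\].
#' @export
clean_survival <- function(raw) {
  if (length(raw) == 0L)
    stop("cannot clean an empty survival curve", call. = FALSE)
  out <- numeric(length(raw))
  out[1L] <- 1
  for (i in seq_along(raw)[-1L]) {
    out[i] <- min(1, raw[i], out[i - 1L])
  }
  out
}

#' Survival integral (area under the survival curve)
#'
#' Trapezoidal integral of survival fractions over age, in day-fraction
#' units. Uneven spacing between age-points is respected, so an experiment
#' sampled on days 2, 4, 6, 9, 11, 13 weighs the 3-day gap accordingly.
#'
#' @param days Strictly increasing age labels (days or treatment ordinals).
#' @param s Survival fractions, same length as `days`.
#' @return The integral, in day-fraction units.
#' @export
survival_integral <- function(days, s) {
  if (length(days) != length(s))
    stop("days and survival fractions must have the same length",
         call. = FALSE)
  if (length(days) < 2L)
    stop("survival integral needs at least 2 age-points", call. = FALSE)
  if (any(diff(days) <= 0))
    stop("age labels must be strictly increasing", call. = FALSE)
  sum(diff(days) * (s[-length(s)] + s[-1L]) / 2)
}

#' Build well lineages across age-points
#'
#' Tracks each sample well position through an ordered series of outgrowth
#' runs: estimates the reference doubling time from the first age-point's
#' curve, measures the time shift of every later age-point at
#' `params$timeshift_od`, converts shifts to survival fractions, optionally
#' cleans the survival curve, and integrates it over age.
#'
#' @param runs List of [outgrowth_run()] objects; sorted by `day` internally.
#'   The earliest day is the reference age-point. All runs must have the
#'   same number of well columns (well position is maintained across
#'   age-points).
#' @param wells A `well_info` data frame; blank wells are skipped. `NULL`
#'   treats every column as its own sample ([default_well_info()]).
#' @param params A [curve_params()].
#' @param clean Apply [clean_survival()] (default `TRUE`).
#' @return An object of class `lineage_set`: a list with
#'   `$wells` (one row per sample well: `position`, `name`, `group`,
#'   `ref_day`, `ref_doubling_time`, `survival_integral`) and
#'   `$ages` (one row per well per age-point: `position`, `name`, `group`,
#'   `day`, `time_shift`, `survival_raw`, `survival_clean`), plus `$days`
#'   and the `params` used.
#' @export
build_lineages <- function(runs, wells = NULL, params = curve_params(),
                           clean = TRUE) {
  if (length(runs) < 2L)
    stop("lineages need at least 2 age-points (runs)", call. = FALSE)
  stopifnot(all(vapply(runs, inherits, TRUE, "outgrowth_run")))
  days <- vapply(runs, `[[`, 0, "day")
  if (anyDuplicated(days))
    stop("day labels must be unique across runs", call. = FALSE)
  runs <- runs[order(days)]
  days <- sort(days)
  n_wells <- ncol(runs[[1L]]$table$wells)
  if (!all(vapply(runs, function(r) ncol(r$table$wells), 0L) == n_wells))
    stop("all runs must have the same well columns in the same order",
         call. = FALSE)
  if (is.null(wells)) wells <- default_well_info(n_wells)
  samples <- wells[wells$role == "sample" & wells$position <= n_wells, ,
                   drop = FALSE]
  if (nrow(samples) == 0L)
    stop("no sample wells to analyze", call. = FALSE)

  ref_run <- runs[[1L]]
  well_rows <- list(); age_rows <- list()
  for (k in seq_len(nrow(samples))) {
    pos <- samples$position[k]
    tag <- sprintf("well %d ('%s')", pos, samples$name[k])
    ref_curve <- well_curve(ref_run, pos)
    delta <- doubling_time(ref_curve, params)
    if (is.na(delta))
      stop(sprintf("%s: doubling-time estimation failed on the reference ",
                   tag), "age-point (day ", days[1L], ")", call. = FALSE)
    delta <- apply_dt_correction(delta, params$correction)
    shifts <- vapply(seq_along(runs), function(i) {
      cv <- well_curve(runs[[i]], pos)
      tryCatch(time_shift(cv, ref_curve, params$timeshift_od),
               error = function(e) stop(sprintf(
                 "%s, day %g: %s", tag, days[i], conditionMessage(e)),
                 call. = FALSE))
    }, 0)
    raw <- survival_fraction(shifts, delta)
    cleaned <- clean_survival(raw)
    used <- if (clean) cleaned else raw
    si <- survival_integral(days, used)
    well_rows[[k]] <- data.frame(
      position = pos, name = samples$name[k], group = samples$group[k],
      ref_day = days[1L], ref_doubling_time = delta,
      survival_integral = si, stringsAsFactors = FALSE)
    age_rows[[k]] <- data.frame(
      position = pos, name = samples$name[k], group = samples$group[k],
      day = days, time_shift = shifts, survival_raw = raw,
      survival_clean = cleaned, stringsAsFactors = FALSE)
  }
  structure(list(wells = do.call(rbind, well_rows),
                 ages = do.call(rbind, age_rows),
                 days = days, params = params, cleaned = clean),
            class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat(sprintf("<lineage_set> %d wells x %d age-points (days %s)\n",
              nrow(x$wells), length(x$days),
              paste(x$days, collapse = ", ")))
  print(utils::head(x$wells, 10))
  invisible(x)
}
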