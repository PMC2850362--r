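# Synthetic outgrowth experiments with known ground truth.
#
# The generative model embodies the assay's core assumption: the OD a
# culture reaches after a fixed period of regrowth is proportional to the
# number of viable cells inoculated. Curves are logistic in base-2
# parameterization, so `doubling_time` is the literal doubling time during
# early exponential growth, and halving the viable inoculum delays the
# whole curve by one doubling time.

#' Specification for a synthetic outgrowth experiment
#'
#' Defaults emulate the standard chronological-aging protocol: a small
#' aliquot of an aging culture diluted into rich medium (inoculum at
#' corrected OD 0.04), read every 30 minutes for 24 hours, with age-points
#' on days 2, 4, 6, 9, 11 and 13 and a wild-type-like doubling time of
#' 1.5 h. OD here is a viable-biomass-equivalent scale, strictly
#' proportional to cell number; the instrument's optical compression of
#' dense cultures is not modeled. The default carrying capacity (200) sits
#' far above the analysis window (corrected OD 0.2-0.5), because real
#' outgrowth in glucose-replete medium is still fully exponential at those
#' densities — a logistic that decelerated inside the window would
#' misrepresent the curves the analysis actually reads. The saturation
#' level itself never enters the analysis, which only reads the curve at
#' ODs up to 0.5.
#'
#' @param doubling_time Doubling time delta in hours.
#' @param carrying_capacity Saturating corrected OD (biomass-equivalent
#'   units) of a full outgrowth.
#' @param inoculum_od Viable-cell-equivalent corrected OD at time 0 for a
#'   fully viable (reference-age) inoculum.
#' @param viability_schedule Data frame or list with `day` and `fraction`
#'   columns: programmed viable fraction at each age-point. The first entry
#'   must have fraction 1 (the reference age-point).
#' @param background Media-only OD added to every reading.
#' @param noise_sd Standard deviation of additive Gaussian OD noise.
#' @param time_step Reading interval in hours.
#' @param duration Total outgrowth time in hours.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(doubling_time = 1.5, carrying_capacity = 200,
                     inoculum_od = 0.04,
                     viability_schedule = data.frame(
                       day = c(2, 4, 6, 9, 11, 13),
                       fraction = c(1, 0.85, 0.6, 0.3, 0.12, 0.04)),
                     background = 0.15, noise_sd = 0.005,
                     time_step = 0.5, duration = 24, seed = 1L) {
  sched <- as.data.frame(viability_schedule)
  if (!all(c("day", "fraction") %in% names(sched)))
    stop("viability_schedule needs 'day' and 'fraction' columns",
         call. = FALSE)
  if (any(sched$fraction < 0 | sched$fraction > 1))
    stop("viable fractions must lie in [0, 1]", call. = FALSE)
  if (any(diff(sched$day) <= 0))
    stop("schedule days must be strictly increasing", call. = FALSE)
  if (sched$fraction[1L] != 1)
    stop("the first (reference) age-point must have viable fraction 1",
         call. = FALSE)
  if (!(inoculum_od > 0 && inoculum_od < carrying_capacity))
    stop("need 0 < inoculum_od < carrying_capacity", call. = FALSE)
  structure(list(doubling_time = doubling_time,
                 carrying_capacity = carrying_capacity,
                 inoculum_od = inoculum_od,
                 viability_schedule = sched,
                 background = background, noise_sd = noise_sd,
                 time_step = time_step, duration = duration,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate one outgrowth curve
#'
#' Raw OD over time for an inoculum carrying `viable_fraction` of the
#' reference viable load:
#' `od_raw(t) = background + K / (1 + (K/x0 - 1) * 2^(-t/delta)) + noise`
#' with `x0 = inoculum_od * viable_fraction`. A fraction of 0 gives a flat
#' background (plus noise) — a dead culture indistinguishable from a blank.
#'
#' @param spec A [sim_spec()].
#' @param viable_fraction Viable fraction in \[0, 1\].
#' @param seed Seed for this curve's noise; defaults to `spec$seed`.
#' @return An [od_curve()] with `spec$background` already recorded as the
#'   background.
#' @export
simulate_curve <- function(spec, viable_fraction = 1, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  if (viable_fraction < 0 || viable_fraction > 1)
    stop("viable_fraction must lie in [0, 1]", call. = FALSE)
  times <- seq(0, spec$duration, by = spec$time_step)
  K <- spec$carrying_capacity
  x0 <- spec$inoculum_od * viable_fraction
  growth <- if (x0 > 0) {
    K / (1 + (K / x0 - 1) * 2^(-times / spec$doubling_time))
  } else rep(0, length(times))
  noise <- if (spec$noise_sd > 0) {
    withr_seed <- .Random.seed_save()
    on.exit(.Random.seed_restore(withr_seed), add = TRUE)
    set.seed(seed)
    stats::rnorm(length(times), sd = spec$noise_sd)
  } else 0
  od_curve(times, spec$background + growth + noise, spec$background)
}

# Save/restore the global RNG state so simulation seeding does not disturb
# a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
}

#' Simulate a full multi-age-point experiment to disk
#'
#' Writes one run CSV per scheduled day in the EZExperiment layout (well
#' order identical across files, one shared media-only blank well last), a
#' well-info CSV, and a ground-truth table of programmed viable fractions
#' and the generative doubling time.
#'
#' @param spec A [sim_spec()]; its `viability_schedule` is the default
#'   schedule for every group.
#' @param out_dir Output directory (created if needed).
#' @param n_replicate_wells Wells per group.
#' @param groups Named list of viability schedules (data frames with `day`,
#'   `fraction`), one per strain/treatment group; all must share the same
#'   days. Default: a single group `"WT"` using `spec$viability_schedule`.
#' @return Invisibly, a list with `run_files` (named by day), `well_info`
#'   path, `truth` path and data frame, and the per-well seeds used.
#' @export
simulate_experiment <- function(spec, out_dir,
                                n_replicate_wells = 3L,
                                groups = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(groups)) groups <- list(WT = spec$viability_schedule)
  if (length(groups) < 1L) stop("need at least one group", call. = FALSE)
  groups <- lapply(groups, as.data.frame)
  days <- groups[[1L]]$day
  for (g in groups) {
    if (!identical(as.numeric(g$day), as.numeric(days)))
      stop("all groups must share the same schedule days", call. = FALSE)
    if (g$fraction[1L] != 1)
      stop("each group's first age-point must have viable fraction 1",
           call. = FALSE)
  }
  n_samples <- length(groups) * n_replicate_wells
  if (n_samples + 1L > MAX_WELLS)
    stop(sprintf("%d wells (plus blank) exceed the %d-well capacity",
                 n_samples, MAX_WELLS), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # plate layout: group replicates in blocks, blank well last
  wi <- data.frame(
    position = seq_len(n_samples + 1L),
    name = c(paste0(rep(names(groups), each = n_replicate_wells), "_",
                    rep(seq_len(n_replicate_wells), length(groups))),
             "blank"),
    group = c(rep(names(groups), each = n_replicate_wells), ""),
    media = "YPD",
    role = c(rep("sample", n_samples), "blank"),
    stringsAsFactors = FALSE)
  well_info_path <- file.path(out_dir, "well_info.csv")
  utils::write.csv(wi, well_info_path, row.names = FALSE, quote = FALSE)

  truth <- list(); run_files <- character(0)
  for (i in seq_along(days)) {
    cols <- list(); nm <- character(0)
    for (gi in seq_along(groups)) {
      frac <- groups[[gi]]$fraction[i]
      for (r in seq_len(n_replicate_wells)) {
        pos <- (gi - 1L) * n_replicate_wells + r
        seed_i <- spec$seed + 1000L * i + pos
        cv <- simulate_curve(spec, frac, seed = seed_i)
        cols[[length(cols) + 1L]] <- cv$od_raw
        nm <- c(nm, wi$name[pos])
        truth[[length(truth) + 1L]] <- data.frame(
          position = pos, name = wi$name[pos], group = names(groups)[gi],
          day = days[i], viable_fraction = frac,
          doubling_time = spec$doubling_time, stringsAsFactors = FALSE)
      }
    }
    blank <- simulate_curve(spec, 0, seed = spec$seed + 1000L * i)
    cols[[length(cols) + 1L]] <- blank$od_raw
    nm <- c(nm, "blank")
    wells <- do.call(cbind, cols)
    colnames(wells) <- nm
    tab <- raw_run_table(blank$times, wells,
                         source_name = sprintf("day%g", days[i]))
    path <- file.path(out_dir, sprintf("day%g.csv", days[i]))
    write_run(tab, path)
    run_files[as.character(days[i])] <- path
  }
  truth <- do.call(rbind, truth)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(run_files = run_files, well_info = well_info_path,
                 truth_file = truth_path, truth = truth, days = days))
}
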