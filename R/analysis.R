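# End-to-end analysis driver: config -> io -> curves -> survival -> stats
# -> export. The YAML config replaces the original web-form workflow; every
# form field (well info, per-file day and background, curve parameters,
# export options) has a config counterpart.

#' Read an experiment configuration
#'
#' The configuration is a YAML file with top-level keys:
#' \describe{
#'   \item{experiment}{Experiment name (optional).}
#'   \item{well_info}{Path to the well-info CSV (optional).}
#'   \item{runs}{List of entries with `file`, `day` and an optional
#'     `background` (`well: NAME` for a named blank well, or
#'     `value: NUMBER`; omitted value means the 0.15 default).}
#'   \item{params}{Any [curve_params()] arguments.}
#'   \item{export}{Any [export_config()] arguments, plus `mode`
#'     (synonym for `output_mode`), `reference` (synonym for
#'     `reference_group`) and `out` (output CSV path).}
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated config list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  if (!is.null(cfg$well_info)) cfg$well_info <- resolve(cfg$well_info)
  if (is.null(cfg$runs) || length(cfg$runs) < 1L)
    stop("config must list at least one run file", call. = FALSE)
  cfg$runs <- lapply(cfg$runs, function(r) {
    if (is.null(r$file) || is.null(r$day))
      stop("each run entry needs 'file' and 'day'", call. = FALSE)
    r$file <- resolve(r$file)
    r
  })
  days <- vapply(cfg$runs, function(r) as.numeric(r$day), 0)
  if (anyDuplicated(days))
    stop("day labels must be unique across runs", call. = FALSE)
  cfg
}

.config_params <- function(cfg) {
  p <- cfg$params
  if (is.null(p)) return(curve_params())
  if (!is.null(p$correction)) p$correction <- as.numeric(p$correction)
  do.call(curve_params, p)
}

.config_export <- function(cfg) {
  e <- cfg$export
  if (is.null(e)) e <- list()
  out_path <- e$out
  e$out <- NULL
  if (!is.null(e$mode)) { e$output_mode <- e$mode; e$mode <- NULL }
  if (!is.null(e$reference)) {
    e$reference_group <- e$reference; e$reference <- NULL
  }
  list(cfg = do.call(export_config, e), out = out_path)
}

#' Run a full outgrowth analysis from a configuration
#'
#' Loads every run file, computes and logs each run's background, builds
#' the requested runs or lineages table, and writes it to CSV when an
#' output path is configured. Progress and per-run backgrounds go to
#' `message()` (stderr); wells that die or fail doubling-time estimation
#' are reported there too.
#'
#' @param config Path to a YAML config file, or an equivalent list (as
#'   returned by [read_experiment_config()]).
#' @return Invisibly, a list with the result `table`, the `runs` list, the
#'   `lineages` (`NULL` in runs mode), and the output `path` (`NULL` if not
#'   written).
#' @export
run_analysis <- function(config) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  wells <- if (!is.null(cfg$well_info)) parse_well_info(cfg$well_info)
  else NULL
  params <- .config_params(cfg)
  exp_cfg <- .config_export(cfg)

  runs <- lapply(cfg$runs, function(r) {
    table <- parse_run(r$file)
    bg_spec <- r$background
    bg <- if (!is.null(bg_spec$well)) {
      compute_background(table, wells, blank_well = bg_spec$well)
    } else {
      compute_background(table, value = bg_spec$value)
    }
    message(sprintf("run '%s' (day %s): background %.4f (%s)",
                    table$source_name, r$day, as.numeric(bg),
                    attr(bg, "source")))
    outgrowth_run(table, as.numeric(r$day), bg)
  })

  if (exp_cfg$cfg$output_mode == "runs") {
    table <- export_runs(runs, wells, params, exp_cfg$cfg)
    lineages <- NULL
  } else {
    lineages <- build_lineages(runs, wells, params,
                               clean = exp_cfg$cfg$clean)
    dead <- lineages$ages[is.na(lineages$ages$time_shift), , drop = FALSE]
    if (nrow(dead) > 0L)
      for (i in seq_len(nrow(dead)))
        message(sprintf(
          "well %d ('%s'), day %g: no outgrowth (scored survival 0)",
          dead$position[i], dead$name[i], dead$day[i]))
    table <- export_lineages(lineages, exp_cfg$cfg)
  }

  path <- exp_cfg$out
  if (!is.null(path)) {
    write_export(table, path)
    message(sprintf("wrote %d rows to %s", nrow(table), path))
  }
  invisible(list(table = table, runs = runs, lineages = lineages,
                 path = path))
}
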