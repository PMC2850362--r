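# Result tables: "runs" (per well x run) and "lineages" (per well across
# age-points), with grouping and reference comparisons.

#' Export configuration
#'
#' @param output_mode `"runs"` (one row per well per run: doubling times,
#'   optionally OD readings) or `"lineages"` (one row per well — or per
#'   group — across age-points: survival curve, survival integral).
#' @param grouping `"none"`, `"average"` or `"median"`.
#' @param reference_group Group name for comparison columns, or `NULL`.
#' @param append_ods Append per-time-point OD columns to a runs export.
#' @param subtract_background Background-subtract appended ODs.
#' @param dt_inflection,dt_interval Include the respective doubling-time
#'   columns in a runs export.
#' @param dt_correction Apply the affine correction from the curve
#'   parameters to exported doubling times.
#' @param survival,survival_area,show_time_shifts Include survival
#'   fractions, the survival integral, and time-shift columns in a
#'   lineages export.
#' @param clean Export cleaned survival fractions (monotone non-increasing,
#'   reference pinned at 1) rather than raw ones.
#' @param pct_change,log2_ratio,t_test Comparison columns versus
#'   `reference_group` on survival integrals. A t-test needs replicate
#'   groups, so it requires `grouping != "none"`.
#' @param selected_wells Integer well positions to keep, or `NULL` for all.
#' @param selected_runs Day labels to keep, or `NULL` for all.
#' @return An object of class `export_config`.
#' @export
export_config <- function(output_mode = c("lineages", "runs"),
                          grouping = c("none", "average", "median"),
                          reference_group = NULL,
                          append_ods = FALSE, subtract_background = TRUE,
                          dt_inflection = FALSE, dt_interval = TRUE,
                          dt_correction = FALSE,
                          survival = TRUE, survival_area = TRUE,
                          clean = TRUE, show_time_shifts = FALSE,
                          pct_change = FALSE, log2_ratio = FALSE,
                          t_test = FALSE,
                          selected_wells = NULL, selected_runs = NULL) {
  output_mode <- match.arg(output_mode)
  grouping <- match.arg(grouping)
  if (t_test && grouping == "none")
    stop("t-test versus reference requires a grouping option ",
         "('average' or 'median') to be selected", call. = FALSE)
  if ((pct_change || log2_ratio || t_test) && is.null(reference_group))
    stop("comparison columns require a reference_group", call. = FALSE)
  structure(list(output_mode = output_mode, grouping = grouping,
                 reference_group = reference_group,
                 append_ods = append_ods,
                 subtract_background = subtract_background,
                 dt_inflection = dt_inflection, dt_interval = dt_interval,
                 dt_correction = dt_correction,
                 survival = survival, survival_area = survival_area,
                 clean = clean, show_time_shifts = show_time_shifts,
                 pct_change = pct_change, log2_ratio = log2_ratio,
                 t_test = t_test,
                 selected_wells = selected_wells,
                 selected_runs = selected_runs),
            class = "export_config")
}

.filter_wells <- function(wells, cfg) {
  if (!is.null(cfg$selected_wells))
    wells <- wells[wells$position %in% cfg$selected_wells, , drop = FALSE]
  wells
}

#' Build the runs table
#'
#' One row per (sample well, run): well name, run name, day and the
#' configured doubling-time columns, with OD readings appended when
#' requested.
#'
#' @param runs List of [outgrowth_run()] objects.
#' @param wells A `well_info` data frame, or `NULL` for positional defaults.
#' @param params A [curve_params()].
#' @param cfg An [export_config()] with `output_mode = "runs"`.
#' @return A data frame.
#' @export
export_runs <- function(runs, wells = NULL, params = curve_params(),
                        cfg = export_config("runs")) {
  stopifnot(inherits(cfg, "export_config"))
  if (cfg$output_mode != "runs")
    stop("export_runs requires output_mode 'runs'", call. = FALSE)
  stopifnot(all(vapply(runs, inherits, TRUE, "outgrowth_run")))
  if (!is.null(cfg$selected_runs))
    runs <- Filter(function(r) r$day %in% cfg$selected_runs, runs)
  if (length(runs) == 0L)
    stop("empty run selection", call. = FALSE)
  n_wells <- ncol(runs[[1L]]$table$wells)
  if (is.null(wells)) wells <- default_well_info(n_wells)
  samples <- .filter_wells(wells[wells$role == "sample" &
                                   wells$position <= n_wells, , drop = FALSE],
                           cfg)
  if (nrow(samples) == 0L)
    stop("empty well selection", call. = FALSE)

  rows <- list()
  for (run in runs) {
    for (k in seq_len(nrow(samples))) {
      pos <- samples$position[k]
      cv <- well_curve(run, pos)
      row <- data.frame(well_position = pos, well_name = samples$name[k],
                        group = samples$group[k], media = samples$media[k],
                        run_name = run$table$source_name, day = run$day,
                        background = run$background,
                        stringsAsFactors = FALSE)
      corr <- if (cfg$dt_correction) params$correction else c(1, 0)
      if (cfg$dt_inflection) {
        dt <- doubling_time_inflection(cv, params)
        row$dt_inflection <- if (is.na(dt)) NA_real_ else
          apply_dt_correction(dt, corr)
      }
      if (cfg$dt_interval) {
        dt <- doubling_time_interval(cv, params)
        row$dt_interval <- if (is.na(dt)) NA_real_ else
          apply_dt_correction(dt, corr)
      }
      if (cfg$append_ods) {
        od <- if (cfg$subtract_background) cv$od_corr else cv$od_raw
        od_cols <- as.data.frame(as.list(od))
        names(od_cols) <- paste0("od_", format_time(cv$times))
        row <- cbind(row, od_cols)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the lineages table
#'
#' With `grouping = "none"`, one row per sample well: reference doubling
#' time, survival at each age-point, optional time shifts, and the survival
#' integral. With `"average"`/`"median"`, one row per replicate group with
#' spread columns and optional comparisons versus a reference group.
#'
#' @param lineages A `lineage_set` from [build_lineages()].
#' @param cfg An [export_config()] with `output_mode = "lineages"`.
#' @return A data frame.
#' @export
export_lineages <- function(lineages, cfg = export_config("lineages")) {
  stopifnot(inherits(lineages, "lineage_set"), inherits(cfg, "export_config"))
  if (cfg$output_mode != "lineages")
    stop("export_lineages requires output_mode 'lineages'", call. = FALSE)
  wells <- .filter_wells(lineages$wells, cfg)
  if (nrow(wells) == 0L)
    stop("empty well selection", call. = FALSE)
  ages <- lineages$ages[lineages$ages$position %in% wells$position, ,
                        drop = FALSE]
  days <- lineages$days
  surv_col <- if (cfg$clean) "survival_clean" else "survival_raw"

  if (cfg$grouping == "none") {
    if (cfg$t_test)
      stop("t-test versus reference requires a grouping option to be ",
           "selected", call. = FALSE)
    rows <- lapply(seq_len(nrow(wells)), function(k) {
      w <- wells[k, , drop = FALSE]
      a <- ages[ages$position == w$position, , drop = FALSE]
      a <- a[order(a$day), , drop = FALSE]
      out <- data.frame(well_position = w$position, well_name = w$name,
                        group = w$group,
                        doubling_time = w$ref_doubling_time,
                        stringsAsFactors = FALSE)
      if (cfg$show_time_shifts)
        for (i in seq_along(days))
          out[[paste0("time_shift_day_", days[i])]] <- a$time_shift[i]
      if (cfg$survival)
        for (i in seq_along(days))
          out[[paste0("survival_day_", days[i])]] <- a[[surv_col]][i]
      if (cfg$survival_area) out$survival_integral <- w$survival_integral
      if (cfg$pct_change || cfg$log2_ratio) {
        ref <- lineages$wells[lineages$wells$group == cfg$reference_group, ]
        if (nrow(ref) == 0L)
          stop(sprintf("reference group '%s' not found", cfg$reference_group),
               call. = FALSE)
        ref_center <- mean(ref$survival_integral)
        if (cfg$pct_change)
          out$pct_change <- pct_change(w$survival_integral, ref_center)
        if (cfg$log2_ratio)
          out$log2_ratio <- log2_ratio(w$survival_integral, ref_center)
      }
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  # grouped export
  filtered <- lineages
  filtered$wells <- wells
  filtered$ages <- ages
  mode <- cfg$grouping
  ref <- if (cfg$pct_change || cfg$log2_ratio || cfg$t_test)
    cfg$reference_group else NULL
  res <- summarize_lineages(filtered, mode = mode, reference_group = ref,
                            use_clean = cfg$clean)
  drop <- character(0)
  if (!cfg$survival)
    drop <- c(drop, grep("^survival_day_", names(res), value = TRUE))
  if (!cfg$survival_area)
    drop <- c(drop, "survival_integral", "survival_integral_sd")
  if (!cfg$pct_change) drop <- c(drop, "pct_change")
  if (!cfg$log2_ratio) drop <- c(drop, "log2_ratio")
  if (!cfg$t_test) drop <- c(drop, "t_stat", "p_value")
  res[, setdiff(names(res), drop), drop = FALSE]
}

#' Write an export table to CSV
#'
#' UTF-8 CSV with reals printed to 6 decimals; column order is stable
#' across versions for scriptability.
#'
#' @param table A data frame from [export_runs()] or [export_lineages()].
#' @param path Output path.
#' @export
write_export <- function(table, path) {
  fmt <- table
  num <- vapply(fmt, is.numeric, TRUE) &
    !vapply(fmt, is.integer, TRUE)
  for (j in which(num)) {
    v <- fmt[[j]]
    fmt[[j]] <- ifelse(is.na(v), "", formatC(v, digits = 6, format = "f"))
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
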