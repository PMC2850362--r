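# Replicate grouping and comparisons against an experiment-matched
# reference group.

#' Center and spread of a replicate group
#'
#' @param values Numeric vector of member values (e.g. survival integrals or
#'   doubling times of a well group).
#' @param mode `"average"` (arithmetic mean) or `"median"`.
#' @return Named numeric `c(center, spread)`; spread is the sample standard
#'   deviation (n-1 denominator), 0 for a single member.
#' @export
summarize_group <- function(values, mode = c("average", "median")) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("group summary needs at least one non-missing value", call. = FALSE)
  center <- if (mode == "average") mean(values) else stats::median(values)
  spread <- if (length(values) > 1L) stats::sd(values) else 0
  c(center = center, spread = spread)
}

#' Percent change of a group versus the reference
#'
#' @param group_center,ref_center Group and reference center values.
#' @return `100 * (group_center - ref_center) / ref_center`.
#' @export
pct_change <- function(group_center, ref_center) {
  if (any(ref_center == 0))
    stop("percent change undefined for a zero reference", call. = FALSE)
  100 * (group_center - ref_center) / ref_center
}

#' log2 ratio of a group versus the reference
#'
#' @inheritParams pct_change
#' @return `log2(group_center / ref_center)`.
#' @export
log2_ratio <- function(group_center, ref_center) {
  if (any(group_center <= 0) || any(ref_center <= 0))
    stop("log2 ratio requires positive values", call. = FALSE)
  log2(group_center / ref_center)
}

#' Welch t-test of a group versus the reference
#'
#' Two-sample, two-sided t-test with unequal variances
#' (Welch-Satterthwaite degrees of freedom); with as few as three
#' biological replicates per group, assuming equal variances is unsafe.
#'
#' @param group_values,ref_values Numeric vectors, each of length >= 2.
#' @return Named numeric `c(t_stat, p_value)`.
#' @export
t_test_vs_ref <- function(group_values, ref_values) {
  if (length(group_values) < 2L || length(ref_values) < 2L)
    stop("t-test requires >=2 replicates in each group", call. = FALSE)
  if (stats::sd(group_values) == 0 && stats::sd(ref_values) == 0) {
    # degenerate: both groups constant; identical means => no evidence
    if (mean(group_values) == mean(ref_values))
      return(c(t_stat = 0, p_value = 1))
    return(c(t_stat = Inf * sign(mean(group_values) - mean(ref_values)),
             p_value = 0))
  }
  fit <- stats::t.test(group_values, ref_values, var.equal = FALSE,
                       alternative = "two.sided")
  c(t_stat = unname(fit$statistic), p_value = fit$p.value)
}

#' Summarize lineage statistics by replicate group
#'
#' Computes, for each well group, the center and spread of the reference
#' doubling time, the survival fraction at every age-point, and the
#' survival integral; optionally compares survival integrals against a
#' reference group (percent change, log2 ratio, Welch t-test).
#'
#' @param lineages A `lineage_set` from [build_lineages()].
#' @param mode `"average"` or `"median"` group center.
#' @param reference_group Name of the reference group, or `NULL` for no
#'   comparisons.
#' @param use_clean Summarize cleaned (default) or raw survival fractions.
#' @return A data frame, one row per group, with `n`, per-statistic center
#'   and `_sd` columns, and — when a reference is set — `pct_change`,
#'   `log2_ratio`, `t_stat`, `p_value` on survival integrals.
#' @export
summarize_lineages <- function(lineages, mode = c("average", "median"),
                               reference_group = NULL, use_clean = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lineages, "lineage_set"))
  wells <- lineages$wells
  ages <- lineages$ages
  surv_col <- if (use_clean) "survival_clean" else "survival_raw"
  groups <- unique(wells$group)
  if (!is.null(reference_group) && !(reference_group %in% groups))
    stop(sprintf("reference group '%s' not found; groups: %s",
                 reference_group, paste(groups, collapse = ", ")),
         call. = FALSE)
  ref_si <- if (!is.null(reference_group))
    wells$survival_integral[wells$group == reference_group] else NULL

  rows <- lapply(groups, function(g) {
    members <- wells[wells$group == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(members),
                      stringsAsFactors = FALSE)
    dt <- summarize_group(members$ref_doubling_time, mode)
    out$doubling_time <- dt[["center"]]; out$doubling_time_sd <- dt[["spread"]]
    for (d in lineages$days) {
      v <- ages[ages$group == g & ages$day == d, surv_col]
      s <- summarize_group(v, mode)
      out[[paste0("survival_day_", d)]] <- s[["center"]]
      out[[paste0("survival_day_", d, "_sd")]] <- s[["spread"]]
    }
    si <- summarize_group(members$survival_integral, mode)
    out$survival_integral <- si[["center"]]
    out$survival_integral_sd <- si[["spread"]]
    if (!is.null(ref_si)) {
      ref_center <- summarize_group(ref_si, mode)[["center"]]
      out$pct_change <- pct_change(si[["center"]], ref_center)
      out$log2_ratio <- log2_ratio(si[["center"]], ref_center)
      tt <- t_test_vs_ref(members$survival_integral, ref_si)
      out$t_stat <- tt[["t_stat"]]; out$p_value <- tt[["p_value"]]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
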