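# Shared fixture builders: run-file text, exponential curves, small
# in-memory experiments.

# Write a run CSV from a time grid (hours) and an OD matrix (rows = times).
write_run_fixture <- function(times, od, path = tempfile(fileext = ".csv"),
                              header = TRUE, well_names = NULL) {
  n_wells <- ncol(od)
  if (is.null(well_names)) well_names <- paste0("w", seq_len(n_wells))
  lines <- character(0)
  if (header) lines <- paste(c("Time", well_names), collapse = ",")
  body <- vapply(seq_along(times), function(i) {
    paste(c(format_time(times[i]),
            formatC(od[i, ], digits = 6, format = "f")), collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path)
  path
}

write_well_info_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Pure exponential corrected-OD curve: od0 * 2^(t / delta), plus background.
exp_curve <- function(delta, od0 = 0.01, background = 0,
                      times = seq(0, 24, by = 0.5)) {
  od_curve(times, background + od0 * 2^(times / delta), background)
}

# A tiny two-group in-memory experiment built from exact exponentials whose
# inocula encode the viable fractions (delayed curves).
make_exact_runs <- function(days, fractions_by_group,
                            n_rep = 3, delta = 1.5, od0 = 0.01,
                            background = 0.15,
                            times = seq(0, 24, by = 0.5)) {
  groups <- names(fractions_by_group)
  n_wells <- length(groups) * n_rep
  runs <- lapply(seq_along(days), function(i) {
    wells <- sapply(seq_len(n_wells), function(w) {
      g <- groups[ceiling(w / n_rep)]
      f <- fractions_by_group[[g]][i]
      if (f > 0) background + od0 * f * 2^(times / delta)
      else rep(background, length(times))
    })
    colnames(wells) <- paste0(rep(groups, each = n_rep), "_",
                              rep(seq_len(n_rep), length(groups)))
    outgrowth_run(raw_run_table(times, wells,
                                source_name = sprintf("day%g", days[i])),
                  day = days[i], background = background)
  })
  wi <- data.frame(position = seq_len(n_wells),
                   name = colnames(runs[[1]]$table$wells),
                   group = rep(groups, each = n_rep),
                   media = "YPD", role = "sample",
                   stringsAsFactors = FALSE)
  class(wi) <- c("well_info", "data.frame")
  list(runs = runs, wells = wi)
}
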