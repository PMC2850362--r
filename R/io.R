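# Reading and validating plate-reader run files and well-info tables.
#
# Run files follow the Bioscreen "EZExperiment" export layout: first column
# elapsed time as HH:MM:SS, each subsequent column one well's OD readings,
# optionally preceded by a single header row.

#' Maximum number of well columns accepted in one run file
#'
#' The Bioscreen C instrument reads at most two 100-well Honeycomb plates at
#' once, so a single run can carry at most 200 aging cultures.
#' @export
MAX_WELLS <- 200L

#' Default background optical density
#'
#' Used when a value-type background is requested without an explicit number.
#' Approximately the OD reading of 150 uL of plain YPD medium in a Honeycomb
#' well.
#' @export
DEFAULT_BACKGROUND <- 0.15

#' Parse an HH:MM:SS time stamp into decimal hours
#'
#' The hours field is unbounded (multi-day reads exceed 24); minutes and
#' seconds must lie in 00-59.
#'
#' @param stamp Character vector of time stamps, e.g. `"00:30:00"`.
#' @param context Optional label (file name, row index) used in error messages.
#' @return Numeric vector of elapsed hours.
#' @examples
#' parse_time("00:30:00")  # 0.5
#' parse_time("25:15:30")  # 25.258...
#' @export
parse_time <- function(stamp, context = NULL) {
  stamp <- trimws(as.character(stamp))
  m <- regmatches(stamp, regexec("^([0-9]+):([0-9]{2}):([0-9]{2})$", stamp))
  bad <- vapply(m, length, 0L) != 4L
  if (!any(bad)) {
    parts <- vapply(m, function(x) as.numeric(x[2:4]), numeric(3))
    mm <- parts[2L, ]
    ss <- parts[3L, ]
    bad <- mm > 59 | ss > 59
    if (!any(bad)) {
      return(parts[1L, ] + mm / 60 + ss / 3600)
    }
  }
  where <- which(bad)[1L]
  ctx <- if (is.null(context)) "" else paste0(" in ", context)
  stop(sprintf("malformed time stamp '%s' at row %d%s (expected H+:MM:SS)",
               stamp[where], where, ctx), call. = FALSE)
}

#' Format decimal hours as an HH:MM:SS stamp
#'
#' Inverse of [parse_time()] to the nearest second.
#' @param hours Numeric vector of elapsed hours.
#' @return Character vector of stamps.
#' @export
format_time <- function(hours) {
  total <- round(hours * 3600)
  sprintf("%02d:%02d:%02d", total %/% 3600L, (total %% 3600L) %/% 60L,
          total %% 60L)
}

#' Construct a raw run table
#'
#' @param times Numeric vector of elapsed hours, strictly increasing.
#' @param wells Numeric matrix of OD readings, one column per well, one row
#'   per time point. Column names label the wells.
#' @param source_name Text label for the run (typically the file name).
#' @return An object of class `raw_run_table`.
#' @export
raw_run_table <- function(times, wells, source_name = "run") {
  wells <- as.matrix(wells)
  storage.mode(wells) <- "double"
  if (length(times) < 2L)
    stop("a run needs at least 2 time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time column must be strictly increasing (found equal or ",
         "decreasing consecutive stamps)", call. = FALSE)
  if (nrow(wells) != length(times))
    stop("every well column must have exactly one reading per time point",
         call. = FALSE)
  if (ncol(wells) < 1L)
    stop("no well columns", call. = FALSE)
  if (ncol(wells) > MAX_WELLS)
    stop(sprintf("%d well columns exceed the instrument capacity of %d wells",
                 ncol(wells), MAX_WELLS), call. = FALSE)
  if (any(!is.finite(wells)))
    stop("non-numeric or missing OD reading in run table", call. = FALSE)
  if (is.null(colnames(wells)))
    colnames(wells) <- paste0("well_", seq_len(ncol(wells)))
  structure(list(source_name = source_name, times = as.numeric(times),
                 wells = wells),
            class = "raw_run_table")
}

#' @export
print.raw_run_table <- function(x, ...) {
  cat(sprintf("<raw_run_table> %s: %d time points x %d wells, %.2f-%.2f h\n",
              x$source_name, length(x$times), ncol(x$wells),
              min(x$times), max(x$times)))
  invisible(x)
}

# Split raw delimited lines into fields, dropping trailing all-empty columns.
.read_delim_cells <- function(path, sep = ",") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  lapply(strsplit(lines, sep, fixed = TRUE), trimws)
}

.looks_like_time <- function(x) {
  grepl("^[0-9]+:[0-9]{2}:[0-9]{2}$", trimws(x))
}

#' Read a plate-reader run file
#'
#' Reads a comma-delimited (or spreadsheet, first sheet only) run file in the
#' EZExperiment layout: first column HH:MM:SS time stamps, each subsequent
#' column one well's OD readings. A single header row is detected
#' automatically (its first cell does not parse as a time stamp). Trailing
#' empty columns are dropped.
#'
#' @param path Path to a `.csv` (canonical) or `.xls`/`.xlsx` file.
#' @param source_name Label for the run; defaults to the file's base name.
#' @return A [raw_run_table()].
#' @export
parse_run <- function(path, source_name = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("run file not found: %s", path), call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheet workbooks requires the 'readxl' package",
           call. = FALSE)
    df <- readxl::read_excel(path, sheet = 1L, col_names = FALSE,
                             col_types = "text", .name_repair = "minimal")
    rows <- lapply(seq_len(nrow(df)), function(i) {
      v <- as.character(unlist(df[i, ], use.names = FALSE))
      trimws(ifelse(is.na(v), "", v))
    })
  } else {
    rows <- .read_delim_cells(path)
  }
  if (length(rows) == 0L)
    stop(sprintf("run file %s is empty", source_name), call. = FALSE)

  # drop trailing all-empty columns
  width <- max(vapply(rows, length, 0L))
  grid <- vapply(rows, function(r) c(r, rep("", width - length(r))),
                 character(width))
  grid <- matrix(grid, nrow = width)  # columns of grid = file rows
  keep <- which(apply(grid, 1L, function(col) any(nzchar(col))))
  if (length(keep) > 0L) grid <- grid[seq_len(max(keep)), , drop = FALSE]
  width <- nrow(grid)

  # ragged check on the trimmed width
  lens <- vapply(rows, function(r) {
    r <- r[seq_len(min(length(r), width))]
    last <- which(nzchar(r))
    if (length(last) == 0L) 0L else max(last)
  }, 0L)
  header <- !.looks_like_time(grid[1L, 1L])
  body_rows <- if (header) seq_len(ncol(grid))[-1L] else seq_len(ncol(grid))
  if (length(body_rows) == 0L)
    stop(sprintf("run file %s has a header but no data rows", source_name),
         call. = FALSE)
  ragged <- body_rows[lens[body_rows] != width]
  if (length(ragged) > 0L)
    stop(sprintf("ragged row %d in %s: expected %d columns",
                 ragged[1L], source_name, width), call. = FALSE)

  if (width < 2L)
    stop(sprintf("run file %s has no well columns", source_name),
         call. = FALSE)
  n_wells <- width - 1L
  if (n_wells > MAX_WELLS)
    stop(sprintf(
      "%d well columns in %s exceed the instrument capacity of %d wells",
      n_wells, source_name, MAX_WELLS), call. = FALSE)

  times <- parse_time(grid[1L, body_rows], context = source_name)
  od_text <- grid[-1L, body_rows, drop = FALSE]  # wells x time
  suppressWarnings(od <- as.numeric(od_text))
  if (anyNA(od)) {
    bad <- which(is.na(od))[1L]
    w <- (bad - 1L) %% n_wells + 1L
    r <- (bad - 1L) %/% n_wells + 1L
    stop(sprintf("non-numeric OD value '%s' in %s at data row %d, well column %d",
                 od_text[bad], source_name, r, w), call. = FALSE)
  }
  od <- matrix(od, nrow = n_wells)
  wells <- t(od)
  colnames(wells) <- if (header) {
    nm <- grid[-1L, 1L]
    ifelse(nzchar(nm), nm, paste0("well_", seq_len(n_wells)))
  } else paste0("well_", seq_len(n_wells))
  raw_run_table(times, wells, source_name = source_name)
}

#' Write a run table back to the run-CSV layout
#'
#' Emits the same layout [parse_run()] reads: a header row, HH:MM:SS stamps
#' in the first column, one well per subsequent column.
#'
#' @param table A [raw_run_table()].
#' @param path Output file path.
#' @param digits Number of decimals for OD readings.
#' @export
write_run <- function(table, path, digits = 6L) {
  stopifnot(inherits(table, "raw_run_table"))
  header <- paste(c("Time", colnames(table$wells)), collapse = ",")
  body <- vapply(seq_along(table$times), function(i) {
    paste(c(format_time(table$times[i]),
            formatC(table$wells[i, ], digits = digits, format = "f")),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a well-info table
#'
#' A CSV with header `position,name,group,media,role` mapping plate positions
#' (1-based, matching run-file well column order) to well names, replicate
#' groups, media and sample/blank role. `name` is required; `group` defaults
#' to the name, `media` to `""`, `role` to `"sample"`.
#'
#' @param path Path to the well-info CSV.
#' @return A data frame of class `well_info`, sorted by position, with
#'   columns `position`, `name`, `group`, `media`, `role`.
#' @export
parse_well_info <- function(path) {
  if (!file.exists(path))
    stop(sprintf("well-info file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(trimws(names(df)))
  if (!all(c("position", "name") %in% names(df)))
    stop("well-info file needs at least 'position' and 'name' columns",
         call. = FALSE)
  if (nrow(df) == 0L) return(.as_well_info(df[0, , drop = FALSE]))
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos) || any(pos < 1L) || any(pos > MAX_WELLS))
    stop(sprintf("well positions must be integers in 1-%d", MAX_WELLS),
         call. = FALSE)
  if (anyDuplicated(pos))
    stop(sprintf("duplicate well position %d in well info",
                 pos[duplicated(pos)][1L]), call. = FALSE)
  out <- data.frame(
    position = pos,
    name = df$name,
    group = if ("group" %in% names(df)) df$group else df$name,
    media = if ("media" %in% names(df)) df$media else "",
    role = if ("role" %in% names(df)) df$role else "sample",
    stringsAsFactors = FALSE)
  out$role[!nzchar(out$role)] <- "sample"
  out$group[!nzchar(out$group)] <- out$name[!nzchar(out$group)]
  bad_role <- setdiff(unique(out$role), c("sample", "blank"))
  if (length(bad_role) > 0L)
    stop(sprintf("well role must be 'sample' or 'blank', got '%s'",
                 bad_role[1L]), call. = FALSE)
  # a media-only blank is not a biological replicate of anything
  out$group[out$role == "blank"] <- ""
  .as_well_info(out[order(out$position), , drop = FALSE])
}

.as_well_info <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("well_info", "data.frame")
  df
}

#' Default well info for an unannotated run
#'
#' When no well-info table is given, wells are named by position and each
#' forms its own group.
#' @param n_wells Number of well columns in the run.
#' @return A `well_info` data frame.
#' @export
default_well_info <- function(n_wells) {
  .as_well_info(data.frame(
    position = seq_len(n_wells),
    name = paste0("well_", seq_len(n_wells)),
    group = paste0("well_", seq_len(n_wells)),
    media = "", role = "sample", stringsAsFactors = FALSE))
}

#' Compute the background OD for a run
#'
#' The background is the optical density of medium without cells, subtracted
#' from every reading. It is either taken from a named media-only (blank)
#' well — as the median over that well's whole series, robust to a single
#' contaminated reading — or given as a fixed value. A value-type background
#' with no number falls back to [DEFAULT_BACKGROUND].
#'
#' @param table A [raw_run_table()].
#' @param wells A `well_info` data frame (needed for a named-well background).
#' @param blank_well Name of the blank well, or `NULL`.
#' @param value Fixed background OD, or `NULL`.
#' @return Numeric background OD with attribute `source` set to
#'   `"named_well"` or `"fixed_value"`.
#' @export
compute_background <- function(table, wells = NULL, blank_well = NULL,
                               value = NULL) {
  if (!is.null(blank_well)) {
    if (is.null(wells))
      stop("a named-well background requires a well-info table", call. = FALSE)
    blanks <- wells[wells$role == "blank", , drop = FALSE]
    hit <- blanks[blanks$name == blank_well, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop(sprintf("blank well '%s' not found; known blank wells: %s",
                   blank_well,
                   if (nrow(blanks)) paste(blanks$name, collapse = ", ")
                   else "(none)"), call. = FALSE)
    pos <- hit$position[1L]
    if (pos > ncol(table$wells))
      stop(sprintf("blank well '%s' at position %d exceeds the run's %d wells",
                   blank_well, pos, ncol(table$wells)), call. = FALSE)
    bg <- stats::median(table$wells[, pos])
    src <- "named_well"
  } else {
    bg <- if (is.null(value)) DEFAULT_BACKGROUND else as.numeric(value)
    src <- "fixed_value"
  }
  if (!is.finite(bg) || bg < 0)
    stop("background must be a non-negative number", call. = FALSE)
  structure(bg, source = src)
}

#' Assemble an outgrowth run
#'
#' Couples a raw run table with its age label (day) and background reading.
#' The day may be any real-valued ordinal: culture age in days for a
#' chronological-aging experiment, or a treatment ordinal (e.g. minutes of
#' heat shock) when treatments are encoded as pseudo-age-points.
#'
#' @param table A [raw_run_table()].
#' @param day Real-valued age label.
#' @param background Background OD (from [compute_background()] or a number).
#' @return An object of class `outgrowth_run`.
#' @export
outgrowth_run <- function(table, day, background = DEFAULT_BACKGROUND) {
  stopifnot(inherits(table, "raw_run_table"))
  if (!is.numeric(day) || length(day) != 1L || !is.finite(day))
    stop("day must be a single finite number", call. = FALSE)
  day <- as.numeric(day)
  src <- attr(background, "source")
  background <- as.numeric(background)
  if (!is.finite(background) || background < 0)
    stop("background must be a non-negative number", call. = FALSE)
  structure(list(table = table, day = day, background = background,
                 background_source = if (is.null(src)) "fixed_value" else src),
            class = "outgrowth_run")
}

#' @export
print.outgrowth_run <- function(x, ...) {
  cat(sprintf("<outgrowth_run> day %g, background %.4f (%s)\n",
              x$day, x$background, x$background_source))
  print(x$table)
  invisible(x)
}
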