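#' Read plate-reader absorbance data
#'
#' Two CSV dialects are supported.
#'
#' **long** (default): one row per well reading, columns `concentration`,
#' `time`, `experiment`, `replicate`, `absorbance`, and optionally
#' `cell_line`, `drug`, `conc_unit`, `time_unit`. `time_unit` may also be
#' given as an argument; a per-file `time_unit` column wins over the
#' argument. Default unit is hours.
#'
#' **wide** (96-well-style): one CSV per time point with columns `well` and
#' `absorbance`, plus a mandatory plate-layout sidecar CSV mapping
#' `well -> (concentration, experiment, replicate)`. No heuristic well
#' inference is done; wells absent from the layout are dropped. The
#' time point of each file is supplied through `times` (same length and
#' order as `path`).
#'
#' @param path for `dialect = "long"` a single CSV path; for `"wide"` a
#'   character vector of per-time-point CSV paths.
#' @param dialect `"long"` or `"wide"`.
#' @param layout path of the layout CSV (wide dialect only), with columns
#'   `well`, `concentration`, `experiment`, `replicate`.
#' @param times numeric vector of time points, one per file (wide dialect
#'   only), in `time_unit`.
#' @param time_unit unit of the `time` column / `times` argument,
#'   `"hours"` (default) or `"days"`.
#' @param drug,cell_line,conc_unit metadata used when the file carries none.
#' @return a validated [assay_table] with times in days.
#' @export
read_assay_csv <- function(path, dialect = c("long", "wide"), layout = NULL,
                           times = NULL, time_unit = c("hours", "days"),
                           drug = NA_character_, cell_line = NA_character_,
                           conc_unit = "ug/mL") {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  for (p in c(path, layout)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (dialect == "long") {
    read_assay_long(path, time_unit, drug, cell_line, conc_unit)
  } else {
    if (is.null(layout)) stop("wide dialect requires a layout CSV", call. = FALSE)
    if (is.null(times) || length(times) != length(path)) {
      stop("wide dialect requires `times`, one per file", call. = FALSE)
    }
    read_assay_wide(path, times, layout, time_unit, drug, cell_line, conc_unit)
  }
}

read_assay_long <- function(path, time_unit, drug, cell_line, conc_unit) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("concentration", "time", "experiment", "replicate", "absorbance")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("long dialect: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  if ("time_unit" %in% names(df)) {
    units <- unique(df$time_unit)
    if (length(units) != 1 || !units %in% c("hours", "days")) {
      stop("time_unit column must be a single value, 'hours' or 'days'",
           call. = FALSE)
    }
    time_unit <- units
  }
  if ("drug" %in% names(df)) drug <- df$drug[1]
  if ("cell_line" %in% names(df)) cell_line <- df$cell_line[1]
  if ("conc_unit" %in% names(df)) conc_unit <- df$conc_unit[1]
  as_assay_table(df, drug = drug, cell_line = cell_line,
                 conc_unit = conc_unit, time_unit = time_unit)
}

read_assay_wide <- function(paths, times, layout, time_unit,
                            drug, cell_line, conc_unit) {
  lay <- readr::read_csv(layout, show_col_types = FALSE, progress = FALSE)
  req <- c("well", "concentration", "experiment", "replicate")
  missing_cols <- setdiff(req, names(lay))
  if (length(missing_cols) > 0) {
    stop("layout CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pieces <- Map(function(p, t) {
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    if (!all(c("well", "absorbance") %in% names(df))) {
      stop("wide time-point CSV needs columns well, absorbance: ", p,
           call. = FALSE)
    }
    merged <- dplyr::inner_join(lay, df[, c("well", "absorbance")], by = "well")
    merged$time <- t
    merged
  }, paths, times)
  df <- dplyr::bind_rows(pieces)
  as_assay_table(df, drug = drug, cell_line = cell_line,
                 conc_unit = conc_unit, time_unit = time_unit)
}

#' Write an assay table as a long-dialect CSV
#'
#' Times are written back in hours (the field's conventional unit for these
#' assays) with an explicit `time_unit` column, so a written file re-reads
#' into an identical table.
#'
#' @param assay an [assay_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(assay, path) {
  out <- tibble::tibble(
    cell_line = attr(assay, "cell_line"),
    drug = attr(assay, "drug"),
    concentration = assay$concentration,
    conc_unit = attr(assay, "conc_unit"),
    time = assay$time * HOURS_PER_DAY,
    time_unit = "hours",
    experiment = assay$experiment,
    replicate = assay$replicate,
    absorbance = assay$absorbance
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Normalize one concentration series to its seeding-time absorbance
#'
#' Within each independent experiment, absorbances are divided by the
#' geometric mean of that experiment's t0 absorbances and natural-log
#' transformed, so the mean log-value at t = 0 is exactly zero per
#' experiment. The result is the log-scale series whose slope over time is
#' the effective growth rate.
#'
#' @param assay an [assay_table].
#' @param concentration one concentration present in the assay.
#' @return a `normalized_series`: list with `concentration`, `times` (days,
#'   ascending), `log_values`, `experiment`, and `n_replicates_per_time`.
#' @export
normalize_to_t0 <- function(assay, concentration) {
  rows <- assay[assay$concentration == concentration, ]
  if (nrow(rows) == 0) {
    stop("concentration ", concentration, " not present in the assay",
         call. = FALSE)
  }
  if (length(unique(rows$time)) < 2) {
    stop("fewer than 2 distinct time points for concentration ",
         concentration, call. = FALSE)
  }
  logv <- numeric(nrow(rows))
  for (exp_id in unique(rows$experiment)) {
    in_exp <- rows$experiment == exp_id
    t0 <- in_exp & rows$time == 0
    if (!any(t0)) {
      stop("experiment ", exp_id, " has no t0 reading at concentration ",
           concentration, call. = FALSE)
    }
    log_t0_mean <- mean(log(rows$absorbance[t0]))
    logv[in_exp] <- log(rows$absorbance[in_exp]) - log_t0_mean
  }
  ord <- order(rows$time)
  times <- rows$time[ord]
  structure(list(
    concentration = concentration,
    times = times,
    log_values = logv[ord],
    experiment = rows$experiment[ord],
    n_replicates_per_time = as.integer(table(factor(times, levels = unique(times))))
  ), class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> concentration %g: %d observations over %d times\n",
              x$concentration, length(x$times), length(unique(x$times))))
  invisible(x)
}

#' Drop the seeding-time points from a normalized series
#'
#' Supports the alternative reading of the fitting window in which only the
#' 24/48/72 h points enter the regression.
#'
#' @param series a `normalized_series`.
#' @return the series without its t = 0 observations.
#' @export
drop_t0 <- function(series) {
  keep <- series$times > 0
  if (length(unique(series$times[keep])) < 2) {
    stop("dropping t0 leaves fewer than 2 distinct time points", call. = FALSE)
  }
  times <- series$times[keep]
  structure(list(
    concentration = series$concentration,
    times = times,
    log_values = series$log_values[keep],
    experiment = series$experiment[keep],
    n_replicates_per_time = as.integer(table(factor(times, levels = unique(times))))
  ), class = "normalized_series")
}
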