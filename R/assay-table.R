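#' Assay tables: tidy plate-reader absorbance observations
#'
#' An `assay_table` is a tibble of absorbance observations keyed by
#' `(concentration, time, experiment, replicate)` with metadata attributes
#' `drug`, `cell_line` and `conc_unit`. Times are always stored in days so
#' that fitted growth rates come out in days^-1; absorbances are in arbitrary
#' optical-density units and must be positive (they are log-transformed
#' downstream). Inputs are expected to be blank-corrected upstream: no
#' background subtraction is performed here.
#'
#' Structural invariants, enforced by [validate_assay()]:
#' * at least one concentration equal to 0 (the untreated control),
#' * every concentration has a `t = 0` (seeding-time) reading,
#' * every concentration has at least two distinct time points,
#' * all absorbances strictly positive.
#'
#' @name assay_table
NULL

new_assay_table <- function(df, drug = NA_character_, cell_line = NA_character_,
                            conc_unit = "ug/mL") {
  df <- tibble::as_tibble(df)
  df <- df[order(df$concentration, df$experiment, df$replicate, df$time), ]
  structure(df,
    drug = drug, cell_line = cell_line, conc_unit = conc_unit,
    class = c("assay_table", class(tibble::tibble())))
}

#' Build an assay table from a data frame
#'
#' @param df data frame with columns `concentration`, `time`, `experiment`,
#'   `replicate`, `absorbance` (extra columns are dropped).
#' @param drug,cell_line optional metadata strings.
#' @param conc_unit concentration unit label (default `"ug/mL"`).
#' @param time_unit unit of the `time` column; `"hours"` (default) or
#'   `"days"`. Hours are converted to days internally.
#' @return a validated [assay_table].
#' @export
#' @examples
#' df <- expand.grid(concentration = c(0, 5), time = c(0, 24, 48, 72),
#'                   experiment = 1, replicate = 1:3)
#' df$absorbance <- 0.2 * exp(0.3 * df$time / 24)
#' as_assay_table(df, drug = "oxaliplatin", cell_line = "HCT116")
as_assay_table <- function(df, drug = NA_character_, cell_line = NA_character_,
                           conc_unit = "ug/mL", time_unit = c("hours", "days")) {
  time_unit <- match.arg(time_unit)
  req <- c("concentration", "time", "experiment", "replicate", "absorbance")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    concentration = as.numeric(df$concentration),
    time = to_days(as.numeric(df$time), time_unit),
    experiment = as.character(df$experiment),
    replicate = as.character(df$replicate),
    absorbance = as.numeric(df$absorbance)
  )
  validate_assay(new_assay_table(out, drug = drug, cell_line = cell_line,
                                 conc_unit = conc_unit))
}

#' Validate an assay table's structural invariants
#'
#' @param assay an [assay_table].
#' @return `assay`, invisibly usable, after passing all checks.
#' @export
validate_assay <- function(assay) {
  if (any(!is.finite(assay$absorbance))) {
    stop("non-finite absorbance at row(s) ",
         paste(head(which(!is.finite(assay$absorbance)), 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(assay$absorbance <= 0)
  if (length(bad) > 0) {
    stop("non-positive absorbance at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         ": log-transform requires absorbance > 0", call. = FALSE)
  }
  if (any(assay$concentration < 0) || any(assay$time < 0)) {
    stop("concentrations and times must be non-negative", call. = FALSE)
  }
  if (!any(assay$concentration == 0)) {
    stop("no zero-concentration control series in the assay", call. = FALSE)
  }
  for (conc in unique(assay$concentration)) {
    tt <- assay$time[assay$concentration == conc]
    if (!any(tt == 0)) {
      stop("missing t0 (seeding-time) reading for concentration ", conc,
           call. = FALSE)
    }
    if (length(unique(tt)) < 2) {
      stop("fewer than 2 distinct time points for concentration ", conc,
           call. = FALSE)
    }
  }
  assay
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf(
    "<assay_table> %s / %s: %d observations, %d concentrations (%s), %d time points\n",
    attr(x, "cell_line") %||% "?", attr(x, "drug") %||% "?", nrow(x),
    length(unique(x$concentration)), attr(x, "conc_unit"),
    length(unique(x$time))))
  NextMethod()
}

assay_concentrations <- function(assay) sort(unique(assay$concentration))

#' Restrict an assay to a subset of its observed time points
#'
#' @param assay an [assay_table].
#' @param times times to keep, in days; must be observed times, include 0 and
#'   at least one later point.
#' @return the filtered, revalidated [assay_table].
#' @export
filter_endpoints <- function(assay, times) {
  obs <- sort(unique(assay$time))
  extra <- setdiff(times, obs)
  if (length(extra) > 0) {
    stop("endpoint(s) not observed in the assay: ",
         paste(extra, collapse = ", "), " (days)", call. = FALSE)
  }
  if (!0 %in% times || length(unique(times)) < 2) {
    stop("endpoints must include t = 0 and at least one later time",
         call. = FALSE)
  }
  keep <- assay$time %in% times
  validate_assay(new_assay_table(assay[keep, ], drug = attr(assay, "drug"),
                                 cell_line = attr(assay, "cell_line"),
                                 conc_unit = attr(assay, "conc_unit")))
}
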