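#' Endpoint viability relative to the same-time control
#'
#' Conventional viability: per concentration, the mean treated absorbance at
#' the requested time divided by the mean control (zero-concentration)
#' absorbance at the same time, times 100. Because treated and control
#' populations grow at different rates, this quantity depends explicitly on
#' the endpoint chosen — the motivation for the growth-rate indices.
#'
#' @param assay an [assay_table].
#' @param time endpoint, in `time_unit`; must be observed for every
#'   concentration.
#' @param time_unit `"days"` (default) or `"hours"`.
#' @return tibble with `concentration`, `time` (days), `viability_pct`.
#'   The control row is 100 by construction.
#' @export
compute_viability <- function(assay, time, time_unit = c("days", "hours")) {
  time_unit <- match.arg(time_unit)
  t_day <- to_days(time, time_unit)
  concs <- assay_concentrations(assay)
  at_t <- assay[assay$time == t_day, ]
  missing_c <- setdiff(concs, unique(at_t$concentration))
  if (nrow(at_t) == 0 || length(missing_c) > 0) {
    stop("time ", t_day, " days not observed for concentration(s): ",
         paste(if (nrow(at_t) == 0) concs else missing_c, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- mean(at_t$absorbance[at_t$concentration == 0])
  means <- vapply(concs, function(cc) mean(at_t$absorbance[at_t$concentration == cc]),
                  numeric(1))
  tibble::tibble(concentration = concs, time = t_day,
                 viability_pct = means / ctrl * 100)
}

#' Fit the four-parameter logistic (4PL) dose-response baseline
#'
#' Conventional sigmoid used by standard IC50 calculators:
#' `Y = Ymin + (Ymax - Ymin) / (1 + (X / IC50)^H)`. The fitted `ic50` is the
#' relative IC50 — the concentration at the curve's midpoint
#' `(Ymin + Ymax)/2`, not at 50% absolute viability. Fitting is plain
#' nonlinear least squares on the concentration scale; the zero-
#' concentration control is included as X = 0, where the model evaluates to
#' `Ymax` for positive Hill slope, so the control anchors the top plateau
#' without needing a log-dose placeholder.
#'
#' @param viability_points data frame with columns `concentration` and
#'   `viability_pct` (output of [compute_viability()]); at least 5 distinct
#'   concentrations spanning high and low response.
#' @return a `four_pl_fit`: list with `y_min`, `y_max`, `hill`, `ic50`,
#'   `rss`, `converged`, `outside_range` (fitted ic50 outside the tested
#'   positive doses). For decreasing-viability data a fit with Hill slope
#'   <= 0 is marked non-converged.
#' @export
fit_four_pl <- function(viability_points) {
  vp <- tibble::as_tibble(viability_points)
  if (!all(c("concentration", "viability_pct") %in% names(vp))) {
    stop("need columns concentration, viability_pct", call. = FALSE)
  }
  vp <- vp[order(vp$concentration), ]
  x <- vp$concentration
  y <- vp$viability_pct
  if (length(unique(x)) < 5) {
    stop("need at least 5 distinct concentrations for a 4PL fit", call. = FALSE)
  }
  failed <- structure(list(y_min = NA_real_, y_max = NA_real_,
                           hill = NA_real_, ic50 = NA_real_,
                           rss = sum((y - mean(y))^2), converged = FALSE,
                           outside_range = NA),
                      class = "four_pl_fit")
  ymin0 <- min(y); ymax0 <- max(y)
  if (ymax0 - ymin0 < sqrt(.Machine$double.eps)) return(failed)
  mid <- (ymin0 + ymax0) / 2
  pos <- x > 0
  ic0 <- x[pos][which.min(abs(y[pos] - mid))]
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(x[pos])
  dat <- data.frame(X = x, Y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Y ~ ymin + (ymax - ymin) / (1 + (X / ic50)^h), data = dat,
      start = list(ymin = ymin0, ymax = ymax0, ic50 = ic0, h = 1),
      lower = c(-Inf, -Inf, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- coef(fit)
  decreasing <- y[which.max(x)] < y[which.min(x)]
  ok <- all(is.finite(p)) && p[["ic50"]] > 0 && p[["ymin"]] < p[["ymax"]] &&
    (!decreasing || p[["h"]] > 0)
  structure(list(
    y_min = unname(p[["ymin"]]), y_max = unname(p[["ymax"]]),
    hill = unname(p[["h"]]), ic50 = unname(p[["ic50"]]),
    rss = sum(residuals(fit)^2), converged = ok,
    outside_range = p[["ic50"]] < min(x[pos]) || p[["ic50"]] > max(x)
  ), class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(
    "<four_pl_fit> Ymin %.3g, Ymax %.3g, Hill %.3g, relative IC50 %.4g (%s%s)\n",
    x$y_min, x$y_max, x$hill, x$ic50,
    if (x$converged) "converged" else "NOT converged",
    if (isTRUE(x$outside_range)) ", ic50 outside tested range" else ""))
  invisible(x)
}

#' Predicted viability from a 4PL fit
#'
#' @param fit a `four_pl_fit`.
#' @param concentration non-negative concentration(s).
#' @return predicted viability (%).
#' @export
predict_viability <- function(fit, concentration) {
  fit$y_min + (fit$y_max - fit$y_min) / (1 + (concentration / fit$ic50)^fit$hill)
}
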