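#' Specification of a synthetic plate assay
#'
#' Defines the ground truth for a simulated MTT-style assay: a population
#' growing exponentially at each concentration, with rate
#' `r(C) = amplitude * exp(-decay * C) - floor`, read out as absorbance with
#' multiplicative log-normal measurement noise. The defaults mirror the
#' standard assay design this package targets: readings at 0/24/48/72 h,
#' 3 technical replicates in each of 3 independent experiments, and eleven
#' doses (vehicle control plus ten two-fold dilutions from 50 down to
#' ~0.098 ug/mL). The default ground-truth curve (A = 0.85, alpha = 0.06,
#' r_inf = 0.55 — control rate 0.30 days^-1, high-dose decline rate
#' -0.55 days^-1) and noise sigma = 0.08 reproduce the magnitudes seen in
#' real oxaliplatin assays on colorectal lines.
#'
#' @param amplitude,decay,floor ground-truth dose-response parameters
#'   (days^-1, per-concentration-unit, days^-1).
#' @param concentrations doses including 0.
#' @param times reading times in days.
#' @param n_experiments,n_replicates independent experiments and technical
#'   replicates per experiment.
#' @param noise_sigma SD of the Gaussian noise on log-absorbance
#'   (multiplicative log-normal on absorbance), >= 0.
#' @param noise_type `"lognormal"` (default) or `"additive"` (absorbance
#'   plus Gaussian noise of SD `noise_sigma * baseline_absorbance`, clamped
#'   positive — a robustness stress-test, not the calibrated noise model).
#' @param baseline_absorbance seeding-time expected absorbance (OD units).
#' @param seed integer seed making [generate_assay()] deterministic.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(amplitude = 0.85, decay = 0.06, floor = 0.55,
                           concentrations = c(0, 50 * 2^-(9:0)),
                           times = c(0, 1, 2, 3),
                           n_experiments = 3, n_replicates = 3,
                           noise_sigma = 0.08,
                           noise_type = c("lognormal", "additive"),
                           baseline_absorbance = 0.2, seed = 1) {
  noise_type <- match.arg(noise_type)
  stopifnot(amplitude > 0, decay > 0, noise_sigma >= 0,
            baseline_absorbance > 0, n_experiments >= 1, n_replicates >= 1)
  if (!any(concentrations == 0)) {
    stop("concentrations must include the 0 control", call. = FALSE)
  }
  if (length(unique(times)) < 2 || !any(times == 0)) {
    stop("times must include 0 and at least one later point", call. = FALSE)
  }
  structure(list(
    amplitude = amplitude, decay = decay, floor = floor,
    concentrations = sort(unique(concentrations)), times = sort(unique(times)),
    n_experiments = as.integer(n_experiments),
    n_replicates = as.integer(n_replicates),
    noise_sigma = noise_sigma, noise_type = noise_type,
    baseline_absorbance = baseline_absorbance, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' True growth rate of a synthetic spec at given concentrations
#'
#' @param spec a `synthetic_spec`.
#' @param concentration concentration(s).
#' @return `amplitude * exp(-decay * C) - floor`, days^-1.
#' @export
true_rate <- function(spec, concentration) {
  spec$amplitude * exp(-spec$decay * concentration) - spec$floor
}

#' Generate a synthetic assay table
#'
#' Absorbance of each well is
#' `baseline * exp(r(C) * t) * exp(eps)`, `eps ~ N(0, noise_sigma^2)` drawn
#' independently per well and reading. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [assay_table] (drug `"synthetic"`).
#' @export
generate_assay <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- expand.grid(
    time = spec$times,
    replicate = paste0("r", seq_len(spec$n_replicates)),
    experiment = paste0("e", seq_len(spec$n_experiments)),
    concentration = spec$concentrations,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- spec$baseline_absorbance * exp(true_rate(spec, grid$concentration) * grid$time)
  set.seed(spec$seed)
  if (spec$noise_type == "lognormal") {
    grid$absorbance <- mu * exp(rnorm(nrow(grid), 0, spec$noise_sigma))
  } else {
    grid$absorbance <- pmax(mu + rnorm(nrow(grid), 0,
                                       spec$noise_sigma * spec$baseline_absorbance),
                            1e-6)
  }
  as_assay_table(grid, drug = "synthetic", cell_line = "synthetic",
                 conc_unit = "ug/mL", time_unit = "days")
}

#' Analytic ground-truth potency indices of a synthetic spec
#'
#' Closed-form inversion of the generating curve at the three index target
#' rates: `r0 + log(viability)/duration` (IC50 convention),
#' 0 (ICr0) and `r0 / 2` (ICrmed), with `r0 = amplitude - floor`.
#'
#' @param spec a `synthetic_spec`.
#' @param viability,duration the IC50 viability convention (defaults 0.5 and
#'   3 days).
#' @return named list `ic50`, `icr0`, `icrmed` (concentration units).
#' @export
ground_truth_indices <- function(spec, viability = 0.5, duration = 3) {
  r0 <- spec$amplitude - spec$floor
  targets <- c(ic50 = r0 + log(viability) / duration,
               icr0 = 0,
               icrmed = r0 / 2)
  out <- lapply(names(targets), function(nm) {
    tr <- targets[[nm]]
    if (tr + spec$floor <= 0) {
      stop(nm, ": target rate ", signif(tr, 4),
           " at or below the asymptotic floor; unreachable", call. = FALSE)
    }
    if (tr > r0) {
      stop(nm, ": target rate ", signif(tr, 4),
           " above the control rate; unreachable by a positive dose",
           call. = FALSE)
    }
    -1 / spec$decay * log((tr + spec$floor) / spec$amplitude)
  })
  setNames(out, names(targets))
}

#' Read / write a synthetic spec as JSON or YAML
#'
#' Format chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param spec a `synthetic_spec`.
#' @param path file path.
#' @return `write_synthetic_spec`: `path` invisibly;
#'   `read_synthetic_spec`: a `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lst <- unclass(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(synthetic_spec, lst)
}
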