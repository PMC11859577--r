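#' @importFrom stats coef lm median qnorm quantile residuals rnorm sd setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

HOURS_PER_DAY <- 24

#' Convert times to the internal unit (days)
#'
#' @param time numeric vector of times.
#' @param unit `"hours"` or `"days"`.
#' @return numeric vector in days.
#' @keywords internal
to_days <- function(time, unit = c("hours", "days")) {
  unit <- match.arg(unit)
  if (unit == "hours") time / HOURS_PER_DAY else time
}

# Sample skewness and excess kurtosis (moment estimators, no small-sample
# correction: they are applied to bootstrap distributions with n >= 100).
moment_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_excess_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Each stochastic stage of the pipeline consumes its own seed so that
#' adding or removing a concentration does not perturb the random stream of
#' the others.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_subseeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

z_for_conf <- function(conf_level) {
  stopifnot(conf_level > 0, conf_level < 1)
  qnorm(1 - (1 - conf_level) / 2)
}
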