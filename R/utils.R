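#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to a dose-grid step, half away from zero
#'
#' Commercial tacrolimus capsules come in 0.5 mg increments; administered
#' doses are therefore snapped to a step grid. `round()` in R rounds half to
#' even, which is wrong for dose rounding (6.5/2 = 3.25 mg must round up to
#' 3.5, not down to 3.0 on alternate calls), so half-up rounding is used.
#'
#' @param x numeric vector of doses (mg).
#' @param step grid granularity (mg), must be > 0.
#' @return `x` rounded to the nearest multiple of `step`.
#' @export
round_step <- function(x, step) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  step * floor(x / step + 0.5)
}

## lognormal sdlog for a given fractional coefficient of variation
sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

## median-1 lognormal multipliers (the usual exp(eta), eta ~ N(0, omega^2))
rlnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sdlog_from_cv(cv)))
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

## midpoint-interpolated median computed via sort indexing; exported metrics
## use stats::median, this is only for internal degenerate-size handling
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
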