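#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler used by the synthetic cohort generator.
#'
#' @param n number of draws
#' @param mean,sd parameters of the parent normal
#' @param lower,upper truncation bounds
#' @return numeric vector of length `n`, all values in `[lower, upper]`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd > 0)
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
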