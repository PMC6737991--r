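#' Gross return above fertilizer cost
#'
#' Gross return is grain yield times the farmgate price of unmilled
#' rice (the price is US$ per kg, yield Mg/ha, hence the factor 1000);
#' GRF is gross return minus the total fertilizer cost.
#'
#' @param grain_yield Mg/ha at 14% moisture
#' @param prices a [price_set()] (or a bare paddy price in US$/kg)
#' @param tfc total fertilizer cost, US$/ha
#' @param fn_applied fertilizer N applied, kg/ha (for PFP; `NA` to skip)
#' @return object of class `economics_result` with fields
#'   `grain_yield`, `fn_applied`, `tfc`, `gross_return`, `grf`, `pfp`
#' @export
#' @examples
#' gross_return_above_fertilizer_cost(5.5, price_set(0.21), tfc = 88)
gross_return_above_fertilizer_cost <- function(grain_yield, prices, tfc,
                                               fn_applied = NA_real_) {
  paddy <- if (inherits(prices, "price_set")) prices$paddy_price else prices
  if (grain_yield < 0 || tfc < 0 || paddy <= 0)
    stop_input("yield and tfc must be non-negative, price positive")
  gross <- 1000 * grain_yield * paddy
  pfp <- if (is.finite(fn_applied) && fn_applied > 0)
    partial_factor_productivity(grain_yield, fn_applied) else NA_real_
  structure(list(grain_yield = grain_yield, fn_applied = fn_applied,
                 tfc = tfc, gross_return = gross, grf = gross - tfc,
                 pfp = pfp),
            class = "economics_result")
}

#' Added net benefit of one treatment over another
#'
#' The difference in gross return above fertilizer cost (GRF) between
#' two treatments evaluated at the same price set.  Antisymmetric.
#'
#' @param grf_a,grf_b GRF values (US$/ha) or `economics_result` objects
#' @return US$/ha
#' @export
added_net_benefit <- function(grf_a, grf_b) {
  g <- function(x) if (inherits(x, "economics_result")) x$grf else x
  g(grf_a) - g(grf_b)
}

#' Partial factor productivity of fertilizer N
#'
#' PFP = 1000 x GY / FN, in kg grain per kg N.
#'
#' @param grain_yield Mg/ha
#' @param fn fertilizer N, kg/ha (> 0)
#' @return kg grain per kg N
#' @export
#' @examples
#' partial_factor_productivity(4, 80)  # 50
partial_factor_productivity <- function(grain_yield, fn) {
  if (any(fn <= 0))
    stop_input("PFP undefined for fn <= 0")
  1000 * grain_yield / fn
}

#' Exceedance probabilities of added net benefit
#'
#' For each threshold t, the fraction of values at or above t (the
#' cumulative probability of exceeding an added net benefit).  The
#' comparison is inclusive.
#'
#' @param values numeric vector (e.g. per-trial ANB, US$/ha)
#' @param thresholds numeric vector of thresholds
#' @return data.frame with columns `threshold` and `probability`
#' @export
#' @examples
#' exceedance_curve(c(-5, 10, 30, 50), thresholds = c(0, 25))
exceedance_curve <- function(values, thresholds) {
  if (length(values) == 0) stop_input("empty value list")
  p <- vapply(thresholds, function(t) mean(values >= t), numeric(1))
  data.frame(threshold = thresholds, probability = p)
}
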