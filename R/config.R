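#' Engine configuration
#'
#' Bundles every calibration constant and rule parameter of the
#' nutrient-management engine into one auditable record.  The defaults
#' are the Odisha calibration: the fertilizer-N line rises from 57 kg
#' N/ha at a 3 Mg/ha target yield to 123 kg N/ha at 6 Mg/ha; fertilizer
#' K uses a 15% yield gain from applied K and a recovery efficiency of
#' 0.44 kg/kg; the P input-output balance assumes 15% of above-ground
#' biomass retained and 70% of plant P in the grain; total K up to 33
#' kg/ha is applied basal; zinc sulfate is a flat 25 kg/ha policy.
#'
#' @param ty_uplift Mg/ha added to the farmer-reported historical yield
#'   when setting the target yield (default 0.5, the observed mean
#'   GY_T - GY_R gap).
#' @param ty_min,ty_max bounds on the target yield, Mg/ha (3.0, 6.5).
#' @param late_penalty_per_week Mg/ha of target yield removed per week
#'   of transplanting delay beyond the critical date.
#' @param n_calibration_anchors matrix-like of (target yield Mg/ha,
#'   kg N/ha) pairs, strictly increasing in both coordinates.
#' @param n_split_fractions three fractions of total N applied basal,
#'   at mid-tillering and at panicle initiation; must sum to 1.
#' @param rie_p,rie_k reciprocal internal efficiencies: kg P (K) taken
#'   up by the mature crop per Mg of grain yield.
#' @param grain_p_fraction fraction of total plant P in harvested grain.
#' @param residue_biomass_fraction fraction of above-ground biomass
#'   retained in the field after harvest (engine default assumption).
#' @param straw_p_fraction fraction of plant P in the straw
#'   (1 - grain_p_fraction by default).
#' @param k_yield_gain_fraction assumed fractional yield increase from
#'   applied K.
#' @param k_recovery_efficiency recovery efficiency of fertilizer K,
#'   kg taken up per kg applied.
#' @param k_basal_threshold kg K/ha at or below which all K goes basal.
#' @param pi_offset_days days before maturity at panicle initiation.
#' @param basal_window_map named list with `duration` (days) and `dat`
#'   (days after transplanting): endpoints of the linear map from
#'   variety duration to the basal application deadline.
#' @param zinc_sulfate_rate kg/ha of zinc sulfate applied basal under
#'   the flat zinc policy.
#' @param bfr_rates named vector of the blanket recommendation's
#'   elemental rates, kg/ha.
#' @param bfr_n_split_fractions the blanket recommendation's N split.
#'
#' @return an object of class `engine_config`
#' @export
#' @examples
#' cfg <- engine_config()
#' n_rate(4.5, cfg)
engine_config <- function(ty_uplift = 0.5,
                          ty_min = 3.0,
                          ty_max = 6.5,
                          late_penalty_per_week = 0.25,
                          n_calibration_anchors = cbind(ty = c(3, 6),
                                                        n = c(57, 123)),
                          n_split_fractions = c(0.30, 0.30, 0.40),
                          rie_p = 2.6,
                          grain_p_fraction = 0.70,
                          residue_biomass_fraction = 0.15,
                          straw_p_fraction = 1 - grain_p_fraction,
                          k_yield_gain_fraction = 0.15,
                          rie_k = 14.5,
                          k_recovery_efficiency = 0.44,
                          k_basal_threshold = 33,
                          pi_offset_days = 60,
                          basal_window_map = list(duration = c(100, 160),
                                                  dat = c(5, 21)),
                          zinc_sulfate_rate = 25,
                          bfr_rates = c(n = 80, p = 17, k = 33),
                          bfr_n_split_fractions = c(0.20, 0.50, 0.30)) {
  cfg <- list(
    ty_uplift = ty_uplift, ty_min = ty_min, ty_max = ty_max,
    late_penalty_per_week = late_penalty_per_week,
    n_calibration_anchors = n_calibration_anchors,
    n_split_fractions = n_split_fractions,
    rie_p = rie_p, grain_p_fraction = grain_p_fraction,
    residue_biomass_fraction = residue_biomass_fraction,
    straw_p_fraction = straw_p_fraction,
    k_yield_gain_fraction = k_yield_gain_fraction,
    rie_k = rie_k, k_recovery_efficiency = k_recovery_efficiency,
    k_basal_threshold = k_basal_threshold,
    pi_offset_days = pi_offset_days,
    basal_window_map = basal_window_map,
    zinc_sulfate_rate = zinc_sulfate_rate,
    bfr_rates = bfr_rates,
    bfr_n_split_fractions = bfr_n_split_fractions
  )
  class(cfg) <- "engine_config"
  validate_engine_config(cfg)
  cfg
}

validate_engine_config <- function(cfg) {
  a <- cfg$n_calibration_anchors
  if (nrow(a) < 2 || any(diff(a[, 1]) <= 0) || any(diff(a[, 2]) <= 0))
    stop_input("n_calibration_anchors must be >= 2 pairs, strictly ",
               "increasing in both coordinates")
  if (abs(sum(cfg$n_split_fractions) - 1) > 1e-9)
    stop_input("n_split_fractions must sum to 1")
  if (length(cfg$n_split_fractions) != 3L)
    stop_input("n_split_fractions must have length 3")
  if (cfg$ty_min >= cfg$ty_max) stop_input("ty_min must be < ty_max")
  nonneg <- c("ty_uplift", "late_penalty_per_week", "rie_p", "rie_k",
              "grain_p_fraction", "residue_biomass_fraction",
              "straw_p_fraction", "k_yield_gain_fraction",
              "k_basal_threshold", "zinc_sulfate_rate")
  for (nm in nonneg)
    if (cfg[[nm]] < 0) stop_input(nm, " must be non-negative")
  if (cfg$k_recovery_efficiency <= 0)
    stop_input("k_recovery_efficiency must be > 0")
  if (abs(sum(cfg$bfr_n_split_fractions) - 1) > 1e-9)
    stop_input("bfr_n_split_fractions must sum to 1")
  invisible(cfg)
}

#' @export
print.engine_config <- function(x, ...) {
  cat("Nutrient-management engine configuration\n")
  cat(sprintf("  target yield: GY_R + %.2f Mg/ha, bounds [%.1f, %.1f]\n",
              x$ty_uplift, x$ty_min, x$ty_max))
  cat(sprintf("  late-transplanting penalty: %.2f Mg/ha per week\n",
              x$late_penalty_per_week))
  a <- x$n_calibration_anchors
  cat("  N calibration anchors (TY Mg/ha -> kg N/ha): ",
      paste(sprintf("%.1f -> %.0f", a[, 1], a[, 2]), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  N split fractions: %s\n",
              paste(format(x$n_split_fractions), collapse = "/")))
  cat(sprintf("  P balance: rie_p %.2f kg/Mg, grain P fraction %.2f,\n",
              x$rie_p, x$grain_p_fraction))
  cat(sprintf("    residue biomass retained %.2f, straw P fraction %.2f\n",
              x$residue_biomass_fraction, x$straw_p_fraction))
  cat(sprintf("  K: yield gain %.2f, rie_k %.1f kg/Mg, recovery %.2f kg/kg,\n",
              x$k_yield_gain_fraction, x$rie_k, x$k_recovery_efficiency))
  cat(sprintf("    all-basal threshold %.0f kg K/ha\n", x$k_basal_threshold))
  cat(sprintf("  phenology: PI at duration - %d d; basal window %d-%d DAT\n",
              x$pi_offset_days, x$basal_window_map$dat[1],
              x$basal_window_map$dat[2]))
  cat(sprintf("  zinc sulfate policy: %.0f kg/ha basal\n",
              x$zinc_sulfate_rate))
  cat(sprintf("  blanket recommendation: N %.0f / P %.0f / K %.0f kg/ha, N split %s\n",
              x$bfr_rates["n"], x$bfr_rates["p"], x$bfr_rates["k"],
              paste(format(x$bfr_n_split_fractions), collapse = "/")))
  invisible(x)
}

#' Read or write an engine configuration as YAML
#'
#' @param path file path
#' @return `read_engine_config()` returns an `engine_config`;
#'   `write_engine_config()` returns `path` invisibly.
#' @export
read_engine_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$n_calibration_anchors))
    raw$n_calibration_anchors <- do.call(cbind, raw$n_calibration_anchors)
  if (!is.null(raw$bfr_rates)) raw$bfr_rates <- unlist(raw$bfr_rates)
  known <- names(formals(engine_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_input("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(engine_config, raw)
}

#' @rdname read_engine_config
#' @param cfg an `engine_config`
#' @export
write_engine_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$n_calibration_anchors <- list(ty = out$n_calibration_anchors[, 1],
                                    n = out$n_calibration_anchors[, 2])
  out$bfr_rates <- as.list(out$bfr_rates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Farmgate price set for the economic analysis
#'
#' @param paddy_price US$ per kg of unmilled rice (0.21 for most
#'   season-years, 0.22 for the 2015 wet season).
#' @param exchange_rate Indian rupees per US$ (65, fixed).
#' @return object of class `price_set`
#' @export
price_set <- function(paddy_price = 0.21, exchange_rate = 65) {
  if (paddy_price <= 0 || exchange_rate <= 0)
    stop_input("prices must be positive")
  structure(list(paddy_price = paddy_price, exchange_rate = exchange_rate),
            class = "price_set")
}
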