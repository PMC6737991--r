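#' Set the target yield for a field
#'
#' The target yield GY_T starts at the farmer's reported historical
#' yield plus a fixed uplift, is capped by an optional per-variety
#' ceiling, is reduced for transplanting delayed beyond the critical
#' date, and is finally clamped to the engine's admissible range
#' (3.0-6.5 Mg/ha by default).
#'
#' @param interview a [farmer_interview()]
#' @param cfg an [engine_config()]
#' @return target yield, Mg/ha
#' @export
#' @examples
#' iv <- farmer_interview("x", historical_yield_GYR = 4.6)
#' set_target_yield(iv, engine_config())  # 5.1
set_target_yield <- function(interview, cfg = engine_config()) {
  gyr <- interview$historical_yield_GYR
  if (!is.finite(gyr) || gyr <= 0)
    stop_input("historical_yield_GYR must be positive")
  ty <- gyr + cfg$ty_uplift
  if (is.finite(interview$variety_yield_ceiling))
    ty <- min(ty, interview$variety_yield_ceiling)
  ty <- ty - cfg$late_penalty_per_week * interview$transplant_delay_days / 7
  clamp(ty, cfg$ty_min, cfg$ty_max)
}

#' Fertilizer N rate from the yield-gain calibration line
#'
#' Piecewise-linear interpolation through the calibration anchors;
#' outside the anchors' hull (but inside the admissible target-yield
#' range) the terminal segment is extrapolated.  With the default two
#' anchors this is the single line FN = 57 + 22 (GY_T - 3).
#'
#' @param target_yield Mg/ha, within `[ty_min, ty_max]`
#' @param cfg an [engine_config()]
#' @return kg N/ha (vectorised over `target_yield`)
#' @export
n_rate <- function(target_yield, cfg = engine_config()) {
  if (any(target_yield < cfg$ty_min - 1e-9 | target_yield > cfg$ty_max + 1e-9))
    stop_input("target yield outside [", cfg$ty_min, ", ", cfg$ty_max, "]")
  a <- cfg$n_calibration_anchors
  ty <- a[, 1]
  n <- a[, 2]
  k <- nrow(a)
  vapply(target_yield, function(x) {
    if (x <= ty[1])
      return(n[1] + (n[2] - n[1]) / (ty[2] - ty[1]) * (x - ty[1]))
    if (x >= ty[k])
      return(n[k] + (n[k] - n[k - 1]) / (ty[k] - ty[k - 1]) * (x - ty[k]))
    stats::approx(ty, n, xout = x)$y
  }, numeric(1))
}

#' Growth-stage schedule in days after transplanting
#'
#' Panicle initiation (PI) is placed a fixed offset before maturity, so
#' PI in days after transplanting (DAT) is
#' `duration - pi_offset - seedling_age`; mid-tillering is half way to
#' PI; and the deadline for the basal application scales linearly with
#' variety duration between 5 DAT (shortest) and 21 DAT (longest).
#'
#' @param growth_duration_days variety duration, days
#' @param seedling_age_days seedling age at transplanting, days
#' @param cfg an [engine_config()]
#' @return named numeric vector `c(basal, mid_tillering,
#'   panicle_initiation)`, strictly increasing DATs
#' @export
#' @examples
#' stage_schedule(140, 25)  # basal 16, MT 28, PI 55
stage_schedule <- function(growth_duration_days, seedling_age_days,
                           cfg = engine_config()) {
  pi_dat <- growth_duration_days - cfg$pi_offset_days - seedling_age_days
  mt_dat <- round(pi_dat / 2)
  bw <- cfg$basal_window_map
  slope <- diff(bw$dat) / diff(bw$duration)
  basal <- round(bw$dat[1] + slope * (growth_duration_days - bw$duration[1]))
  basal <- clamp(basal, min(bw$dat), max(bw$dat))
  out <- c(basal = basal, mid_tillering = mt_dat,
           panicle_initiation = pi_dat)
  if (any(diff(out) <= 0))
    stop_input("variety too short for this seedling age: schedule ",
               paste(sprintf("%s=%d", names(out), out), collapse = ", "),
               " is not strictly increasing")
  out
}

#' Split a total N rate across the three application stages
#'
#' The first two splits are the configured fractions of the total; the
#' final (panicle initiation) split absorbs any rounding so the three
#' amounts sum to the total exactly.
#'
#' @param fn total fertilizer N, kg/ha
#' @param cfg an [engine_config()]
#' @param fractions optional override of the three split fractions
#' @return numeric vector of three stage amounts, kg N/ha
#' @export
n_split_amounts <- function(fn, cfg = engine_config(),
                            fractions = cfg$n_split_fractions) {
  if (fn < 0) stop_input("fn must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_input("split fractions must sum to 1")
  a <- fn * fractions[1:2]
  c(a, fn - sum(a))
}

#' Fertilizer P rate from the nutrient input-output balance
#'
#' P required for the target yield is the P taken up by the mature crop
#' (rie_p kg per Mg grain) minus the P returned with retained residues
#' of the previous crop (straw holds `straw_p_fraction` of plant P, of
#' which `residue_retained_fraction` is retained).  Never negative.
#'
#' @param target_yield Mg/ha
#' @param previous_crop_yield Mg/ha (0 = no credit)
#' @param residue_retained_fraction fraction of previous-crop straw
#'   retained in the field
#' @param cfg an [engine_config()]
#' @return kg P/ha (elemental)
#' @export
p_rate <- function(target_yield, previous_crop_yield = 0,
                   residue_retained_fraction = cfg$residue_biomass_fraction,
                   cfg = engine_config()) {
  if (any(previous_crop_yield < 0))
    stop_input("previous_crop_yield must be non-negative")
  uptake <- cfg$rie_p * target_yield
  credit <- residue_retained_fraction * cfg$straw_p_fraction * cfg$rie_p *
    previous_crop_yield
  pmax(0, uptake - credit)
}

#' Fertilizer K rate from the yield-gain approach
#'
#' The K taken up to realise an assumed fractional yield gain from
#' applied K (`k_yield_gain_fraction` of the target yield, at `rie_k`
#' kg K per Mg grain) divided by the recovery efficiency of fertilizer
#' K.
#'
#' @param target_yield Mg/ha
#' @param cfg an [engine_config()]
#' @return kg K/ha (elemental)
#' @export
k_rate <- function(target_yield, cfg = engine_config()) {
  if (cfg$k_recovery_efficiency <= 0)
    stop_input("k_recovery_efficiency must be positive")
  cfg$k_yield_gain_fraction * target_yield * cfg$rie_k /
    cfg$k_recovery_efficiency
}

#' Split a total K rate between basal and panicle initiation
#'
#' All K is applied basal when the total is at or below the basal
#' threshold (33 kg K/ha by default); above it, K is split 50% basal
#' and 50% at panicle initiation.
#'
#' @param fk total fertilizer K, kg/ha
#' @param cfg an [engine_config()]
#' @return named numeric vector of one (`basal`) or two (`basal`,
#'   `panicle_initiation`) amounts summing to `fk`
#' @export
k_split_amounts <- function(fk, cfg = engine_config()) {
  if (fk < 0) stop_input("fk must be non-negative")
  if (fk <= cfg$k_basal_threshold) c(basal = fk)
  else c(basal = fk / 2, panicle_initiation = fk / 2)
}

#' Build the full field-specific nutrient prescription
#'
#' Composes the target-yield rule, the N/P/K rate calculations and the
#' growth-stage scheduling into one prescription for a field: total
#' elemental rates plus dated split schedules.
#'
#' @param interview a [farmer_interview()]
#' @param cfg an [engine_config()]
#' @return object of class `nutrient_prescription` with elements
#'   `target_yield`, `fn`, `fp`, `fk`, `schedule`, and the split tables
#'   `n_splits`, `p_split`, `k_splits` (columns `stage`, `dat`,
#'   `kg_per_ha`)
#' @export
#' @examples
#' iv <- farmer_interview("F001", historical_yield_GYR = 4.6,
#'                        growth_duration_days = 140,
#'                        seedling_age_days = 25,
#'                        previous_crop_yield = 4.5)
#' build_prescription(iv)
build_prescription <- function(interview, cfg = engine_config()) {
  validate_interview(interview)
  ty <- set_target_yield(interview, cfg)
  fn <- n_rate(ty, cfg)
  fp <- p_rate(ty, interview$previous_crop_yield,
               interview$residue_retained_fraction, cfg)
  fk <- k_rate(ty, cfg)
  sched <- stage_schedule(interview$growth_duration_days,
                          interview$seedling_age_days, cfg)
  n_amt <- n_split_amounts(fn, cfg)
  n_splits <- data.frame(stage = names(sched), dat = unname(sched),
                         kg_per_ha = n_amt, stringsAsFactors = FALSE)
  k_amt <- k_split_amounts(fk, cfg)
  k_splits <- data.frame(stage = names(k_amt),
                         dat = unname(sched[names(k_amt)]),
                         kg_per_ha = unname(k_amt),
                         stringsAsFactors = FALSE)
  p_split <- data.frame(stage = "basal", dat = unname(sched["basal"]),
                        kg_per_ha = fp, stringsAsFactors = FALSE)
  out <- list(field_id = interview$field_id, target_yield = ty,
              fn = fn, fp = fp, fk = fk, schedule = sched,
              n_splits = n_splits, p_split = p_split, k_splits = k_splits)
  class(out) <- "nutrient_prescription"
  validate_prescription(out, cfg)
  out
}

validate_prescription <- function(p, cfg = engine_config()) {
  if (p$target_yield < cfg$ty_min - 1e-9 || p$target_yield > cfg$ty_max + 1e-9)
    stop_input("target yield outside admissible range")
  if (min(p$fn, p$fp, p$fk) < 0) stop_input("negative nutrient rate")
  if (abs(sum(p$n_splits$kg_per_ha) - p$fn) > 1e-6)
    stop_input("N splits do not sum to FN")
  if (abs(sum(p$k_splits$kg_per_ha) - p$fk) > 1e-6)
    stop_input("K splits do not sum to FK")
  invisible(p)
}

#' @export
print.nutrient_prescription <- function(x, ...) {
  cat(sprintf("Nutrient prescription for field %s\n", x$field_id))
  cat(sprintf("  target yield %.1f Mg/ha; N %.1f, P %.1f, K %.1f kg/ha\n",
              x$target_yield, x$fn, x$fp, x$fk))
  cat("  N splits:\n")
  for (i in seq_len(nrow(x$n_splits)))
    cat(sprintf("    %-18s %3d DAT  %6.1f kg N/ha\n", x$n_splits$stage[i],
                x$n_splits$dat[i], x$n_splits$kg_per_ha[i]))
  cat(sprintf("  P: %.1f kg/ha basal (%d DAT)\n", x$fp, x$p_split$dat[1]))
  cat("  K splits:\n")
  for (i in seq_len(nrow(x$k_splits)))
    cat(sprintf("    %-18s %3d DAT  %6.1f kg K/ha\n", x$k_splits$stage[i],
                x$k_splits$dat[i], x$k_splits$kg_per_ha[i]))
  invisible(x)
}
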