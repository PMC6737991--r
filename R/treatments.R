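new_treatment_plan <- function(label, applications, products,
                               zinc_sulfate = 0, prescription = NULL) {
  applications <- applications[order(applications$dat), , drop = FALSE]
  rownames(applications) <- NULL
  totals <- delivered_nutrients(applications, products)
  plan <- list(label = label, applications = applications,
               totals = totals, zinc_sulfate = zinc_sulfate,
               tfc = total_fertilizer_cost(applications, products),
               prescription = prescription)
  class(plan) <- "treatment_plan"
  plan
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("%s treatment plan: N %.1f / P %.1f / K %.1f kg/ha, TFC %.2f US$/ha\n",
              x$label, x$totals["n"], x$totals["p"], x$totals["k"], x$tfc))
  for (i in seq_len(nrow(x$applications)))
    cat(sprintf("  %3d DAT  %-14s %7.1f kg/ha\n", x$applications$dat[i],
                x$applications$product[i], x$applications$amount_kg_ha[i]))
  invisible(x)
}

# minimal prescription-shaped object for fixed-rate plans
manual_prescription <- function(fn, fp, fk, schedule, n_fractions,
                                k_amounts) {
  n_amt <- c(fn * n_fractions[1:2], fn - sum(fn * n_fractions[1:2]))
  structure(list(
    field_id = NA_character_, target_yield = NA_real_,
    fn = fn, fp = fp, fk = fk, schedule = schedule,
    n_splits = data.frame(stage = names(schedule),
                          dat = unname(schedule), kg_per_ha = n_amt,
                          stringsAsFactors = FALSE),
    p_split = data.frame(stage = "basal", dat = unname(schedule["basal"]),
                         kg_per_ha = fp, stringsAsFactors = FALSE),
    k_splits = data.frame(stage = names(k_amounts),
                          dat = unname(schedule[names(k_amounts)]),
                          kg_per_ha = unname(k_amounts),
                          stringsAsFactors = FALSE)),
    class = "nutrient_prescription")
}

#' Build the field-specific (RCM-style) treatment plan
#'
#' Runs the engine on the interview, allocates the prescription to the
#' farmer's products and prices the plan.  Zinc sulfate is applied
#' basal at the flat policy rate.
#'
#' @param interview a [farmer_interview()]
#' @param products product table
#' @param cfg an [engine_config()]
#' @return a `treatment_plan` labelled `"RCM"`
#' @export
build_rcm_plan <- function(interview, products, cfg = engine_config()) {
  presc <- build_prescription(interview, cfg)
  alloc <- allocate_products(presc, products, cfg, zinc = TRUE)
  new_treatment_plan("RCM", alloc$applications, products,
                     zinc_sulfate = alloc$zinc_sulfate,
                     prescription = presc)
}

#' Build the blanket fertilizer recommendation (BFR) plan
#'
#' Fixed elemental rates (80 kg N, 17 kg P, 33 kg K per ha by default)
#' for every field: N split 20% basal / 50% at tillering / 30% at
#' panicle initiation, all P basal, K 50% basal / 50% at panicle
#' initiation, plus 25 kg/ha zinc sulfate basal.  Timings follow the
#' variety's stage schedule when an interview is supplied; the nutrient
#' totals are invariant to the interview (the blanket property).
#'
#' @param interview optional [farmer_interview()] (timings only)
#' @param products product table
#' @param cfg an [engine_config()]
#' @return a `treatment_plan` labelled `"BFR"`
#' @export
build_bfr_plan <- function(interview = NULL, products,
                           cfg = engine_config()) {
  schedule <- if (is.null(interview))
    c(basal = 10, mid_tillering = 25, panicle_initiation = 45)
  else stage_schedule(interview$growth_duration_days,
                      interview$seedling_age_days, cfg)
  r <- cfg$bfr_rates
  presc <- manual_prescription(
    fn = unname(r["n"]), fp = unname(r["p"]), fk = unname(r["k"]),
    schedule = schedule, n_fractions = cfg$bfr_n_split_fractions,
    k_amounts = c(basal = unname(r["k"]) / 2,
                  panicle_initiation = unname(r["k"]) / 2))
  alloc <- allocate_products(presc, products, cfg, zinc = TRUE)
  new_treatment_plan("BFR", alloc$applications, products,
                     zinc_sulfate = alloc$zinc_sulfate,
                     prescription = presc)
}

#' Build the farmers' fertilizer practice (FFP) plan
#'
#' Mirrors the practice the farmer stated before seeing any
#' recommendation: a verbatim list of (DAT, product, amount)
#' applications.  Zinc sulfate is included only when the farmer
#' reported applying it.  Timings are kept as raw DAT.
#'
#' @param planned_practice data.frame with columns `dat`, `product`,
#'   `amount_kg_ha`
#' @param farmer_applies_zinc logical
#' @param products product table
#' @param cfg an [engine_config()] (zinc rate only)
#' @return a `treatment_plan` labelled `"FFP"`
#' @export
build_ffp_plan <- function(planned_practice, farmer_applies_zinc = FALSE,
                           products, cfg = engine_config()) {
  if (nrow(planned_practice) == 0) stop_input("empty practice list")
  unknown <- setdiff(planned_practice$product, products$name)
  if (length(unknown))
    stop_input("unknown product name: ", paste(unknown, collapse = ", "))
  apps <- data.frame(stage = "farmer", dat = planned_practice$dat,
                     product = planned_practice$product,
                     amount_kg_ha = planned_practice$amount_kg_ha,
                     stringsAsFactors = FALSE)
  zinc_kg <- 0
  if (isTRUE(farmer_applies_zinc) && cfg$zinc_sulfate_rate > 0) {
    zinc_kg <- cfg$zinc_sulfate_rate
    apps <- rbind(apps, data.frame(stage = "farmer", dat = min(apps$dat),
                                   product = "zinc_sulfate",
                                   amount_kg_ha = zinc_kg,
                                   stringsAsFactors = FALSE))
  }
  new_treatment_plan("FFP", apps, products, zinc_sulfate = zinc_kg)
}

#' Elemental N applied in the three reporting stage windows
#'
#' Bins a plan's N applications by days after transplanting into the
#' windows used for stage-wise reporting: at or before 20 DAT, 21-35
#' DAT, and after 35 DAT.
#'
#' @param plan a `treatment_plan`
#' @param products product table
#' @return named numeric vector of kg N/ha in the three windows
#' @export
n_by_stage_window <- function(plan, products) {
  apps <- plan$applications
  nfrac <- elemental_fractions(products)[match(apps$product, products$name),
                                         "n"]
  n_kg <- apps$amount_kg_ha * nfrac
  c(dat_le_20 = sum(n_kg[apps$dat <= 20]),
    dat_21_35 = sum(n_kg[apps$dat > 20 & apps$dat <= 35]),
    dat_gt_35 = sum(n_kg[apps$dat > 35]))
}

#' Assemble a trial record
#'
#' One on-farm trial: the interview, the three treatment plans, the
#' (measured or simulated) grain yields, and the price set.
#'
#' @param interview a [farmer_interview()]
#' @param plans named list with elements `RCM`, `FFP`, `BFR`
#' @param yields named numeric vector of Mg/ha with the same names
#' @param prices a [price_set()]
#' @param model optional response-model parameters (kept for parameter
#'   recovery checks on simulated cohorts)
#' @return object of class `trial_record`
#' @export
trial_record <- function(interview, plans, yields, prices = price_set(),
                         model = NULL) {
  need <- c("RCM", "FFP", "BFR")
  if (!all(need %in% names(plans)))
    stop_input("plans must include RCM, FFP and BFR")
  if (!all(need %in% names(yields)))
    stop_input("yields must include RCM, FFP and BFR")
  if (any(yields < 0)) stop_input("yields must be non-negative")
  structure(list(interview = interview, plans = plans[need],
                 yields = yields[need], prices = prices, model = model),
            class = "trial_record")
}

#' Per-trial economics and treatment contrasts
#'
#' Computes an economics result (TFC, gross return, GRF, PFP) for each
#' of the three treatments and the three pairwise added-net-benefit
#' contrasts RCM-FFP, RCM-BFR and BFR-FFP.
#'
#' @param trial a [trial_record()]
#' @return list with `economics` (one row per treatment) and
#'   `contrasts` (named numeric, US$/ha)
#' @export
evaluate_trial <- function(trial) {
  econ <- lapply(names(trial$plans), function(lbl) {
    plan <- trial$plans[[lbl]]
    y <- trial$yields[[lbl]]
    if (!is.finite(y)) stop_input("missing yield for ", lbl)
    e <- gross_return_above_fertilizer_cost(
      y, trial$prices, plan$tfc, fn_applied = unname(plan$totals["n"]))
    data.frame(treatment = lbl, grain_yield = y,
               n_rate = unname(plan$totals["n"]),
               p_rate = unname(plan$totals["p"]),
               k_rate = unname(plan$totals["k"]),
               tfc = plan$tfc, gross_return = e$gross_return,
               grf = e$grf, pfp = e$pfp, stringsAsFactors = FALSE)
  })
  econ <- do.call(rbind, econ)
  grf <- stats::setNames(econ$grf, econ$treatment)
  contrasts <- c(RCM_FFP = added_net_benefit(grf["RCM"], grf["FFP"]),
                 RCM_BFR = added_net_benefit(grf["RCM"], grf["BFR"]),
                 BFR_FFP = added_net_benefit(grf["BFR"], grf["FFP"]))
  names(contrasts) <- c("RCM_FFP", "RCM_BFR", "BFR_FFP")
  list(economics = econ, contrasts = contrasts)
}

#' Summarize a cohort of trials
#'
#' Group means by season and year of the N/P/K rates, TFC, yield and
#' PFP per treatment; mean added-net-benefit contrasts; and exceedance
#' probabilities of the RCM-FFP and BFR-FFP contrasts at the supplied
#' thresholds, by season.
#'
#' @param trials list of [trial_record()]
#' @param thresholds US$/ha thresholds for the exceedance curves
#' @return list with `treatment_means`, `contrast_means`, `exceedance`,
#'   and the per-trial long table `trial_table`
#' @export
summarize_cohort <- function(trials, thresholds = c(0, 25)) {
  if (length(trials) == 0) stop_input("no trials")
  rows <- lapply(trials, function(tr) {
    ev <- evaluate_trial(tr)
    cbind(field_id = tr$interview$field_id, season = tr$interview$season,
          year = tr$interview$year, ev$economics,
          anb_rcm_ffp = ev$contrasts[["RCM_FFP"]],
          anb_rcm_bfr = ev$contrasts[["RCM_BFR"]],
          anb_bfr_ffp = ev$contrasts[["BFR_FFP"]],
          stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  treatment_means <- stats::aggregate(
    cbind(n_rate, p_rate, k_rate, tfc, grain_yield, pfp) ~
      season + year + treatment, data = tab, FUN = mean)
  per_trial <- tab[tab$treatment == "RCM",
                   c("season", "year", "anb_rcm_ffp", "anb_rcm_bfr",
                     "anb_bfr_ffp")]
  contrast_means <- stats::aggregate(
    cbind(anb_rcm_ffp, anb_rcm_bfr, anb_bfr_ffp) ~ season + year,
    data = per_trial, FUN = mean)
  exc <- do.call(rbind, lapply(split(per_trial, per_trial$season),
                               function(d) {
    rbind(cbind(season = d$season[1], contrast = "RCM_FFP",
                exceedance_curve(d$anb_rcm_ffp, thresholds)),
          cbind(season = d$season[1], contrast = "BFR_FFP",
                exceedance_curve(d$anb_bfr_ffp, thresholds)))
  }))
  rownames(exc) <- NULL
  list(treatment_means = treatment_means, contrast_means = contrast_means,
       exceedance = exc, trial_table = tab)
}
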