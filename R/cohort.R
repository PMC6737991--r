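#' Specification of a synthetic farmer cohort
#'
#' Defines the statistical structure of a generated cohort of on-farm
#' trials: cohort size and stratification (season, year, agro-climatic
#' zone, water regime), the distribution of farmer-reported historical
#' yields, a variety table spanning short/medium/long durations with
#' season-consistent availability (long-duration varieties in the wet
#' season only, short-duration in the dry season only), the farmers'
#' fertilizer-practice rate distributions, and the yield-response model
#' parameters.  A fixed seed makes the whole cohort bit-identical
#' across runs.
#'
#' @param n_trials number of trials (default 209)
#' @param seed integer RNG seed
#' @param season_mix,year_mix,acz_mix categorical sampling weights
#' @param kharif_irrigated_prob probability a wet-season trial is
#'   irrigated (dry-season trials are always irrigated)
#' @param gyr_mean,gyr_sd,gyr_bounds truncated-normal parameters of the
#'   historical yield, Mg/ha
#' @param n_varieties_per_class varieties generated per duration class
#' @param seedling_age_range days, sampled uniformly (integers)
#' @param delay_prob,delay_range probability of late transplanting and
#'   the day range of the delay
#' @param ffp_n_mean,ffp_n_sd,ffp_n_bounds per-season truncated-normal
#'   parameters of the farmers' total N rate, kg/ha
#' @param ffp_p_mean,ffp_p_sd,ffp_p_bounds farmers' P rate, kg/ha
#' @param ffp_k_mean,ffp_k_sd,ffp_k_bounds farmers' K rate, kg/ha
#' @param ffp_n_apps_probs probabilities of 1, 2 and 3 N applications
#' @param ffp_zinc_probability probability the farmer applies zinc
#' @param ae_range agronomic efficiency range, Mg grain per kg N
#' @param headroom_range Mg/ha added to the historical yield to get the
#'   field's potential yield
#' @param typical_ffp_n per-season typical farmer N rate used to derive
#'   the zero-N base yield from the historical yield
#' @param zinc_responsive_prob probability a field is zinc-responsive
#' @param zinc_penalty Mg/ha lost on a responsive field with no zinc
#' @param noise_sd yield noise standard deviation, Mg/ha
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_trials = 209,
                        seed = 1L,
                        season_mix = c(kharif = 108 / 209, rabi = 101 / 209),
                        year_mix = list(
                          kharif = c("2014" = 84 / 108, "2015" = 24 / 108),
                          rabi = c("2013-2014" = 39 / 101,
                                   "2014-2015" = 62 / 101)),
                        acz_mix = stats::setNames(
                          c(66, 10, 58, 54, 11, 10) / 209, ACZ_LEVELS),
                        kharif_irrigated_prob = 48 / 108,
                        gyr_mean = 4.4, gyr_sd = 0.7,
                        gyr_bounds = c(1.7, 6.3),
                        n_varieties_per_class = 8,
                        seedling_age_range = c(18, 32),
                        delay_prob = 0.12, delay_range = c(7, 28),
                        ffp_n_mean = c(kharif = 75, rabi = 98),
                        ffp_n_sd = c(kharif = 25, rabi = 35),
                        ffp_n_bounds = list(kharif = c(10, 200),
                                            rabi = c(14, 252)),
                        ffp_p_mean = 22, ffp_p_sd = 14,
                        ffp_p_bounds = c(0, 64),
                        ffp_k_mean = 44, ffp_k_sd = 30,
                        ffp_k_bounds = c(0, 156),
                        ffp_n_apps_probs = c(0.05, 0.20, 0.75),
                        ffp_zinc_probability = 0.05,
                        ae_range = c(0.010, 0.025),
                        headroom_range = c(0.5, 2.5),
                        typical_ffp_n = c(kharif = 75, rabi = 98),
                        zinc_responsive_prob = 0.3,
                        zinc_penalty = 0.4,
                        noise_sd = 0.3) {
  spec <- as.list(environment())
  if (abs(sum(season_mix) - 1) > 1e-9 || abs(sum(acz_mix) - 1) > 1e-9)
    stop_input("categorical weights must sum to 1")
  for (s in names(year_mix))
    if (abs(sum(year_mix[[s]]) - 1) > 1e-9)
      stop_input("year weights must sum to 1")
  if (abs(sum(ffp_n_apps_probs) - 1) > 1e-9)
    stop_input("ffp_n_apps_probs must sum to 1")
  if (gyr_bounds[1] >= gyr_bounds[2]) stop_input("gyr_bounds out of order")
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  class(spec) <- "cohort_spec"
  spec
}

# 24 named varieties (8 per duration class) with fixed durations spread
# across short (<=120 d), medium (121-140 d) and long (>140 d)
variety_table <- function(spec) {
  k <- spec$n_varieties_per_class
  data.frame(
    variety_name = c(sprintf("short_%02d", seq_len(k)),
                     sprintf("medium_%02d", seq_len(k)),
                     sprintf("long_%02d", seq_len(k))),
    duration_class = rep(c("short", "medium", "long"), each = k),
    growth_duration_days = c(round(seq(100, 120, length.out = k)),
                             round(seq(122, 140, length.out = k)),
                             round(seq(142, 165, length.out = k))),
    stringsAsFactors = FALSE
  )
}

#' Sample a cohort of farmer interviews
#'
#' Draws `n_trials` interviews with the configured stratification.
#' Historical yields follow the truncated normal; variety durations are
#' consistent with season (no long-duration varieties in the dry
#' season, no short-duration in the wet season); the previous crop is
#' taken to be rice with the same yield as the reported historical
#' yield.
#'
#' @param spec a [cohort_spec()]
#' @param set_seed seed the RNG from `spec$seed` (set `FALSE` when the
#'   caller manages the RNG state)
#' @return list of [farmer_interview()]
#' @export
sample_interviews <- function(spec, set_seed = TRUE) {
  if (isTRUE(set_seed)) set.seed(spec$seed)
  vt <- variety_table(spec)
  n <- spec$n_trials
  season <- sample(names(spec$season_mix), n, replace = TRUE,
                   prob = spec$season_mix)
  gyr <- rtruncnorm(n, spec$gyr_mean, spec$gyr_sd, spec$gyr_bounds[1],
                    spec$gyr_bounds[2])
  lapply(seq_len(n), function(i) {
    s <- season[i]
    ym <- spec$year_mix[[s]]
    year <- sample(names(ym), 1, prob = ym)
    acz <- sample(names(spec$acz_mix), 1, prob = spec$acz_mix)
    water <- if (s == "rabi") "irrigated" else
      if (stats::runif(1) < spec$kharif_irrigated_prob) "irrigated" else
        "rainfed"
    classes <- if (s == "kharif") c("medium", "long") else
      c("short", "medium")
    cand <- vt[vt$duration_class %in% classes, ]
    v <- cand[sample.int(nrow(cand), 1), ]
    delay <- if (stats::runif(1) < spec$delay_prob)
      sample(seq(spec$delay_range[1], spec$delay_range[2]), 1) else 0
    # keep seedling age consistent with the variety's phenology: the
    # schedule basal < mid-tillering < panicle initiation must hold
    basal <- round(clamp(5 + (v$growth_duration_days - 100) * 16 / 60,
                         5, 21))
    age_max <- min(spec$seedling_age_range[2],
                   v$growth_duration_days - 60 - (2 * basal + 2))
    farmer_interview(
      field_id = sprintf("SYN%04d", i), district = acz, acz = acz,
      season = s, year = year, water_regime = water,
      variety_name = v$variety_name,
      growth_duration_days = v$growth_duration_days,
      seedling_age_days = sample(seq(spec$seedling_age_range[1],
                                     age_max), 1),
      transplant_delay_days = delay,
      historical_yield_GYR = gyr[i],
      previous_crop_yield = gyr[i],
      residue_retained_fraction = 0.15,
      selected_products = c("urea", "DAP", "MOP"),
      farmer_applies_zinc = stats::runif(1) < spec$ffp_zinc_probability
    )
  })
}

#' Sample a farmer's planned fertilizer practice
#'
#' Total N, P and K are drawn from the season's rate distributions; N
#' is planned in 1-3 applications (probabilities 5/20/75%) with the
#' largest share in the early vegetative window (at or before 20 DAT);
#' P is supplied basally by DAP, K basally by MOP, and the residual N
#' by urea spread over the planned applications (DAP's incidental N
#' scales the urea down proportionally).  Uses the current RNG state.
#'
#' @param interview a [farmer_interview()]
#' @param spec a [cohort_spec()]
#' @param products product table (grades for the conversion to product
#'   amounts)
#' @return data.frame with columns `dat`, `product`, `amount_kg_ha`
#' @export
sample_ffp_practice <- function(interview, spec = cohort_spec(),
                                products = default_products()) {
  s <- interview$season
  fn <- rtruncnorm(1, spec$ffp_n_mean[[s]], spec$ffp_n_sd[[s]],
                   spec$ffp_n_bounds[[s]][1], spec$ffp_n_bounds[[s]][2])
  fp <- rtruncnorm(1, spec$ffp_p_mean, spec$ffp_p_sd,
                   spec$ffp_p_bounds[1], spec$ffp_p_bounds[2])
  fk <- rtruncnorm(1, spec$ffp_k_mean, spec$ffp_k_sd,
                   spec$ffp_k_bounds[1], spec$ffp_k_bounds[2])
  n_apps <- sample(1:3, 1, prob = spec$ffp_n_apps_probs)
  split <- switch(n_apps,
                  list(dat = 10, frac = 1),
                  list(dat = c(10, 30), frac = c(0.60, 0.40)),
                  list(dat = c(10, 28, 45), frac = c(0.45, 0.30, 0.25)))
  frac <- elemental_fractions(products)
  rows <- list()
  add <- function(dat, product, amount) {
    if (amount > 1e-9)
      rows[[length(rows) + 1L]] <<- data.frame(
        dat = dat, product = product, amount_kg_ha = amount,
        stringsAsFactors = FALSE)
  }
  n_credit <- 0
  if (fp > 0) {
    dap <- fp / frac[products$name == "DAP", "p"]
    add(split$dat[1], "DAP", dap)
    n_credit <- dap * frac[products$name == "DAP", "n"]
  }
  if (fk > 0) add(split$dat[1], "MOP", fk / frac[products$name == "MOP", "k"])
  # DAP's incidental N scales the urea down proportionally across the
  # planned applications, so the farmer's split structure is kept
  urea_nfrac <- frac[products$name == "urea", "n"]
  urea_n_total <- max(0, fn - n_credit)
  for (j in seq_len(n_apps))
    add(split$dat[j], "urea", urea_n_total * split$frac[j] / urea_nfrac)
  do.call(rbind, rows)
}

#' Sample a field's yield-response model
#'
#' A linear-plateau response: yield rises from the zero-N base at the
#' field's agronomic efficiency (per kg of effectively timed N) up to
#' the potential yield.  The base is the historical yield minus the
#' response to a typical farmer N rate, so historical yields are
#' internally consistent; the potential is the historical yield plus a
#' sampled headroom.  Uses the current RNG state.
#'
#' @param interview a [farmer_interview()]
#' @param spec a [cohort_spec()]
#' @param cfg an [engine_config()] (phenology for the timing window)
#' @return list of response-model parameters
#' @export
sample_response_model <- function(interview, spec = cohort_spec(),
                                  cfg = engine_config()) {
  ae <- stats::runif(1, spec$ae_range[1], spec$ae_range[2])
  base <- max(0.2, interview$historical_yield_GYR -
                ae * spec$typical_ffp_n[[interview$season]])
  potential <- interview$historical_yield_GYR +
    stats::runif(1, spec$headroom_range[1], spec$headroom_range[2])
  sched <- stage_schedule(interview$growth_duration_days,
                          interview$seedling_age_days, cfg)
  list(base_yield_no_n = base, potential_yield = max(potential, base),
       agronomic_efficiency = ae,
       pi_dat = unname(sched["panicle_initiation"]),
       zinc_responsive = stats::runif(1) < spec$zinc_responsive_prob,
       zinc_penalty = spec$zinc_penalty,
       noise_sd = spec$noise_sd)
}

#' Timing multiplier of a plan's fertilizer N
#'
#' Penalizes poorly timed N: a 10% loss of N efficacy when more than
#' half the total N sits in the early vegetative window (at or before
#' 20 DAT), and a loss proportional to the share of N applied more than
#' a week after panicle initiation (half of that late share is wasted).
#' Well-timed plans score 1.
#'
#' @param plan a `treatment_plan`
#' @param model a [sample_response_model()] result (for the PI date)
#' @param products product table
#' @return multiplier in (0, 1]
#' @export
timing_factor <- function(plan, model, products) {
  apps <- plan$applications
  nfrac <- elemental_fractions(products)[match(apps$product,
                                               products$name), "n"]
  n_kg <- apps$amount_kg_ha * nfrac
  total <- sum(n_kg)
  if (total <= 0) return(1)
  f <- 1
  if (sum(n_kg[apps$dat <= 20]) / total > 0.5) f <- f * 0.9
  late <- sum(n_kg[apps$dat > model$pi_dat + 7]) / total
  f * (1 - 0.5 * late)
}

#' Simulate the grain yield of one treatment plan
#'
#' GY = clip(base + AE x FN x timing - zinc penalty + noise,
#' 0, potential).  The zinc penalty applies only on zinc-responsive
#' fields that receive no zinc sulfate.  Uses the current RNG state for
#' the noise term.
#'
#' @param plan a `treatment_plan`
#' @param model a [sample_response_model()] result
#' @param products product table
#' @return grain yield, Mg/ha
#' @export
simulate_yield <- function(plan, model, products) {
  fn <- unname(plan$totals["n"])
  tf <- timing_factor(plan, model, products)
  y <- model$base_yield_no_n + model$agronomic_efficiency * fn * tf
  if (model$zinc_responsive && plan$zinc_sulfate <= 0)
    y <- y - model$zinc_penalty
  if (model$noise_sd > 0) y <- y + stats::rnorm(1, 0, model$noise_sd)
  clamp(y, 0, model$potential_yield)
}

#' Generate a complete synthetic cohort of trials
#'
#' For each sampled interview: the field-specific (RCM) plan from the
#' engine, the blanket (BFR) plan, the farmer's own (FFP) plan sampled
#' from the practice distributions, and simulated yields for all three
#' from the field's response model.  Fully deterministic under
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()]
#' @param products product table
#' @param cfg an [engine_config()]
#' @return list of [trial_record()]
#' @export
#' @examples
#' trials <- generate_trials(cohort_spec(n_trials = 5, seed = 42))
#' summarize_cohort(trials)$treatment_means
generate_trials <- function(spec = cohort_spec(),
                            products = default_products(),
                            cfg = engine_config()) {
  set.seed(spec$seed)
  interviews <- sample_interviews(spec, set_seed = FALSE)
  lapply(interviews, function(iv) {
    practice <- sample_ffp_practice(iv, spec, products)
    model <- sample_response_model(iv, spec, cfg)
    plans <- list(
      RCM = build_rcm_plan(iv, products, cfg),
      FFP = build_ffp_plan(practice, iv$farmer_applies_zinc, products, cfg),
      BFR = build_bfr_plan(iv, products, cfg))
    yields <- vapply(plans, simulate_yield, numeric(1), model = model,
                     products = products)
    paddy <- if (iv$season == "kharif" && iv$year == "2015") 0.22 else 0.21
    trial_record(iv, plans, yields, prices = price_set(paddy),
                 model = model)
  })
}
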