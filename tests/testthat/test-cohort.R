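test_that("a fixed seed makes the whole cohort bit-identical", {
  spec <- cohort_spec(n_trials = 15, seed = 7)
  t1 <- generate_trials(spec, products0, cfg0)
  t2 <- generate_trials(spec, products0, cfg0)
  expect_identical(plans_to_totals(t1), plans_to_totals(t2))
  expect_identical(plans_to_applications(t1), plans_to_applications(t2))
  expect_identical(interviews_to_table(lapply(t1, `[[`, "interview")),
                   interviews_to_table(lapply(t2, `[[`, "interview")))
  t3 <- generate_trials(cohort_spec(n_trials = 15, seed = 8), products0,
                        cfg0)
  expect_false(identical(plans_to_totals(t1), plans_to_totals(t3)))
})

test_that("sampled interviews follow the configured cohort structure", {
  spec <- cohort_spec(n_trials = 4000, seed = 21)
  ivs <- sample_interviews(spec)
  tab <- interviews_to_table(ivs)
  expect_equal(nrow(tab), 4000L)
  expect_true(all(tab$historical_yield_GYR >= 1.7 &
                    tab$historical_yield_GYR <= 6.3))
  # truncated-normal check: empirical mean within 3 sd of the mean
  expect_lt(abs(mean(tab$historical_yield_GYR) - 4.4),
            3 * 0.7 / sqrt(4000))
  # season-consistent variety durations
  expect_true(all(tab$growth_duration_days[tab$season == "rabi"] <= 140))
  expect_true(all(tab$growth_duration_days[tab$season == "kharif"] > 120))
  # dry-season trials are all irrigated
  expect_true(all(tab$water_regime[tab$season == "rabi"] == "irrigated"))
  # every interview yields a valid schedule
  for (iv in ivs[1:50])
    expect_true(all(diff(stage_schedule(iv$growth_duration_days,
                                        iv$seedling_age_days, cfg0)) > 0))
})

test_that("farmer practices match the stated split-count and rate structure", {
  spec <- cohort_spec(seed = 31)
  set.seed(31)
  ivs <- sample_interviews(cohort_spec(n_trials = 2000, seed = 31))
  counts <- integer(0)
  frac <- elemental_fractions(products0)
  for (iv in ivs) {
    pr <- sample_ffp_practice(iv, spec, products0)
    idx <- match(pr$product, products0$name)
    n_kg <- pr$amount_kg_ha * frac[idx, "n"]
    # realized N application times (DATs where elemental N is applied)
    counts <- c(counts, length(unique(pr$dat[n_kg > 1e-9])))
    totals <- delivered_nutrients(pr, products0)
    expect_true(totals["p"] >= 0 && totals["p"] <= 64 + 1e-9)
    expect_true(totals["k"] >= 0 && totals["k"] <= 156 + 1e-9)
    # largest elemental-N share sits in the early window (<= 20 DAT)
    early <- sum(n_kg[pr$dat <= 20])
    expect_gte(early, max(tapply(n_kg, pr$dat, sum)) - 1e-9)
  }
  props <- tabulate(counts, 3) / length(counts)
  expect_lt(abs(props[1] - 0.05), 0.02)
  expect_lt(abs(props[2] - 0.20), 0.02)
  expect_lt(abs(props[3] - 0.75), 0.02)
  zinc_freq <- mean(vapply(ivs, `[[`, TRUE, "farmer_applies_zinc"))
  expect_lt(abs(zinc_freq - 0.05), 0.02)
})

test_that("the yield response is base at zero N and plateaus at potential", {
  iv <- make_interview()
  spec <- cohort_spec(noise_sd = 0, zinc_responsive_prob = 0)
  set.seed(1)
  model <- sample_response_model(iv, spec, cfg0)
  zero_n <- build_ffp_plan(data.frame(dat = 10, product = "MOP",
                                      amount_kg_ha = 40),
                           FALSE, products0, cfg0)
  expect_equal(simulate_yield(zero_n, model, products0),
               model$base_yield_no_n)
  lots <- build_ffp_plan(data.frame(dat = c(10, 30, 45), product = "urea",
                                    amount_kg_ha = c(300, 400, 400)),
                         FALSE, products0, cfg0)
  expect_equal(simulate_yield(lots, model, products0),
               model$potential_yield)
  # monotone non-decreasing in FN up to the plateau
  yields <- vapply(seq(0, 1200, by = 50), function(kg) {
    plan <- build_ffp_plan(data.frame(dat = c(10, 30),
                                      product = "urea",
                                      amount_kg_ha = c(kg / 2, kg / 2) + 1),
                           FALSE, products0, cfg0)
    simulate_yield(plan, model, products0)
  }, numeric(1))
  expect_true(all(diff(yields) >= 0))
})

test_that("zinc-responsive fields lose the penalty only without zinc", {
  iv <- make_interview()
  spec <- cohort_spec(noise_sd = 0, zinc_responsive_prob = 1)
  set.seed(2)
  model <- sample_response_model(iv, spec, cfg0)
  expect_true(model$zinc_responsive)
  no_zinc <- build_ffp_plan(data.frame(dat = 10, product = "urea",
                                       amount_kg_ha = 100),
                            FALSE, products0, cfg0)
  with_zinc <- build_ffp_plan(data.frame(dat = 10, product = "urea",
                                         amount_kg_ha = 100),
                              TRUE, products0, cfg0)
  expect_equal(simulate_yield(with_zinc, model, products0) -
                 simulate_yield(no_zinc, model, products0),
               spec$zinc_penalty)
})

test_that("ordinary least squares recovers the agronomic efficiency on a noise-free cohort", {
  spec <- cohort_spec(n_trials = 120, seed = 13, noise_sd = 0,
                      zinc_responsive_prob = 0,
                      ae_range = c(0.017, 0.017),
                      headroom_range = c(5, 5))
  trials <- generate_trials(spec, products0, cfg0)
  rows <- do.call(rbind, lapply(trials, function(tr) {
    do.call(rbind, lapply(names(tr$plans), function(lbl) {
      plan <- tr$plans[[lbl]]
      data.frame(
        y = tr$yields[[lbl]] - tr$model$base_yield_no_n,
        fn_eff = unname(plan$totals["n"]) *
          timing_factor(plan, tr$model, products0))
    }))
  }))
  fit <- stats::lm(y ~ 0 + fn_eff, data = rows)
  expect_equal(unname(stats::coef(fit)), 0.017, tolerance = 1e-4)
})

test_that("with a strongly N-limited model the engine out-yields under-fertilizing practice", {
  spec <- cohort_spec(n_trials = 80, seed = 17, noise_sd = 0,
                      headroom_range = c(4, 6))
  trials <- generate_trials(spec, products0, cfg0)
  kharif <- Filter(function(tr) tr$interview$season == "kharif", trials)
  mean_y <- function(trs, lbl)
    mean(vapply(trs, function(tr) tr$yields[[lbl]], numeric(1)))
  expect_gte(mean_y(kharif, "RCM"), mean_y(kharif, "FFP"))
})
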