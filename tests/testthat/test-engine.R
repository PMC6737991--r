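test_that("target yield is historical yield plus uplift, clamped to range", {
  expect_equal(set_target_yield(make_interview(gyr = 4.6), cfg0), 5.1)
  expect_equal(set_target_yield(make_interview(gyr = 3.7), cfg0), 4.2)
  expect_equal(set_target_yield(make_interview(gyr = 2.0), cfg0), 3.0)
  expect_equal(set_target_yield(make_interview(gyr = 6.4), cfg0), 6.5)
  expect_error(set_target_yield(make_interview(gyr = -1), cfg0), "positive")
})

test_that("target yield honours ceiling and late-transplanting penalty", {
  expect_equal(set_target_yield(make_interview(gyr = 5.0, ceiling = 4.8),
                                cfg0), 4.8)
  # 0.25 Mg/ha per week of delay
  expect_equal(set_target_yield(make_interview(gyr = 5.0, delay = 14), cfg0),
               5.0)
  # monotone: non-decreasing in GY_R, non-increasing in delay, in bounds
  gyr <- seq(0.5, 10, by = 0.25)
  ty <- vapply(gyr, function(g)
    set_target_yield(make_interview(gyr = g), cfg0), numeric(1))
  expect_true(all(diff(ty) >= 0))
  expect_true(all(ty >= 3.0 & ty <= 6.5))
  delays <- seq(0, 70, by = 7)
  tyd <- vapply(delays, function(d)
    set_target_yield(make_interview(gyr = 5, delay = d), cfg0), numeric(1))
  expect_true(all(diff(tyd) <= 0))
})

test_that("fertilizer N follows the calibration line, extrapolated at the ends", {
  expect_equal(n_rate(3.0, cfg0), 57)
  expect_equal(n_rate(6.0, cfg0), 123)
  expect_equal(n_rate(4.5, cfg0), 90)
  expect_equal(n_rate(6.5, cfg0), 123 + 22 * 0.5)
  expect_error(n_rate(2.9, cfg0), "outside")
  expect_error(n_rate(6.6, cfg0), "outside")
})

test_that("N calibration is piecewise linear through arbitrary anchors", {
  cfg3 <- engine_config(n_calibration_anchors = cbind(ty = c(3, 5, 6),
                                                      n = c(57, 100, 123)))
  expect_equal(n_rate(4, cfg3), (57 + 100) / 2)
  expect_equal(n_rate(5.5, cfg3), 111.5)
  ty <- seq(3, 6.5, by = 0.1)
  expect_true(all(diff(n_rate(ty, cfg3)) > 0))
})

test_that("stage schedule places basal, mid-tillering and PI correctly", {
  expect_equal(stage_schedule(140, 25, cfg0),
               c(basal = 16, mid_tillering = 28, panicle_initiation = 55))
  expect_equal(unname(stage_schedule(100, 15, cfg0)["basal"]), 5)
  expect_equal(unname(stage_schedule(160, 25, cfg0)["basal"]), 21)
  expect_equal(unname(stage_schedule(110, 20, cfg0)["panicle_initiation"]),
               30)
  expect_error(stage_schedule(110, 40, cfg0), "too short")
})

test_that("PI shifts one day earlier per day of seedling age (grid oracle)", {
  for (dur in c(120, 140, 160)) {
    ages <- 10:30
    pis <- vapply(ages, function(a)
      unname(stage_schedule(dur, a, cfg0)["panicle_initiation"]), numeric(1))
    expect_equal(diff(pis), rep(-1, length(ages) - 1))
    # brute force: PI equals duration - 60 - age everywhere on the grid
    expect_equal(pis, dur - 60 - ages)
    sched <- stage_schedule(dur, ages[1], cfg0)
    expect_true(all(diff(sched) > 0))
  }
})

test_that("N splits follow the configured fractions and sum exactly", {
  expect_equal(n_split_amounts(100, cfg0), c(30, 30, 40))
  expect_equal(n_split_amounts(0, cfg0), c(0, 0, 0))
  expect_equal(n_split_amounts(80, cfg0, fractions = c(0.2, 0.5, 0.3)),
               c(16, 40, 24))
  for (fn in c(103.2, 57, 1 / 3, 99.999)) {
    expect_identical(sum(n_split_amounts(fn, cfg0)), fn)
  }
  expect_error(n_split_amounts(-1, cfg0), "non-negative")
})

test_that("P rate is the input-output balance, floored at zero", {
  expect_equal(p_rate(5.0, 4.5, 0.15, cfg0), 13.0 - 0.5265, tolerance = 1e-9)
  expect_equal(p_rate(5.0, 0, 0.15, cfg0), 2.6 * 5.0)
  # linear decreasing in previous yield, never negative
  prev <- seq(0, 50, by = 5)
  fp <- vapply(prev, function(pv) p_rate(4, pv, 0.5, cfg0), numeric(1))
  expect_true(all(diff(fp) <= 0))
  expect_true(all(fp >= 0))
  pos <- fp[fp > 0]
  expect_equal(diff(pos), rep(diff(pos)[1], length(pos) - 1))
})

test_that("P rates over the admissible target-yield range stay in the reported band", {
  ty <- seq(3.0, 6.5, by = 0.1)
  fp <- p_rate(ty, previous_crop_yield = 4.4, 0.15, cfg0)
  expect_true(all(fp >= 6 & fp <= 21))
})

test_that("K rate is the yield gain over recovery efficiency", {
  expect_equal(k_rate(3.0, cfg0), 0.45 * 14.5 / 0.44)
  expect_equal(k_rate(6.0, cfg0), 0.15 * 6 * 14.5 / 0.44)
  expect_equal(k_rate(4, engine_config(k_yield_gain_fraction = 0)), 0)
  # degree-1 homogeneity in gain and rie_k, inverse in recovery
  base <- k_rate(5, cfg0)
  expect_equal(k_rate(5, engine_config(k_yield_gain_fraction = 0.30)),
               2 * base)
  expect_equal(k_rate(5, engine_config(rie_k = 29)), 2 * base)
  expect_equal(k_rate(5, engine_config(k_recovery_efficiency = 0.88)),
               base / 2)
})

test_that("K split is all basal at or below 33 kg/ha, else 50/50 with PI", {
  expect_equal(k_split_amounts(28, cfg0), c(basal = 28))
  expect_equal(k_split_amounts(33, cfg0), c(basal = 33))
  expect_equal(k_split_amounts(34, cfg0),
               c(basal = 17, panicle_initiation = 17))
  expect_error(k_split_amounts(-2, cfg0), "non-negative")
  for (fk in seq(0, 60, by = 2.5)) {
    ks <- k_split_amounts(fk, cfg0)
    expect_identical(sum(ks), fk)
    expect_equal(length(ks), if (fk <= 33) 1L else 2L)
  }
})

test_that("build_prescription composes the engine and satisfies its invariants", {
  p <- build_prescription(make_interview(), cfg0)
  expect_equal(p$target_yield, 5.1)
  expect_equal(p$fn, 103.2)
  expect_equal(p$fp, 12.7335, tolerance = 1e-9)
  expect_equal(p$fk, 0.15 * 5.1 * 14.5 / 0.44)
  expect_equal(nrow(p$n_splits), 3L)
  expect_equal(nrow(p$k_splits), 1L)
  expect_equal(build_prescription(make_interview(gyr = 2.0), cfg0)$fn, 57)

  set.seed(101)
  for (i in 1:40) {
    iv <- random_interview()
    p <- build_prescription(iv, cfg0)
    expect_true(p$target_yield >= 3.0 && p$target_yield <= 6.5)
    expect_true(min(p$fn, p$fp, p$fk) >= 0)
    expect_equal(sum(p$n_splits$kg_per_ha), p$fn, tolerance = 1e-9)
    expect_equal(sum(p$k_splits$kg_per_ha), p$fk, tolerance = 1e-9)
    expect_equal(nrow(p$k_splits), if (p$fk <= 33) 1L else 2L)
    expect_true(all(diff(p$schedule) > 0))
  }
})
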