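cfg0 <- engine_config()
products0 <- default_products()

# urea/DAP/MOP subset (plus zinc) used in most allocation checks
npk_products <- products0[products0$name %in%
                            c("urea", "DAP", "MOP", "zinc_sulfate"), ]

make_interview <- function(gyr = 4.6, duration = 140, age = 25,
                           delay = 0, prev = 4.5, ceiling = NA, ...) {
  farmer_interview("T", historical_yield_GYR = gyr,
                   growth_duration_days = duration,
                   seedling_age_days = age,
                   transplant_delay_days = delay,
                   previous_crop_yield = prev,
                   variety_yield_ceiling = ceiling, ...)
}

random_interview <- function() {
  duration <- sample(100:165, 1)
  basal <- round(min(max(5 + (duration - 100) * 16 / 60, 5), 21))
  age <- sample(seq(10, min(45, duration - 60 - (2 * basal + 2))), 1)
  make_interview(gyr = runif(1, 1.7, 6.3), duration = duration, age = age,
                 delay = sample(c(0, 0, 0, 7, 21), 1),
                 prev = runif(1, 0, 6),
                 residue_retained_fraction = runif(1))
}

# brute-force oracle: solve the 3x3 linear system for urea/DAP/MOP
# amounts delivering exactly (fn, fp, fk)
solve_udm_amounts <- function(fn, fp, fk) {
  A <- sapply(c("urea", "DAP", "MOP"), function(nm) {
    grade_to_elemental(as.list(npk_products[npk_products$name == nm, ]))
  })
  solve(A, c(n = fn, p = fp, k = fk))
}
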