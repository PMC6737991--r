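# ricenm

Site-specific nutrient management (SSNM) for transplanted rice, as an R
package. Blanket fertilizer recommendations give every field in a
region the same N/P/K rates; SSNM engines such as IRRI's Rice Crop
Manager instead compute field-specific rates and application times from
a short farmer interview. `ricenm` implements the complete nutrient
side of such an engine — with the Odisha (eastern India) calibration as
its defaults — plus the fertilizer-product allocation, costing and
partial-budget economics needed to compare the engine's recommendation
(**RCM**) against the state blanket recommendation (**BFR**, 80/17/33
kg/ha elemental N/P/K) and each farmer's own pre-stated practice
(**FFP**), and a seeded synthetic cohort simulator so the full
three-treatment comparison runs with no external data. It is aimed at
agronomists and decision-support developers who want an auditable,
configurable reference implementation of the SSNM calculations.

## The model

For a field with farmer-reported historical yield GY_R (Mg/ha):

* **Target yield** — GY_T = clamp(min(GY_R + 0.5, variety ceiling) −
  0.25 × weeks of transplanting delay, 3.0, 6.5).
* **Fertilizer N** — piecewise-linear yield-gain calibration through
  anchors (3 Mg/ha, 57 kg N/ha) and (6, 123): FN = 57 + 22 (GY_T − 3),
  split 30/30/40% at the basal window, mid-tillering and panicle
  initiation (PI). The stage calendar comes from variety duration D
  and seedling age A: PI_DAT = D − 60 − A, mid-tillering at half that,
  basal deadline linear in D from 5 DAT (D = 100) to 21 DAT (D = 160).
* **Fertilizer P** — input–output balance:
  FP = max(0, 2.6 GY_T − r × 0.30 × 2.6 × Y_prev), with RIE_P = 2.6 kg
  P/Mg grain, 30% of plant P in straw and r the retained-residue
  fraction.
* **Fertilizer K** — yield-gain approach:
  FK = 0.15 GY_T × 14.5 / 0.44 (15% yield gain from K, RIE_K = 14.5 kg
  K/Mg, recovery efficiency 0.44 kg/kg); all basal when FK ≤ 33 kg/ha,
  else 50% basal + 50% at PI. Zinc sulfate is a flat 25 kg/ha basal.
* **Economics** — TFC = Σ amount × price; gross return = 1000 × GY ×
  paddy price; GRF = gross return − TFC; ANB = ΔGRF between
  treatments; PFP = 1000 × GY / FN; exceedance curves P(ANB ≥ t).

Prescriptions are allocated to commercial products (urea, DAP, MOP,
SSP, compound NP/NPK) by a deterministic priority rule after
grade-to-elemental conversion (P = 0.4364 × P₂O₅, K = 0.8301 × K₂O).
See `vignettes/nutrient-engine.Rmd` for assumptions, parameter
defaults and design rationale.

## Worked example

```r
library(ricenm)
iv <- farmer_interview("F001", historical_yield_GYR = 4.6,
                       growth_duration_days = 140, seedling_age_days = 25,
                       previous_crop_yield = 4.5)
presc <- build_prescription(iv)
presc
#> Nutrient prescription for field F001
#>   target yield 5.1 Mg/ha; N 103.2, P 12.7, K 25.2 kg/ha
#>   N splits:
#>     basal               16 DAT    31.0 kg N/ha
#>     mid_tillering       28 DAT    31.0 kg N/ha
#>     panicle_initiation  55 DAT    41.3 kg N/ha
#>   P: 12.7 kg/ha basal (16 DAT)
#>   K splits:
#>     basal               16 DAT    25.2 kg K/ha
```

The farmer reported 4.6 Mg/ha, so the engine targets 5.1; the N line
gives 103.2 kg N/ha in three splits timed to this 140-day variety
transplanted at 25 days (PI at 55 DAT); the P balance credits the
previous crop's retained residue; and 25.2 kg K/ha is under the 33
kg/ha threshold, so all K goes basal. Allocating to the packaged
product table and pricing:

```r
alloc <- allocate_products(presc, default_products())
alloc
#> Product allocation
#>   basal               16 DAT  zinc_sulfate      25.0 kg/ha
#>   basal               16 DAT  DAP               63.4 kg/ha
#>   basal               16 DAT  MOP               50.6 kg/ha
#>   basal               16 DAT  urea              42.5 kg/ha
#>   mid_tillering       28 DAT  urea              67.3 kg/ha
#>   panicle_initiation  55 DAT  urea              89.7 kg/ha
#>   delivered N/P/K: 103.2 / 12.7 / 25.2 kg/ha
total_fertilizer_cost(alloc, default_products())
#> [1] 82.22177
```

DAP covers the P (its 18% N is credited against the basal N split),
MOP the K, urea the rest of the N; the plan costs 82.22 US$/ha. A
synthetic cohort exercises the whole RCM/FFP/BFR comparison:

```r
trials <- generate_trials(cohort_spec(n_trials = 50, seed = 7))
summarize_cohort(trials, thresholds = c(0, 25))$contrast_means
#>   season      year anb_rcm_ffp anb_rcm_bfr anb_bfr_ffp
#> 1   rabi 2013-2014    20.07237    62.08779  -42.015415
#> 2 kharif      2014   129.75052    82.97487   46.775654
#> 3   rabi 2014-2015    83.24198    86.63754   -3.395561
#> 4 kharif      2015   145.04344    20.94323  124.100206
```

— the mean added net benefit (US$/ha) of the field-specific
recommendation over the farmer practice and the blanket
recommendation, by season and year.

A command-line wrapper with subcommands `recommend`, `bfr`, `cohort`,
`evaluate` and `show-config` is installed at
`system.file("cli", "ricenm", package = "ricenm")`; packaged fixtures
(the product/price table, three example interviews, the default engine
configuration) live under `inst/extdata/`.

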