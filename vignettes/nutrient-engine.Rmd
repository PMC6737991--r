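---
title: "The field-specific nutrient-management engine: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The field-specific nutrient-management engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricenm)
```

## The problem

Blanket fertilizer recommendations apply one N/P/K rate to every rice
field in a region. Site-specific nutrient management (SSNM) instead
adjusts rates and application times per field, using what the farmer
can report in a short interview: historical yield, variety, seedling
age at transplanting, previous crop and residue management, and the
fertilizer products they can buy. `ricenm` implements such an engine
for transplanted rice — as calibrated for Odisha, India — together with
the product-allocation, costing and partial-budget machinery needed to
compare the engine's recommendation (RCM) against a blanket
recommendation (BFR, 80/17/33 kg/ha N/P/K) and each farmer's own
fertilizer practice (FFP), and a synthetic cohort simulator so the
whole comparison runs without any field data.

## The engine's model

**Target yield.** GY_T = clamp(min(GY_R + 0.5, ceiling) −
0.25 × weeks_late, 3.0, 6.5) Mg/ha. The +0.5 Mg/ha uplift over the
farmer-reported historical yield GY_R is the observed mean gap between
target and historical yields in all four season-years of the Odisha
evaluation. The 3.0–6.5 Mg/ha bounds are the engine's admissible
target range. The downward adjustment for transplanting delayed beyond
the critical date is documented behaviour of the deployed tool but its
magnitude is not published; we expose it as a configurable penalty
(default 0.25 Mg/ha per week, with the delay supplied directly as an
interview field), which makes the documented adjustment exercisable
and explains why a target can fall below the reported yield. The
optional per-variety yield ceiling plays the same role for low-yielding
varieties and is absent by default.

**Fertilizer N.** A yield-gain calibration expressed as a
piecewise-linear curve through anchor points (target yield, kg N/ha),
by default (3, 57) and (6, 123) — the line FN = 57 + 22 (GY_T − 3),
extrapolated along its terminal segment between the anchor hull and the
target-yield bounds. We house the calibration as anchors rather than a
ΔGY/AE quotient because only the calibrated endpoints are published;
the implied slope of 22 kg N per Mg is derived. The implied agronomic
efficiency never appears as a standalone constant: at GY_T = 4 the line
gives 79 kg N/ha (commonly rounded to 80, i.e. a partial factor
productivity near 50 kg grain per kg N).

**N timing.** N is applied in three splits — early vegetative (basal
window), mid-tillering, panicle initiation (PI). The stage calendar
derives from variety duration D and seedling age A: PI occurs 60 days
before maturity, so PI_DAT = D − 60 − A; mid-tillering at PI_DAT/2;
and the basal deadline maps linearly from duration (5 DAT at D = 100 to
21 DAT at D = 160, the published endpoints; the 100/160-day endpoints
themselves are our assumption). The deployed tool's exact phenology
model is unpublished; this one reproduces its published behaviour
(earlier PI for older seedlings, wider basal window for longer
varieties) and is configurable. A seedling too old for its variety
(schedule not strictly increasing) is a hard error, not a silent
clamp. The RCM split fractions are not published; the default
0.30/0.30/0.40 is inferred from the reported mean stage-wise amounts
(30/31/40 kg N/ha on a ≈101 kg/ha mean). The last split absorbs any
rounding so the splits sum to the total exactly.

**Fertilizer P.** An input–output balance: FP = max(0, 2.6 GY_T −
r × 0.30 × 2.6 × Y_prev), where 2.6 kg P/Mg is the reciprocal internal
efficiency (RIE) of P, 30% of plant P sits in the straw (70% in
grain), r is the retained-residue fraction (engine default 0.15, the
assumption that only 15% of above-ground biomass remains after manual
harvest) and Y_prev the previous crop's yield.

**Fertilizer K.** A yield-gain approach: the K uptake needed for an
assumed 15% yield increase from applied K (RIE_K = 14.5 kg K/Mg)
divided by a 0.44 kg/kg recovery efficiency:
FK = 0.15 GY_T × 14.5 / 0.44. We read the 15% gain as a fraction of
the *target* yield (the published wording is ambiguous between target
and K-omission yield; the switch is configurable, and no residue K
credit is taken). K at or below 33 kg/ha is all basal; above 33 it is
split 50/50 between basal and PI. The RIE values 2.6 (P) and 14.5 (K)
are the standard SSNM/QUEFTS-derived constants; they are not printed in
the Odisha evaluation, so every cohort-level cost quantity that depends
on them is approximate (see *Known limitations*).

**Zinc.** A flat 25 kg/ha of zinc sulfate applied basal with RCM and
BFR; the engine deliberately has no field-specific zinc logic.

All rates are computed as continuous values; rounding to 0.1 kg/ha
happens only at the presentation layer (flat-file output).

## Products, allocation and cost

Grades quoted as N–P₂O₅–K₂O percentages convert to elemental fractions
with the stoichiometric factors P = 0.4364 P₂O₅ and K = 0.8301 K₂O.
The allocation of an elemental prescription to products is a
deterministic priority rule — P met basally by the highest-P product,
each K split by the highest-K product, incidental N from those sources
credited against the basal split first, the residual N of each split
met by the highest-N single-nutrient product — rather than a
least-cost blend: it reproduces the urea+DAP+MOP source mix actually
observed, is explainable to a farmer, and equals the unique solution of
the linear system whenever each nutrient has a dedicated source (a
property the tests check against a `solve()` oracle). Excess N from a
basal P source carries forward to later splits; ties break by product
table order; demand no product can supply is reported as unmet, never
dropped. Total fertilizer cost (TFC) is the price-weighted sum of
applied amounts; zinc sulfate is costed but carries no N/P/K.

## Economics

Gross return = 1000 × yield × farmgate paddy price (the price is US$
per kg of unmilled rice — 0.21, or 0.22 in the 2015 wet season — a
per-kg reading required by dimensional analysis of the published gross
returns, although the source prints the unit as US$/ha). GRF = gross
return − TFC; the added net benefit (ANB) of one treatment over
another is the GRF difference at a common price set; PFP = 1000 GY/FN.
Exceedance curves report P(ANB ≥ t) with an inclusive threshold, and
financial loss means strictly negative ANB. Mixed-model inference on
the contrasts is out of scope: the package reports means and empirical
probabilities; a user wanting formal tests can feed the flat trial
tables to `lme4`/`emmeans` directly.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults describe the evaluation cohort: 209 trials
across six agro-climatic zones and ten districts, a ~52/48 wet
(kharif) / dry (rabi) season split with the observed year mix, all dry
trials irrigated and ~44% of wet trials irrigated, historical yields
drawn from a truncated Normal(4.4, 0.7) on [1.7, 6.3] Mg/ha, and 24
varieties whose durations span short (≤120 d, dry season only), medium
(121–140 d) and long (>140 d, wet season only). Farmer practices use
1/2/3 N applications with probabilities 5/20/75%, the largest N share
in the early window (≤20 DAT), season-specific N totals (means ≈75
kg/ha wet, ≈98 dry, matching the reported treatment means) and P and K
totals inside the printed 0–64 and 0–156 kg/ha ranges; only the ranges
are published, so the within-range shapes (truncated normals) are our
choice. Zinc is applied by 5% of farmers. Transplanting is late on 12%
of fields (the fraction of trials where the target fell below the
historical yield), with a 7–28 day delay; seedling ages are sampled
within whatever range the variety's phenology admits.

Yield response is linear-plateau — the simplest form consistent with
the agronomic-efficiency framing of SSNM: GY = clip(base + AE × FN ×
timing − zinc penalty + noise, 0, potential), with AE ~ U(0.010,
0.025) Mg grain per kg N, base = GY_R − AE × typical FFP N (so
reported yields are internally consistent), potential = GY_R + U(0.5,
2.5) Mg/ha headroom, a timing multiplier that docks 10% when more than
half the N sits in the early window and wastes half of any N applied
more than a week after PI, a 0.4 Mg/ha penalty on the 30% of fields
flagged zinc-responsive when no zinc is applied (the true frequency is
unpublished; soil-test means near common critical levels motivate the
0.3), and Normal(0, 0.3) noise. Everything is deterministic under the
spec's seed.

What passing simulator-based tests show is therefore *internal*
consistency — the engine, allocator and economics compose correctly,
and cohort-level structure (rate bands, cost shares, exceedance
monotonicity) emerges from the stated conditions. They do not show
that the response model predicts real fields: the simulator has no
weather, hydrology, pest or soil-nutrient dynamics, no spatial
correlation, and its zero-N base is an accounting identity, not an
indigenous-supply measurement.

## Numerical choices and degenerate inputs

Split amounts sum to their totals exactly (the final split absorbs
rounding); the K split boundary is inclusive at 33 kg/ha; the P
balance floors at zero rather than recommending mining credit;
target-yield clamping happens after the ceiling and delay adjustments;
stage DATs round to whole days with the basal deadline clamped to
[5, 21]; allocation drops applications below 10⁻¹² kg/ha; unmet demand
below 10⁻⁹ kg/ha is treated as zero. A non-positive historical yield,
a negative rate, an empty product list, or a schedule that cannot be
strictly increasing are errors, not warnings. Truncated-normal draws
use the inverse-CDF method, so they are reproducible from plain
`runif()` streams.

## Problem sizes in the test and acceptance runs

Distributional checks sample 2,000–4,000 interviews; the cohort-level
zinc-cost-share quantity uses 1,000 fields (well above the 209 of the
emulated design, to shrink the sampling error of the reported mean);
parameter-recovery regressions use 60–120 noise-free trials; the
end-to-end determinism checks use 12–20 trials.

## Known limitations

* The cohort-mean zinc-sulfate share of fertilizer cost computed under
  the default RIE constants comes out near 34% of TFC versus the
  reported mean of 32%: the engine's default K calibration
  (15% gain, RIE 14.5, recovery 0.44) prescribes somewhat less K —
  and hence a smaller MOP bill — than the deployed tool evidently did
  (reported RCM K rates reach 49 kg/ha where the default formula tops
  out near 32), which inflates the fixed zinc cost's share by about
  two percentage points. We keep the literature defaults rather than
  retro-fitting the RIEs to the cost table.
* The late-transplanting penalty, per-variety ceilings, phenology
  endpoints and the FFP within-range rate shapes are reasoned defaults
  for unpublished quantities; all are configurable.
* No NOPT-based recalibration, no water-stress or variety-genetics
  modelling, no zinc-rate adjustment, no labor or non-fertilizer costs,
  and no currency handling beyond the fixed 65 INR/US$ rate.

## A worked field

```{r}
iv <- farmer_interview("F001", historical_yield_GYR = 4.6,
                       growth_duration_days = 140, seedling_age_days = 25,
                       previous_crop_yield = 4.5)
presc <- build_prescription(iv)
presc
alloc <- allocate_products(presc, default_products())
total_fertilizer_cost(alloc, default_products())
```

```{r}
trials <- generate_trials(cohort_spec(n_trials = 50, seed = 7))
summarize_cohort(trials, thresholds = c(0, 25))$contrast_means
```
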