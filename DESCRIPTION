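Package: ricenm
Title: Field-Specific Nutrient Management Engine for Transplanted Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Site-specific nutrient management (SSNM) calculations for
    transplanted rice: target-yield setting from farmer-reported
    historical yield, fertilizer N rate from a yield-gain calibration
    line, P rate from a nutrient input-output balance, K rate from a
    yield-gain approach with a fixed recovery efficiency, growth-stage
    split scheduling keyed to variety duration and seedling age,
    allocation of elemental prescriptions to commercial fertilizer
    products with grade-to-elemental conversion and costing, and
    partial-budget economics (total fertilizer cost, gross return above
    fertilizer cost, added net benefit, partial factor productivity of
    N, exceedance curves). A seeded synthetic farmer-cohort generator
    with a linear-plateau yield response model lets the full comparison
    of a field-specific recommendation against a blanket recommendation
    and the farmers' own practice be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
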