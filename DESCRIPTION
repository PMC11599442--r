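Package: coexposr
Title: Co-Exposure to Medication Combinations from Prescription Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses concurrent exposure (co-exposure) to free-dose and
    fixed-dose medication combinations from prescription-redemption
    registers. Prescription durations are estimated from the empirical
    distribution of refill waiting times (Sessa Empirical Estimator);
    per-drug treatment episodes are built with same-medication carry-over
    and a permissible gap; pairwise and higher-order overlaps of treatment
    episodes yield co-exposure periods, which are merged into final
    gap-free co-exposure episodes per patient. Includes new-user cohort
    assembly with washout and censoring, early/late treatment-stage
    summaries with small-cell suppression, a synthetic register generator
    with known ground truth, and a brute-force day-resolution oracle for
    validating the interval algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
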