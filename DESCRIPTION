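Package: panelcost
Title: Full-Cost Micro-Costing of Multigene NGS Panels Versus
    Single-Gene Testing in Lung Cancer Diagnostics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A micro-costing (activity-based costing) engine for molecular
    diagnostic laboratories, built around the workflow of a pathology unit
    running a multigene next-generation-sequencing (NGS) panel for
    non-squamous non-small-cell lung cancer (NSCLC). Computes per-sample
    unit costs with a full-cost approach (direct labor, consumables
    prorated by reagent and machine saturation, straight-line annualized
    equipment, a fixed overhead uplift and value-added tax on goods),
    compares a one-shot multigene panel against an ordered sequence of
    single-gene tests (cumulative cost, break-even biomarker count,
    hands-on staff hours, cost per actionable variant), projects targeted
    therapy drug spending from monthly prices and median progression-free
    survival, and generates seeded synthetic patient cohorts with the
    stage mix, variant spectrum, retest/confirmation events and
    turnaround-time structure the analysis assumes, so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
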