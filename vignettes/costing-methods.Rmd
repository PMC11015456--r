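---
title: "Full-cost micro-costing of panel diagnostics: model, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-cost micro-costing of panel diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcost)
```

## The costing model

`panelcost` estimates the unit cost of a molecular diagnostic test with
a full-cost (activity-based) approach. Per sample,

$$
\text{total} \;=\; (\underbrace{L}_{\text{labor}} +
\underbrace{R}_{\text{reagents}} + \underbrace{P}_{\text{platform}} +
\underbrace{E}_{\text{extraction}}) \times (1 + \rho),
$$

where $\rho$ is the overhead rate covering facility common costs
(maintenance, utilities, cleaning, non-healthcare materials,
administration), defaulting to 25% per standard institutional
accounting policy. The components:

* **Labor** $L = \sum_i \text{minutes}_i \times w_{r(i)}/60$ over
  hands-on activities, with $w_r$ the gross hourly wage of role $r$.
  Labor carries no VAT. When a unit has measured its per-sample staff
  cost directly, an assay may carry that observed figure as a fixed
  override while the minutes stay available for staff-time accounting.
* **Reagents** $R$: each consumable's VAT-inclusive price divided by
  its *reagent saturation* — the number of samples the pack actually
  processes — or, for run-scoped items (chips, cartridges), by the
  *machine saturation*: run capacity net of positive/negative control
  slots. Prices may be entered net (uplifted by the goods VAT rate,
  default 22%) or gross; re-applying VAT to a gross price is rejected.
* **Platform** $P$: each instrument's annual cost — VAT-inclusive
  purchase price under straight-line depreciation with zero residual
  value (5 years for main platforms, 10 for ancillary instruments) plus
  annual maintenance/technical assistance — divided by the samples it
  processes per year. Instruments whose per-sample cost falls under a
  configurable threshold (default €0.50, strict comparison) are
  excluded as negligible and reported as such; this reproduces the
  common practice of leaving microscopes, microtomes, water baths and
  quantification devices out of per-test tariffs. Whether maintenance
  contracts are quoted gross varies by supplier, so the type carries an
  explicit `maintenance_vat_included` flag (default `TRUE`).
* **Extraction** $E$: either an observed per-sample amount or a nested
  assay definition, in which case its *pre-overhead* subtotal is used
  so the parent's overhead uplift is applied exactly once.

All money is 2023 EUR; no inflation adjustment or discounting is
applied, and external quality assessment fees are excluded by default.

### Rounding conventions

Arithmetic is carried at full double precision; rounding happens only
at presentation. Unit costs round half-to-even to the cent on the
decimal cents scale (`round_cents()`): 1048.325 → 1048.32, 198.125 →
198.12. Cohort-level euro figures truncate to whole euros
(`euro_floor()`): 171924.48 → 171924. These conventions reproduce the
reference tariffs the bundled configuration was calibrated against.
Note that base R's `round()` operates on binary doubles and would give
1048.33 here, which is why the package ships its own cents rounder.
One consequence worth stating: the bundled real-time PCR components sum
to 158.50, so the computed total is 158.50 × 1.25 = 198.125 → €198.12,
while the tariff sheet the components were transcribed from prints
€198.06 — an internal inconsistency of that source, which the package
resolves in favour of the computed value.

```{r}
cfg <- load_costing_config(example_config_path())
print(assay_unit_cost(cfg$assays$NGS_FFPE, cfg$wages))
```

### The calibrated wage table

The bundled configuration's hourly wages (secretary 21.24, laboratory
operator 27.66, technician 30.00, biologist 39.24, physician 60.00
EUR/h) are a calibration, not payroll data: they are chosen so that the
recorded hands-on minutes reproduce the unit's observed per-sample
staff costs exactly for the NGS panel (€35.58), IHC (€14.61) and
Maxwell extraction (€8.88). The observed staff-cost table is not
consistent with any single wage vector across all assays (two
extraction methods share identical minutes but differ in cost), so
real-time PCR (€25.17) and GPI extraction (€9.40) carry their observed
costs as fixed overrides instead. No attempt is made to solve the
underdetermined wage system beyond this.

### A fully bottom-up assay

The fixture enters reagents and platform as observed per-sample
amounts; the bottom-up path is equivalent and available whenever pack
and instrument data exist:

```{r}
seqr <- equipment("sequencer", 250000, annual_maintenance = 19000,
                  annual_samples = 500)          # (305000/5 + 19000)/500
demo <- assay_definition(
  "demo_panel",
  activities = list(labor_activity("biologist", 20)),
  consumables = list(
    consumable_item("library kit", 4500, samples_per_pack = 24),
    consumable_item("chip", 732, vat_included = TRUE, per_run = TRUE)),
  run = run_profile(capacity = 8, controls = 2),
  equipment_items = list(seqr))
assay_unit_cost(demo, wage_table(biologist = 39.24))
```

## Strategy comparison

A `testing_strategy` is either one multigene panel or an ordered
sequence of single-gene tests (IHC, real-time PCR, FISH, Sanger). The
package computes cumulative sequential cost, the **break-even
biomarker count** (smallest $k$ with cumulative cost ≥ panel cost,
ties counting as break-even), per-role hands-on hours, cohort totals
and cost per qualifying (actionable) variant. Percent changes are kept
at full precision; reports display one decimal, since reference
figures in this literature mix truncation and rounding.

Two modelling choices were genuinely open:

* **Sequence order** is configuration-driven; the default tests the
  most prevalent biomarkers first, which is the cost-minimising
  heuristic a laboratory would use. With the bundled unit costs the
  cumulative sequence overtakes the panel price at the sixth biomarker
  (excess ≈ €10).
* **Early stopping**: sequential testing can be run test-all (default)
  or stop-on-first-positive (`stop_on_first_positive = TRUE`). Real
  practice lies between the two, because stage, histology and material
  availability truncate sequences in ways no published rule captures;
  both bounds are therefore exposed.

Cohort billing uses the cent-rounded unit tariff (the price a payer
would actually be charged per test), so a cohort total is
`cases × round_cents(unit_total)` truncated to whole euros.

## Therapy cost projection

For each actionable gene with an approved, reimbursed targeted drug,
the expected per-patient drug cost is `monthly price × median PFS`
(first line) plus `uptake × monthly price × PFS` for an optional second
line, at standard dosage with no interruptions or dose reductions —
deliberately an upper-bound stylisation. Months are continuous. Drug
prices are VAT-inclusive (10%). Median PFS values in the bundled
configuration are literature medians (e.g. osimertinib 18.9 months,
alectinib 25.7 by independent review, entrectinib 15.7,
dabrafenib+trametinib 10.8, tepotinib 11.0 with 55% second-line
uptake; MET first-line targeted cost is zero since the targeted agent
is a later-line option) and are flagged assumptions: override them
when local or updated data exist. The diagnosis/treatment split
`100·d/(d+t)` is presented at one decimal with the rounding residual
assigned to the larger share so the pair always sums to 100.0.

## The synthetic cohort generator

`generate_cohort()` emulates a one-year case series of 210 non-squamous
NSCLC samples so every downstream stage is testable without patient
data: advanced-stage probability 0.781; at most one actionable driver
per case (NSCLC drivers are near mutually exclusive; a frequency table
with ESCAT tiers and reimbursement flags is configurable); NGS retest
probability 0.038; orthogonal confirmation probability 0.10 with
method draws IHC 0.66 and real-time PCR 0.38 made independently
("and/or", at least one method enforced) and gene-conditional
overrides (ALK by IHC 0.86, MET exon 14 by PCR 0.75); therapy assigned
to every advanced case whose driver is reimbursed.

Turnaround time is gamma distributed (positive, right-skewed — only
location statistics are published, so the shape is an assumption,
default 12): routine cases draw from a base gamma with mean 9.44
working days, and retest/orthogonal cases add an independent gamma
delay with mean 3.35 days. Since a fraction
$1-(1-0.038)(1-0.10)=0.134$ of cases is flagged, the overall mean is
$9.44 + 0.134 \times 3.35 \approx 9.89$ days — the calibration implied
by quoting both the all-cases and the repeat-excluded mean. Working
days are generated directly; calendar conversion is out of scope.

The per-gene frequency defaults (EGFR .16, KRAS G12C .12, ALK .06, MET
ex14 .04, BRAF V600E .025, ROS1 .025, RET .02, ERBB2 .025, NTRK .005;
actionable total 48%) are literature-typical for non-squamous NSCLC,
not measured values.

What the generator does *not* emulate: sequencing reads or variant
calls, QC failures correlated with sample type, co-mutations (a
relaxable default), squamous or liquid-biopsy cases, and calendar
effects on TAT. Passing tests therefore demonstrate that the
*accounting machinery* is correct and that parameters are recovered
from data with the assumed structure — not that the assumed structure
matches any particular laboratory.

```{r}
cohort <- generate_cohort(cfg$cohort, seed = 42)
summarize_cohort(cohort)
summarize_cohort(cohort, exclude_repeats = TRUE)
```

## Numerical and degenerate-input choices

* Validation happens in constructors, before any sampling or costing:
  probabilities outside $[0,1]$, frequencies summing past 1, missing
  wages for referenced roles, controls ≥ run capacity, zero annual
  samples and non-{5,10} depreciation all fail with messages naming
  the offending field.
* Cost per qualifying variant with zero qualifying cases is *undefined*
  and returned as `NA` (reported as such), not an error; percent change
  from a zero base and the diagnosis/treatment ratio of two zero costs
  are errors.
* Break-even ties (cumulative cost exactly equal to the panel price)
  count as break-even; "never" is represented as `NA_integer_`.
* The generator restores the caller's RNG state and stores seed plus a
  parameter hash with the cohort; pipeline CSV/JSON data files are
  byte-identical across re-runs with the same configuration and seed.

Test and simulation problem sizes were chosen to keep the statistical
checks sharp but cheap: parameter-recovery properties run at n = 5000
(3-standard-error bands across 20 seeds), convergence checks at
n = 10000, and the bundled pipeline at the case-series size n = 210.

## Known limitations

* Single-centre cost structure: wages, saturations and tariffs travel
  poorly across institutions and procurement cycles; treat the bundled
  YAML as a template, not a benchmark.
* The therapy model excludes hospitalization, staging and follow-up
  imaging, adverse-event management and clinical staff time, and
  assumes uninterrupted standard dosing over the median PFS; it is a
  drug-budget stylisation, not a cost-effectiveness model (no ICER or
  QALY machinery is provided, deliberately).
* Sequential-testing costs depend on an unpublished ordering and
  stopping rule; only the configurable bounds above are offered.
* VAT treatment of maintenance contracts is supplier-specific; the
  explicit flag defaults to VAT-inclusive.
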