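test_that("labor cost sums minutes times hourly wage", {
  w <- wage_table(tech = 24, biologist = 36, physician = 60, solo = 30)
  expect_equal(labor_cost_per_sample(
    list(labor_activity("solo", 10)), w), 5)
  expect_equal(labor_cost_per_sample(list(), w), 0)
  # 30 min @ 24 + 10 min @ 36 + 10 min @ 60 = 12 + 6 + 10
  acts <- list(labor_activity("tech", 30), labor_activity("biologist", 10),
               labor_activity("physician", 10))
  expect_equal(labor_cost_per_sample(acts, w), 28)
  expect_error(labor_cost_per_sample(
    list(labor_activity("nurse", 5)), w), "nurse")
})

test_that("calibrated wages round-trip the observed NGS staff cost", {
  acts <- list(labor_activity("biomedical_laboratory_technician", 5),
               labor_activity("biologist", 20),
               labor_activity("physician", 20))
  expect_equal(round_cents(labor_cost_per_sample(acts, calibrated_wages())),
               35.58)
})

test_that("consumables prorate by pack and by billable run samples", {
  expect_equal(consumable_cost_per_sample(
    list(consumable_item("kit", 100, vat_rate = 0.22,
                         samples_per_pack = 10))), 12.20)
  chip <- consumable_item("chip", 732, vat_included = TRUE, per_run = TRUE)
  expect_equal(consumable_cost_per_sample(
    list(chip), run_profile(8, 2)), 122)
  expect_equal(consumable_cost_per_sample(list()), 0)
  expect_error(run_profile(8, 8), "no billable samples per run")
  expect_error(consumable_cost_per_sample(list(chip)), "run-scoped")
})

test_that("VAT application guards against double taxation and round-trips", {
  expect_equal(apply_vat(100, 0.22), 122)
  expect_error(apply_vat(122, 0.22, vat_included = TRUE),
               "already VAT-inclusive")
  for (net in c(0.01, 1, 461.79, 1e5)) {
    expect_equal(remove_vat(apply_vat(net, 0.22), 0.22), net,
                 tolerance = 1e-12)
  }
  expect_error(apply_vat(10, 1.2), "VAT rate")
})

test_that("equipment is annualized straight-line over its depreciation", {
  seqr <- equipment("sequencer", 250000, annual_maintenance = 19000,
                    annual_samples = 500)
  expect_equal(equipment_cost_per_sample(seqr), 160)
  expect_equal(equipment_cost_per_sample(
    equipment("free", 0, annual_samples = 100)), 0)
  seqr10 <- equipment("sequencer", 250000, annual_maintenance = 19000,
                      depreciation_years = 10, annual_samples = 500)
  expect_equal(equipment_cost_per_sample(seqr10), 99)
  expect_error(equipment("x", 1000, annual_samples = 0), "annual_samples")
  expect_error(equipment("x", 1000, depreciation_years = 7,
                         annual_samples = 10), "5 or 10")
})

test_that("per-sample equipment cost conserves the annual cost", {
  set.seed(7)
  for (i in 1:20) {
    eq <- equipment("e", runif(1, 0, 5e5),
                    annual_maintenance = runif(1, 0, 3e4),
                    depreciation_years = sample(c(5L, 10L), 1),
                    annual_samples = sample(1:5000, 1))
    expect_equal(equipment_cost_per_sample(eq) * eq$annual_samples,
                 equipment_annual_cost(eq), tolerance = 1e-6)
  }
})

test_that("negligible-equipment test is a strict threshold", {
  cheap <- equipment("scope", 8000, vat_included = TRUE,
                     depreciation_years = 10, annual_samples = 20000)
  expect_equal(equipment_cost_per_sample(cheap), 0.04)
  expect_true(is_negligible_equipment(cheap, 0.50))
  # exactly at the threshold: kept (strict less-than)
  at <- equipment("at", 25, vat_included = TRUE, depreciation_years = 5,
                  annual_samples = 10)
  expect_equal(equipment_cost_per_sample(at), 0.50)
  expect_false(is_negligible_equipment(at, 0.50))
})

test_that("full-cost breakdowns reproduce the bundled worked examples", {
  cfg <- monza_config()
  ihc <- assay_unit_cost(cfg$assays$IHC, cfg$wages)
  expect_equal(ihc$labor, 14.61, tolerance = 1e-9)
  expect_equal(ihc$subtotal, 54.61, tolerance = 1e-9)
  expect_equal(round_cents(ihc$total), 68.26)

  ngs <- assay_unit_cost(cfg$assays$NGS_FFPE, cfg$wages)
  expect_equal(ngs$labor, 35.58, tolerance = 1e-9)
  expect_equal(ngs$subtotal, 838.66, tolerance = 1e-9)
  expect_equal(round_cents(ngs$total), 1048.32)

  pcr <- assay_unit_cost(cfg$assays$real_time_PCR, cfg$wages)
  expect_equal(pcr$subtotal, 158.50, tolerance = 1e-9)
  expect_equal(pcr$total, 198.125, tolerance = 1e-9)
  expect_equal(round_cents(pcr$total), 198.12)
})

test_that("an all-zero assay costs exactly zero", {
  z <- assay_definition("zero")
  expect_equal(assay_unit_cost(z)$total, 0)
})

test_that("breakdown satisfies the overhead identity and additivity", {
  set.seed(11)
  for (i in 1:25) {
    ra <- random_assay()
    bd <- assay_unit_cost(ra$assay, ra$wages)
    expect_equal(bd$subtotal,
                 bd$labor + bd$reagents + bd$platform + bd$extraction,
                 tolerance = 0.005)
    expect_equal(bd$overheads, ra$assay$overhead_rate * bd$subtotal,
                 tolerance = 0.005)
    if (bd$subtotal > 0) {
      expect_equal(bd$total / bd$subtotal, 1 + ra$assay$overhead_rate,
                   tolerance = 1e-9)
    }
  }
})

test_that("scaling all monetary inputs scales the whole breakdown", {
  cfg <- monza_config()
  base <- assay_unit_cost(cfg$assays$NGS_FFPE, cfg$wages)
  k <- 3.7
  scaled_assay <- assay_definition(
    "scaled", labor_cost = base$labor * k,
    fixed_reagent_cost = 563.38 * k, fixed_platform_cost = 209.52 * k,
    extraction = 30.18 * k, overhead_rate = 0.25)
  scaled <- assay_unit_cost(scaled_assay)
  expect_equal(scaled$subtotal, k * base$subtotal, tolerance = 1e-9)
  expect_equal(scaled$overheads, k * base$overheads, tolerance = 1e-9)
  expect_equal(scaled$total, k * base$total, tolerance = 1e-9)
})

test_that("assay_unit_cost agrees with the brute-force oracle", {
  set.seed(23)
  for (i in 1:40) {
    ra <- random_assay()
    expect_equal(assay_unit_cost(ra$assay, ra$wages)$total,
                 oracle_assay_total(ra$assay, ra$wages),
                 tolerance = 0.005)
  }
})

test_that("negligible equipment is excluded and reported", {
  a <- assay_definition("mixed", equipment_items = list(
    equipment("big", 250000, annual_maintenance = 19000,
              annual_samples = 500),
    equipment("scope", 8000, vat_included = TRUE,
              depreciation_years = 10, annual_samples = 20000)))
  bd <- assay_unit_cost(a)
  expect_equal(bd$platform, 160)
  expect_identical(attr(bd, "excluded_equipment"), "scope")
})

test_that("nested extraction sub-assays contribute their pre-overhead subtotal", {
  w <- wage_table(tech = 30)
  extr <- assay_definition("extr",
                           activities = list(labor_activity("tech", 10)),
                           fixed_reagent_cost = 12, overhead_rate = 0.25)
  parent <- assay_definition("parent", fixed_reagent_cost = 100,
                             extraction = extr)
  bd <- assay_unit_cost(parent, w)
  expect_equal(bd$extraction, 17)          # 5 labor + 12 reagents, no uplift
  expect_equal(bd$total, 117 * 1.25, tolerance = 1e-9)
})

test_that("presentation rounding is half-to-even on the cents scale", {
  expect_equal(round_cents(1048.325), 1048.32)
  expect_equal(round_cents(198.125), 198.12)
  expect_equal(round_cents(68.2625), 68.26)
  expect_equal(round_cents(c(0.005, 0.015, 0.025)), c(0.00, 0.02, 0.02))
  expect_equal(euro_floor(171924.48), 171924)
  expect_equal(euro_floor(164 * 1048.32), 171924)
})
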