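# Shared fixtures and independent oracles for the costing tests.

monza_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- load_costing_config(example_config_path())
    cfg
  }
})

# Wage table calibrated to the observed per-sample staff costs of the
# bundled configuration (NGS 35.58, IHC 14.61, Maxwell extraction 8.88).
calibrated_wages <- function() {
  wage_table(technical_secretary_operator = 21.24,
             technical_laboratory_operator = 27.66,
             biomedical_laboratory_technician = 30,
             biologist = 39.24,
             physician = 60)
}

# Draw a random small assay (<= 10 consumables) plus a matching wage
# table, for oracle-equivalence and invariance properties.
random_assay <- function() {
  roles <- c("tech", "biologist", "physician")
  wages <- wage_table(stats::setNames(round(runif(3, 15, 80), 2), roles))
  n_act <- sample(0:4, 1)
  acts <- lapply(seq_len(n_act), function(i) {
    labor_activity(sample(roles, 1), round(runif(1, 0, 60), 1))
  })
  run <- run_profile(capacity = sample(4:16, 1), controls = sample(0:2, 1))
  n_items <- sample(0:10, 1)
  items <- lapply(seq_len(n_items), function(i) {
    consumable_item(paste0("item", i), round(runif(1, 0, 900), 2),
                    vat_rate = sample(c(0, 0.1, 0.22), 1),
                    samples_per_pack = sample(1:48, 1),
                    vat_included = runif(1) < 0.3,
                    per_run = runif(1) < 0.3)
  })
  n_eq <- sample(0:2, 1)
  equip <- lapply(seq_len(n_eq), function(i) {
    equipment(paste0("eq", i), round(runif(1, 0, 3e5), 2),
              vat_included = runif(1) < 0.3,
              annual_maintenance = round(runif(1, 0, 2e4), 2),
              depreciation_years = sample(c(5L, 10L), 1),
              annual_samples = sample(50:20000, 1))
  })
  assay <- assay_definition(
    "random", activities = acts, consumables = items, run = run,
    equipment_items = equip,
    fixed_reagent_cost = round(runif(1, 0, 300), 2),
    fixed_platform_cost = round(runif(1, 0, 100), 2),
    extraction = round(runif(1, 0, 50), 2),
    overhead_rate = round(runif(1, 0, 0.5), 3))
  list(assay = assay, wages = wages)
}

# Brute-force full-cost oracle: plain re-summation of every ingredient,
# written independently of the package's component operations.
oracle_assay_total <- function(assay, wages, threshold = 0.50) {
  labor <- 0
  if (!is.null(assay$labor_cost)) {
    labor <- assay$labor_cost
  } else {
    for (a in assay$activities) {
      labor <- labor + (a$minutes / 60) * wages[[a$role]]
    }
  }
  goods <- assay$fixed_reagent_cost
  for (it in assay$consumables) {
    p <- it$pack_price * (if (it$vat_included) 1 else 1 + it$vat_rate)
    div <- if (it$per_run) assay$run$capacity - assay$run$controls
           else it$samples_per_pack
    goods <- goods + p / div
  }
  plat <- assay$fixed_platform_cost
  for (eq in assay$equipment_items) {
    buy <- eq$purchase_price *
      (if (eq$vat_included) 1 else 1 + eq$vat_rate)
    maint <- eq$annual_maintenance *
      (if (eq$maintenance_vat_included) 1 else 1 + eq$vat_rate)
    per_sample <- (buy / eq$depreciation_years + maint) / eq$annual_samples
    if (per_sample >= threshold) plat <- plat + per_sample
  }
  extr <- if (is.numeric(assay$extraction)) assay$extraction else 0
  (labor + goods + plat + extr) * (1 + assay$overhead_rate)
}
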