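#' Load and validate a costing configuration
#'
#' Reads a YAML configuration describing wages, assay definitions,
#' testing strategies, therapy regimens and cohort parameters, validates
#' it (every role referenced by an activity must have a wage; every
#' strategy step must name a defined assay; probabilities must be valid)
#' and builds the corresponding package objects. Validation failures are
#' reported with the offending field before anything is sampled or
#' costed.
#'
#' @param path Path to a YAML file; see the bundled example
#'   `system.file("extdata", "monza2023.yaml", package = "panelcost")`.
#' @return A `costing_config` list with elements `wages`, `assays`
#'   (named list, in file order), `strategies`, `regimens` (named by
#'   gene), `cohort` (a [cohort_params()]), `overhead_rate`, `vat`,
#'   `negligible_threshold`, `study_observed`, `path`.
#' @export
load_costing_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("wages", "assays")) {
    if (is.null(raw[[field]])) {
      stop("config field '", field, "' is missing", call. = FALSE)
    }
  }
  wages <- wage_table(raw$wages)
  overhead <- raw$overhead_rate %||% 0.25
  vat <- list(goods = raw$vat$goods %||% 0.22,
              drugs = raw$vat$drugs %||% 0.10)
  thr <- raw$negligible_equipment_threshold %||% 0.50

  assays <- list()
  for (an in names(raw$assays)) {
    assays[[an]] <- build_assay(an, raw$assays[[an]], wages, overhead,
                                vat$goods)
  }

  strategies <- list()
  for (sn in names(raw$strategies %||% list())) {
    strategies[[sn]] <- build_strategy(sn, raw$strategies[[sn]], assays,
                                       wages)
  }

  regimens <- list()
  for (tr in raw$therapies %||% list()) {
    if (is.null(tr$gene)) stop("therapy entry without 'gene'",
                               call. = FALSE)
    regimens[[tr$gene]] <- therapy_regimen(
      gene = tr$gene, drug = tr$drug %||% NA_character_,
      monthly_cost = tr$monthly_cost %||% 0,
      pfs_months = tr$pfs_months %||% 0,
      dosage = tr$dosage %||% NA_character_,
      second_line = tr$second_line)
  }

  cohort <- build_cohort_params(raw$cohort %||% list())

  structure(list(wages = wages, assays = assays, strategies = strategies,
                 regimens = regimens, cohort = cohort,
                 overhead_rate = overhead, vat = vat,
                 negligible_threshold = thr,
                 study_observed = raw$study_observed %||% list(),
                 path = normalizePath(path)),
            class = "costing_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

build_assay <- function(name, entry, wages, overhead, goods_vat) {
  acts <- lapply(entry$activities %||% list(), function(a) {
    if (is.null(a$role) || is.null(a$minutes)) {
      stop("assay '", name, "': each activity needs 'role' and 'minutes'",
           call. = FALSE)
    }
    if (!a$role %in% names(wages)) {
      stop("missing wage for role '", a$role, "' referenced by assay '",
           name, "'", call. = FALSE)
    }
    labor_activity(a$role, a$minutes)
  })
  run <- if (!is.null(entry$run)) {
    run_profile(entry$run$capacity, entry$run$controls %||% 0L)
  } else NULL
  items <- lapply(entry$reagents$items %||% list(), function(it) {
    consumable_item(it$name %||% "item", it$pack_price,
                    vat_rate = it$vat_rate %||% goods_vat,
                    samples_per_pack = it$samples_per_pack %||% 1L,
                    vat_included = isTRUE(it$vat_included),
                    per_run = isTRUE(it$per_run))
  })
  equip <- lapply(entry$platform$equipment %||% list(), function(e) {
    equipment(e$name %||% "equipment", e$purchase_price,
              vat_rate = e$vat_rate %||% goods_vat,
              vat_included = isTRUE(e$vat_included),
              annual_maintenance = e$annual_maintenance %||% 0,
              maintenance_vat_included =
                !isFALSE(e$maintenance_vat_included),
              depreciation_years = e$depreciation_years %||% 5L,
              annual_samples = e$annual_samples)
  })
  assay_definition(
    name, activities = acts, labor_cost = entry$labor_cost,
    consumables = items, run = run,
    fixed_reagent_cost = entry$reagents$fixed_per_sample %||% 0,
    equipment_items = equip,
    fixed_platform_cost = entry$platform$fixed_per_sample %||% 0,
    extraction = entry$extraction %||% 0,
    overhead_rate = entry$overhead_rate %||% overhead)
}

build_strategy <- function(name, entry, assays, wages) {
  mode <- entry$mode %||% stop("strategy '", name, "' has no 'mode'",
                              call. = FALSE)
  if (mode == "panel") {
    if (!entry$assay %in% names(assays)) {
      stop("strategy '", name, "' references unknown assay '", entry$assay,
           "'", call. = FALSE)
    }
    strategy_from_assays(name, "panel", unlist(entry$biomarkers),
                         entry$assay, assays, wages)
  } else if (mode == "sequential") {
    steps <- entry$steps %||% stop("sequential strategy '", name,
                                  "' has no 'steps'", call. = FALSE)
    bio <- vapply(steps, function(s) s$biomarker, character(1))
    asy <- vapply(steps, function(s) s$assay, character(1))
    missing <- setdiff(asy, names(assays))
    if (length(missing)) {
      stop("strategy '", name, "' references unknown assay(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    strategy_from_assays(name, "sequential", bio, asy, assays, wages)
  } else {
    stop("strategy '", name, "': mode must be 'panel' or 'sequential'",
         call. = FALSE)
  }
}

build_cohort_params <- function(entry) {
  vt <- if (!is.null(entry$variants)) {
    do.call(rbind, lapply(entry$variants, function(v) {
      data.frame(gene = v$gene, tier = as.character(v$tier),
                 freq = v$freq, reimbursed = isTRUE(v$reimbursed),
                 stringsAsFactors = FALSE)
    }))
  } else default_variant_table()
  cohort_params(
    n = entry$n %||% 210L,
    advanced_prob = entry$advanced_prob %||% 0.781,
    variant_table = vt,
    retest_prob = entry$retest_prob %||% 0.038,
    orthogonal_prob = entry$orthogonal_prob %||% 0.10,
    orth_ihc_prob = entry$orth_ihc_prob %||% 0.66,
    orth_pcr_prob = entry$orth_pcr_prob %||% 0.38,
    orth_ihc_prob_alk = entry$orth_ihc_prob_alk %||% 0.86,
    orth_pcr_prob_met = entry$orth_pcr_prob_met %||% 0.75,
    tat_base_mean = entry$tat_base_mean %||% 9.44,
    tat_shape = entry$tat_shape %||% 12,
    repeat_delay_mean = entry$repeat_delay_mean %||% 3.35,
    repeat_delay_shape = entry$repeat_delay_shape %||% 4)
}

#' Path to the bundled example configuration
#' @return Path of the packaged `monza2023.yaml`.
#' @export
example_config_path <- function() {
  system.file("extdata", "monza2023.yaml", package = "panelcost",
              mustWork = TRUE)
}
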