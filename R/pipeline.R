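#' Run the full costing pipeline
#'
#' One reproducible end-to-end run: generate the seeded synthetic
#' cohort, cost every configured assay, compare the panel strategy
#' against sequential single-gene testing on the advanced-stage subset
#' (the cases for which complete biomarker testing is indicated),
#' project targeted-therapy spending for the treated cases, summarize
#' the cohort (with and without retest/orthogonal cases in the TAT
#' statistics), and render the report files.
#'
#' @param config A `costing_config` from [load_costing_config()], or a
#'   path to a YAML configuration.
#' @param seed Integer random seed for the cohort draw.
#' @param out_dir Output directory (created if needed); when `NULL`
#'   nothing is written and only the results list is returned.
#' @param stop_on_first_positive Early-stopping rule for the sequential
#'   arm (default `FALSE`: every case receives the full sequence).
#' @param verbose Narrate the stages with `message()`.
#' @return A `pipeline_result` list with elements `assay_costs`,
#'   `cohort`, `summary_all`, `summary_routine`, `scenario`, `therapy`,
#'   `diagnosis_treatment`, and (when `out_dir` is given) `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(example_config_path(), seed = 42)
#' res$assay_costs
#' }
run_pipeline <- function(config, seed, out_dir = NULL,
                         stop_on_first_positive = FALSE,
                         verbose = FALSE) {
  if (is.character(config)) config <- load_costing_config(config)
  stopifnot(inherits(config, "costing_config"))
  say <- function(...) if (verbose) message(...)

  say("Costing ", length(config$assays), " assays")
  breakdowns <- lapply(config$assays, assay_unit_cost,
                       wages = config$wages,
                       negligible_threshold = config$negligible_threshold)
  assay_costs <- do.call(rbind, lapply(breakdowns, as.data.frame))
  rownames(assay_costs) <- NULL
  assay_costs$total_presented <- round_cents(assay_costs$total)

  say("Generating synthetic cohort (n = ", config$cohort$n,
      ", seed = ", seed, ")")
  cohort <- generate_cohort(config$cohort, seed = seed)
  summary_all <- summarize_cohort(cohort)
  summary_routine <- summarize_cohort(cohort, exclude_repeats = TRUE)

  scenario <- NULL
  panel_name <- Find(function(s) config$strategies[[s]]$mode == "panel",
                     names(config$strategies))
  sgt_name <- Find(function(s) config$strategies[[s]]$mode == "sequential",
                   names(config$strategies))
  advanced <- cohort[cohort$stage == "advanced", , drop = FALSE]
  if (!is.null(panel_name) && !is.null(sgt_name) && nrow(advanced) > 0) {
    say("Comparing '", panel_name, "' vs '", sgt_name, "' on ",
        nrow(advanced), " advanced cases")
    scenario <- compare_strategies(
      advanced, config$strategies[[panel_name]],
      config$strategies[[sgt_name]],
      stop_on_first_positive = stop_on_first_positive)
  }

  therapy <- NULL
  dt_ratio <- NULL
  if (length(config$regimens) > 0) {
    counts <- vapply(names(config$regimens), function(g) {
      sum(!is.na(cohort$therapy_gene) & cohort$therapy_gene == g)
    }, numeric(1))
    say("Projecting therapy costs for ", sum(counts), " treated cases")
    therapy <- cohort_therapy_cost(unname(config$regimens), counts)
    if (!is.na(therapy$mean_per_treated) && "NGS_FFPE" %in% assay_costs$assay) {
      ngs_unit <- assay_costs$total_presented[
        assay_costs$assay == "NGS_FFPE"]
      dt_ratio <- diagnosis_treatment_ratio(ngs_unit,
                                            therapy$mean_per_treated)
    }
  }

  res <- list(config_path = config$path, seed = seed,
              assay_costs = assay_costs, breakdowns = breakdowns,
              cohort = cohort, summary_all = summary_all,
              summary_routine = summary_routine, scenario = scenario,
              therapy = therapy, diagnosis_treatment = dt_ratio)
  class(res) <- "pipeline_result"

  if (!is.null(out_dir)) {
    res$manifest <- render_report(res, out_dir)
  }
  res
}

#' Render pipeline results to report files
#'
#' Writes, under `out_dir`: the per-assay cost table (`assay_costs.csv`,
#' rows in configuration order), the serialized cohort (`cohort.csv` +
#' provenance sidecar), the scenario comparison (`scenario.json`), the
#' therapy summary (`therapy.json`), the cohort summary
#' (`cohort_summary.json`) and a run manifest (`manifest.json`) listing
#' the seed, the configuration hash and every artifact produced. Re-runs
#' with the same configuration and seed produce byte-identical CSV/JSON
#' data files.
#'
#' @param results A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return A `run_manifest` list, invisibly.
#' @export
render_report <- function(results, out_dir) {
  stopifnot(inherits(results, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  out <- function(f) file.path(out_dir, f)

  utils::write.csv(results$assay_costs, out("assay_costs.csv"),
                   row.names = FALSE)
  artifacts <- c(artifacts, "assay_costs.csv")

  write_cohort(results$cohort, out("cohort.csv"))
  artifacts <- c(artifacts, "cohort.csv", "cohort.csv.json")

  wj <- function(x, f) {
    jsonlite::write_json(x, out(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    artifacts <<- c(artifacts, f)
  }
  if (!is.null(results$scenario)) {
    s <- results$scenario
    wj(list(n_cases = s$n_cases, n_qualifying = s$n_qualifying,
            panel = s$panel[setdiff(names(s$panel), "staff_hours")],
            panel_staff_hours = as.list(s$panel$staff_hours),
            sgt = s$sgt[setdiff(names(s$sgt), "staff_hours")],
            sgt_staff_hours = as.list(s$sgt$staff_hours),
            break_even_biomarker = if (is.na(s$break_even)) "never"
                                   else s$break_even,
            panel_vs_sgt_pct = s$panel_vs_sgt_pct),
       "scenario.json")
  }
  if (!is.null(results$therapy)) {
    t <- results$therapy
    wj(list(total = t$total, n_treated = t$n_treated,
            mean_per_treated = t$mean_per_treated,
            diagnosis_treatment_shares =
              if (is.null(results$diagnosis_treatment)) NULL
              else as.list(present_shares(results$diagnosis_treatment)),
            breakdown = t$breakdown),
       "therapy.json")
  }
  sa <- results$summary_all
  sr <- results$summary_routine
  wj(list(n = sa$n, n_advanced = sa$n_advanced,
          advanced_fraction = sa$advanced_fraction,
          n_escat_i_ii = sa$n_escat_i_ii,
          n_reimbursed_eligible = sa$n_reimbursed_eligible,
          retest_rate = sa$retest_rate,
          orthogonal_rate = sa$orthogonal_rate,
          tat_mean = sa$tat_mean, tat_median = sa$tat_median,
          tat_mean_excluding_repeats = sr$tat_mean,
          gene_counts = as.list(sa$gene_counts)),
     "cohort_summary.json")

  manifest <- structure(list(
    package = "panelcost",
    version = as.character(utils::packageVersion("panelcost")),
    config = results$config_path,
    config_hash = unname(tools::md5sum(results$config_path)),
    seed = results$seed,
    cohort_params_hash = attr(results$cohort, "params_hash"),
    created = format(Sys.time(), tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ"),
    artifacts = artifacts), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("panelcost pipeline run (seed ", x$seed, ")\n\n", sep = "")
  tab <- x$assay_costs
  tab[-1] <- lapply(tab[-1], round_cents)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$summary_all)
  if (!is.null(x$scenario)) { cat("\n"); print(x$scenario) }
  if (!is.null(x$therapy)) { cat("\n"); print(x$therapy) }
  if (!is.null(x$diagnosis_treatment)) {
    sh <- present_shares(x$diagnosis_treatment)
    cat(sprintf("\nDiagnosis/treatment cost shares: %.1f%% / %.1f%%\n",
                sh[["diagnosis"]], sh[["treatment"]]))
  }
  invisible(x)
}
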