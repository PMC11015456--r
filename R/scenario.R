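#' A biomarker testing strategy
#'
#' Either a single multigene panel covering all biomarkers at one unit
#' cost, or an ordered sequence of single-gene tests (SGT: IHC, real-time
#' PCR, FISH, Sanger), each with its own per-sample cost and hands-on
#' minutes by role.
#'
#' @param name Strategy name.
#' @param mode `"panel"` or `"sequential"`.
#' @param biomarkers Character vector of biomarkers covered, in testing
#'   order for sequential strategies; must be unique and non-empty.
#' @param costs Per-test cost(s) in EUR: length 1 for a panel, one per
#'   biomarker for a sequential strategy; all `>= 0`.
#' @param assays Assay name(s) behind each step (length as `costs`);
#'   optional labels.
#' @param minutes Hands-on minutes per test by role: a single named
#'   numeric vector for a panel, or a list of named vectors (one per
#'   step) for a sequential strategy. May be empty.
#' @return A `testing_strategy` object.
#' @export
testing_strategy <- function(name, mode = c("panel", "sequential"),
                             biomarkers, costs, assays = NULL,
                             minutes = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(biomarkers), length(biomarkers) >= 1L)
  if (anyDuplicated(biomarkers)) {
    stop("biomarkers must be unique within a strategy", call. = FALSE)
  }
  stopifnot(is.numeric(costs), all(is.finite(costs)), all(costs >= 0))
  if (mode == "panel") {
    if (length(costs) != 1L) stop("a panel has one cost", call. = FALSE)
    if (!is.null(minutes)) stopifnot(is.numeric(minutes))
    step_minutes <- list(if (is.null(minutes)) numeric(0) else minutes)
  } else {
    if (length(costs) != length(biomarkers)) {
      stop("sequential strategies need one cost per biomarker",
           call. = FALSE)
    }
    if (is.null(minutes)) {
      step_minutes <- rep(list(numeric(0)), length(biomarkers))
    } else {
      stopifnot(is.list(minutes), length(minutes) == length(biomarkers))
      step_minutes <- minutes
    }
  }
  structure(list(name = name, mode = mode, biomarkers = biomarkers,
                 costs = as.numeric(costs), assays = assays,
                 minutes = step_minutes),
            class = "testing_strategy")
}

#' Build a strategy from assay definitions
#'
#' Convenience constructor: per-step costs are the cent-rounded full-cost
#' totals of the named assays, and per-step minutes come from the assays'
#' activity lists.
#'
#' @param name Strategy name.
#' @param mode `"panel"` or `"sequential"`.
#' @param biomarkers Biomarkers covered (testing order for sequential).
#' @param assay_names One assay name (panel) or one per biomarker.
#' @param assays Named list of [assay_definition()]s.
#' @param wages A [wage_table()].
#' @return A [testing_strategy()].
#' @export
strategy_from_assays <- function(name, mode, biomarkers, assay_names,
                                 assays, wages) {
  stopifnot(all(assay_names %in% names(assays)))
  costs <- vapply(assay_names, function(an) {
    round_cents(assay_unit_cost(assays[[an]], wages)$total)
  }, numeric(1))
  mins <- lapply(assay_names, function(an) {
    m <- minutes_by_role(assays[[an]]$activities)
    if (length(m)) m else numeric(0)
  })
  if (mode == "panel") {
    testing_strategy(name, "panel", biomarkers, unname(costs[1L]),
                     assays = assay_names, minutes = mins[[1L]])
  } else {
    testing_strategy(name, "sequential", biomarkers, unname(costs),
                     assays = assay_names, minutes = mins)
  }
}

#' Percent change between two quantities
#'
#' `(new - old) / old * 100`, at full precision; round only for display.
#'
#' @param old Reference value, non-zero.
#' @param new New value.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(68.26, 1048.32)  # ~ +1435.8
percent_change <- function(old, new) {
  stopifnot(is.numeric(old), is.numeric(new))
  if (any(old == 0)) stop("percent change undefined for old = 0",
                          call. = FALSE)
  (new - old) / old * 100
}

#' Cumulative cost of the first k single-gene tests
#'
#' @param strategy A sequential [testing_strategy()].
#' @param k Number of biomarkers tested, `1 <= k <= length(biomarkers)`.
#' @return Cumulative EUR cost of the first `k` tests in strategy order.
#' @export
sgt_cumulative_cost <- function(strategy, k) {
  stopifnot(inherits(strategy, "testing_strategy"))
  if (strategy$mode != "sequential") {
    stop("cumulative cost is defined for sequential strategies",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(strategy$costs)) {
    stop("k out of range [1, ", length(strategy$costs), "]", call. = FALSE)
  }
  sum(strategy$costs[seq_len(k)])
}

#' Break-even biomarker count of a panel versus sequential testing
#'
#' The smallest number of sequentially tested biomarkers at which the
#' cumulative single-gene cost reaches (ties included) the fixed panel
#' cost. Returns `NA` ("never") when even the full sequence stays below
#' the panel cost.
#'
#' @param panel_cost Panel unit cost, `>= 0`.
#' @param strategy A sequential [testing_strategy()].
#' @return Integer break-even index, or `NA_integer_` for never.
#' @export
#' @examples
#' s <- testing_strategy("sgt", "sequential", paste0("g", 1:4), rep(30, 4))
#' break_even_biomarker(100, s)  # 4
break_even_biomarker <- function(panel_cost, strategy) {
  stopifnot(is.numeric(panel_cost), length(panel_cost) == 1L,
            panel_cost >= 0)
  stopifnot(inherits(strategy, "testing_strategy"),
            strategy$mode == "sequential")
  cum <- cumsum(strategy$costs)
  hit <- which(cum >= panel_cost)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Total hands-on staff hours for a cohort under a strategy
#'
#' Per-role hours = cohort size x total minutes for that role across all
#' tests performed under the strategy / 60. For sequential strategies
#' this assumes every case receives every test (the test-all rule); see
#' [cohort_strategy_costs()] for the stop-on-first-positive variant of
#' the cost calculation.
#'
#' @param cohort_size Number of cases, `>= 0`.
#' @param strategy A [testing_strategy()].
#' @return Named numeric vector of hours by role (empty if the strategy
#'   records no minutes).
#' @export
hands_on_totals <- function(cohort_size, strategy) {
  stopifnot(is.numeric(cohort_size), length(cohort_size) == 1L,
            cohort_size >= 0)
  stopifnot(inherits(strategy, "testing_strategy"))
  all_roles <- unique(unlist(lapply(strategy$minutes, names)))
  if (length(all_roles) == 0L) return(numeric(0))
  mins <- vapply(all_roles, function(r) {
    sum(vapply(strategy$minutes,
               function(m) if (r %in% names(m)) m[[r]] else 0,
               numeric(1)))
  }, numeric(1))
  cohort_size * mins / 60
}

#' Cohort-level testing cost
#'
#' @param cases Number of cases tested, `>= 0`.
#' @param unit_cost Per-case cost in EUR (conventionally the cent-rounded
#'   unit tariff).
#' @return Total EUR at full precision; apply [euro_floor()] for the
#'   whole-euro presentation convention.
#' @export
#' @examples
#' euro_floor(cohort_testing_cost(164, 1048.32))  # 171924
cohort_testing_cost <- function(cases, unit_cost) {
  stopifnot(is.numeric(cases), length(cases) == 1L, cases >= 0,
            is.numeric(unit_cost), unit_cost >= 0)
  cases * unit_cost
}

#' Cost per qualifying case (e.g. per actionable variant identified)
#'
#' Total testing spend divided by the number of qualifying cases
#' (variants of a given actionability tier, or variants with a reimbursed
#' therapy). With zero qualifying cases the metric is undefined and `NA`
#' is returned rather than an error, so reports can state "undefined".
#'
#' @param total_cost Total testing cost in EUR, `>= 0`.
#' @param n_qualifying Number of qualifying cases, `>= 0`.
#' @return EUR per qualifying case at full precision (`NA_real_` when
#'   undefined); apply [euro_floor()] for presentation.
#' @export
#' @examples
#' euro_floor(cost_per_qualifying_case(171924, 77))  # 2232
cost_per_qualifying_case <- function(total_cost, n_qualifying) {
  stopifnot(is.numeric(total_cost), total_cost >= 0,
            is.numeric(n_qualifying), n_qualifying >= 0)
  if (n_qualifying == 0) return(NA_real_)
  total_cost / n_qualifying
}

#' Per-case testing costs for a cohort under a strategy
#'
#' For a panel, every case costs the panel unit cost. For a sequential
#' strategy with `stop_on_first_positive = FALSE` (default) every case
#' receives the full sequence; with `TRUE`, a case whose actionable gene
#' appears in the strategy order is tested only up to and including that
#' step, while wild-type cases (or genes outside the sequence) receive
#' the full sequence.
#'
#' @param cohort A synthetic cohort data frame (see [generate_cohort()])
#'   or any data frame with a `gene` column.
#' @param strategy A [testing_strategy()].
#' @param stop_on_first_positive Early-stopping rule for sequential
#'   strategies.
#' @return Numeric vector of per-case EUR costs.
#' @export
cohort_strategy_costs <- function(cohort, strategy,
                                  stop_on_first_positive = FALSE) {
  stopifnot(is.data.frame(cohort), inherits(strategy, "testing_strategy"))
  n <- nrow(cohort)
  if (strategy$mode == "panel") return(rep(strategy$costs[1L], n))
  cum <- cumsum(strategy$costs)
  full <- cum[length(cum)]
  if (!stop_on_first_positive) return(rep(full, n))
  idx <- match(cohort$gene, strategy$biomarkers)
  ifelse(is.na(idx), full, cum[idx])
}

#' Compare a panel strategy against sequential single-gene testing
#'
#' Runs both strategies over a cohort and assembles the scenario result:
#' cohort totals, per-patient cost range and mean, the break-even
#' biomarker count, per-role hands-on hours, and cost per qualifying
#' variant for each strategy.
#'
#' @param cohort Cohort data frame with `gene` and `escat_tier` columns.
#' @param panel A panel [testing_strategy()].
#' @param sgt A sequential [testing_strategy()].
#' @param qualifying_tiers ESCAT tiers counted as qualifying (default
#'   tiers I and II).
#' @param stop_on_first_positive Early-stopping rule for the sequential
#'   arm.
#' @return A `scenario_result` list.
#' @export
compare_strategies <- function(cohort, panel, sgt,
                               qualifying_tiers = c("I", "II"),
                               stop_on_first_positive = FALSE) {
  stopifnot(panel$mode == "panel", sgt$mode == "sequential")
  per_case <- list(
    panel = cohort_strategy_costs(cohort, panel),
    sgt = cohort_strategy_costs(cohort, sgt, stop_on_first_positive)
  )
  n_qual <- sum(!is.na(cohort$escat_tier) &
                  cohort$escat_tier %in% qualifying_tiers)
  summarise_arm <- function(costs, strategy) {
    total <- sum(costs)
    list(name = strategy$name, total = total,
         per_patient_mean = if (length(costs)) mean(costs) else NA_real_,
         per_patient_min = if (length(costs)) min(costs) else NA_real_,
         per_patient_max = if (length(costs)) max(costs) else NA_real_,
         staff_hours = hands_on_totals(nrow(cohort), strategy),
         cost_per_qualifying_variant =
           cost_per_qualifying_case(total, n_qual))
  }
  res <- list(
    n_cases = nrow(cohort),
    n_qualifying = n_qual,
    panel = summarise_arm(per_case$panel, panel),
    sgt = summarise_arm(per_case$sgt, sgt),
    break_even = break_even_biomarker(panel$costs[1L], sgt),
    panel_vs_sgt_pct = if (sum(per_case$sgt) > 0) {
      percent_change(sum(per_case$sgt), sum(per_case$panel))
    } else NA_real_,
    per_case = per_case
  )
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Testing-strategy comparison over", x$n_cases, "cases\n")
  for (arm in list(x$panel, x$sgt)) {
    cat(sprintf("  %-14s total %s  (per patient %s, range %s-%s)\n",
                arm$name, format_eur(euro_floor(arm$total), 0),
                format_eur(arm$per_patient_mean),
                format_eur(arm$per_patient_min),
                format_eur(arm$per_patient_max)))
  }
  be <- if (is.na(x$break_even)) "never" else x$break_even
  cat("  break-even biomarker count:", be, "\n")
  if (!is.na(x$panel_vs_sgt_pct)) {
    cat(sprintf("  panel vs sequential cohort cost: %+0.1f%%\n",
                x$panel_vs_sgt_pct))
  }
  invisible(x)
}
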