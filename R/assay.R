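#' Define an assay for full-cost unit costing
#'
#' An assay gathers all the cost ingredients of one predictive test:
#'
#' * labor: a list of [labor_activity()] (costed against a wage table) or,
#'   when a laboratory has measured its per-sample staff cost directly, a
#'   fixed `labor_cost` override (activities can still be recorded for
#'   hands-on-time accounting);
#' * reagents: [consumable_item()]s prorated by reagent/machine
#'   saturation, plus an optional fixed VAT-inclusive per-sample amount;
#' * platform: [equipment()] items (negligible ones are excluded at
#'   costing time), plus an optional fixed VAT-inclusive amount;
#' * extraction: either a fixed VAT-inclusive per-sample EUR amount, or
#'   another `assay_definition` whose pre-overhead subtotal is used (so
#'   overheads are applied once, on the parent assay);
#' * an overhead rate applied to the sum of the above (default 25%).
#'
#' Fixed amounts are by convention VAT-inclusive: they represent observed
#' per-sample component costs from laboratory accounting.
#'
#' @param name Assay name.
#' @param activities List of [labor_activity()] (may be empty).
#' @param labor_cost Optional observed per-sample staff cost (EUR);
#'   overrides the activities-based labor cost when given.
#' @param consumables List of [consumable_item()].
#' @param run Optional [run_profile()] for run-scoped consumables.
#' @param fixed_reagent_cost Fixed VAT-inclusive reagent EUR/sample.
#' @param equipment_items List of [equipment()] objects.
#' @param fixed_platform_cost Fixed VAT-inclusive platform EUR/sample.
#' @param extraction `0`/`NULL` for none, a fixed VAT-inclusive EUR
#'   amount, or an `assay_definition` for a pluggable extraction method.
#' @param overhead_rate Overhead fraction `>= 0`, default `0.25`.
#' @return An `assay_definition` object.
#' @export
assay_definition <- function(name, activities = list(), labor_cost = NULL,
                             consumables = list(), run = NULL,
                             fixed_reagent_cost = 0,
                             equipment_items = list(),
                             fixed_platform_cost = 0,
                             extraction = 0, overhead_rate = 0.25) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(labor_cost)) {
    stopifnot(is.numeric(labor_cost), length(labor_cost) == 1L,
              is.finite(labor_cost), labor_cost >= 0)
  }
  stopifnot(is.numeric(overhead_rate), length(overhead_rate) == 1L,
            is.finite(overhead_rate), overhead_rate >= 0)
  stopifnot(is.numeric(fixed_reagent_cost), fixed_reagent_cost >= 0,
            is.numeric(fixed_platform_cost), fixed_platform_cost >= 0)
  if (is.null(extraction)) extraction <- 0
  if (is.numeric(extraction)) {
    stopifnot(length(extraction) == 1L, is.finite(extraction),
              extraction >= 0)
  } else if (!inherits(extraction, "assay_definition")) {
    stop("extraction must be a number >= 0 or an assay_definition",
         call. = FALSE)
  }
  structure(list(name = name, activities = activities,
                 labor_cost = labor_cost, consumables = consumables,
                 run = run, fixed_reagent_cost = fixed_reagent_cost,
                 equipment_items = equipment_items,
                 fixed_platform_cost = fixed_platform_cost,
                 extraction = extraction, overhead_rate = overhead_rate),
            class = "assay_definition")
}

#' Full-cost per-sample breakdown of an assay
#'
#' Implements the full-cost approach: per-sample direct costs (staff
#' labor, consumables), indirect costs (annualized equipment), the
#' extraction component, then a fixed overhead uplift covering facility
#' common costs (maintenance, utilities, cleaning, administration). VAT
#' is carried inside the goods components; labor is VAT-free. Equipment
#' items whose per-sample cost falls below `negligible_threshold` are
#' excluded from the platform component and listed in the
#' `excluded_equipment` attribute of the result.
#'
#' All arithmetic is done at full precision; use `print()` (or
#' [round_cents()]) for the cent-rounded presentation.
#'
#' @param assay An [assay_definition()].
#' @param wages A [wage_table()]; needed unless the assay carries a fixed
#'   `labor_cost` or has no activities.
#' @param negligible_threshold Per-sample EUR threshold below which
#'   equipment is excluded (default 0.50).
#' @return A `cost_breakdown`: list with `labor`, `reagents`, `platform`,
#'   `extraction`, `subtotal`, `overheads`, `total` (EUR per sample).
#' @export
#' @examples
#' w <- wage_table(biologist = 30)
#' a <- assay_definition("toy",
#'        activities = list(labor_activity("biologist", 10)),
#'        fixed_reagent_cost = 40)
#' assay_unit_cost(a, w)
assay_unit_cost <- function(assay, wages = NULL,
                            negligible_threshold = 0.50) {
  stopifnot(inherits(assay, "assay_definition"))

  labor <- if (!is.null(assay$labor_cost)) {
    assay$labor_cost
  } else if (length(assay$activities) > 0L) {
    if (is.null(wages)) {
      stop("assay '", assay$name,
           "' costs labor from activities but no wage table was given",
           call. = FALSE)
    }
    labor_cost_per_sample(assay$activities, wages)
  } else 0

  reagents <- assay$fixed_reagent_cost +
    consumable_cost_per_sample(assay$consumables, assay$run)

  excluded <- character(0)
  platform <- assay$fixed_platform_cost
  for (eq in assay$equipment_items) {
    if (is_negligible_equipment(eq, negligible_threshold)) {
      excluded <- c(excluded, eq$name)
    } else {
      platform <- platform + equipment_cost_per_sample(eq)
    }
  }

  extraction <- if (is.numeric(assay$extraction)) {
    assay$extraction
  } else {
    # nested assay: take its pre-overhead subtotal so the parent's
    # overhead uplift is applied exactly once
    assay_unit_cost(assay$extraction, wages, negligible_threshold)$subtotal
  }

  subtotal <- labor + reagents + platform + extraction
  overheads <- assay$overhead_rate * subtotal
  structure(list(assay = assay$name, labor = labor, reagents = reagents,
                 platform = platform, extraction = extraction,
                 subtotal = subtotal, overheads = overheads,
                 total = subtotal + overheads,
                 overhead_rate = assay$overhead_rate),
            excluded_equipment = excluded,
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Full-cost breakdown per sample --", x$assay, "\n")
  row <- function(lab, v) cat(sprintf("  %-22s %10.2f\n", lab, round_cents(v)))
  row("Staff labor", x$labor)
  row("Reagents", x$reagents)
  row("Platform", x$platform)
  row("Extraction", x$extraction)
  row(sprintf("Overheads (%.0f%%)", 100 * x$overhead_rate), x$overheads)
  cat(sprintf("  %-22s %10.2f\n", "Total", round_cents(x$total)))
  excl <- attr(x, "excluded_equipment")
  if (length(excl)) {
    cat("  (negligible equipment excluded:", paste(excl, collapse = ", "),
        ")\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cost_breakdown <- function(x, ...) {
  data.frame(assay = x$assay, labor = x$labor, reagents = x$reagents,
             platform = x$platform, extraction = x$extraction,
             subtotal = x$subtotal, overheads = x$overheads,
             total = x$total, stringsAsFactors = FALSE)
}
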