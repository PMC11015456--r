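#' A targeted-therapy regimen
#'
#' Drug cost projection for one actionable gene: monthly VAT-inclusive
#' price (drug VAT 10% in the reference jurisdiction, assumed already in
#' the price) times the median progression-free survival (PFS) on the
#' drug, at standard dosage with no treatment interruptions. An optional
#' second line contributes `uptake x monthly x PFS`, where uptake is the
#' fraction of patients who actually go on to receive it.
#'
#' Months are continuous: PFS medians are quoted in decimal months.
#'
#' @param gene Target gene (e.g. `"EGFR"`).
#' @param drug First-line drug name(s).
#' @param monthly_cost First-line monthly cost, EUR VAT-inclusive, `>= 0`.
#' @param pfs_months First-line median PFS in months, `>= 0`.
#' @param dosage Free-text dosage annotation (optional).
#' @param second_line Optional list with `drug`, `monthly_cost`,
#'   `pfs_months`, `uptake` (fraction in `[0, 1]`).
#' @return A `therapy_regimen` object.
#' @export
#' @examples
#' therapy_regimen("ALK", "alectinib", 4027.2, pfs_months = 10)
therapy_regimen <- function(gene, drug, monthly_cost, pfs_months,
                            dosage = NA_character_, second_line = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  stopifnot(is.numeric(monthly_cost), monthly_cost >= 0,
            is.numeric(pfs_months), pfs_months >= 0)
  if (!is.null(second_line)) {
    stopifnot(is.list(second_line),
              all(c("monthly_cost", "pfs_months", "uptake") %in%
                    names(second_line)))
    stopifnot(second_line$monthly_cost >= 0, second_line$pfs_months >= 0,
              second_line$uptake >= 0, second_line$uptake <= 1)
  }
  structure(list(gene = gene, drug = drug,
                 monthly_cost = as.numeric(monthly_cost),
                 pfs_months = as.numeric(pfs_months), dosage = dosage,
                 second_line = second_line),
            class = "therapy_regimen")
}

#' Expected drug cost of a regimen
#'
#' `monthly1 x PFS1 + uptake x monthly2 x PFS2` (second term zero without
#' a second line). Linear in both monthly price and PFS; no interruption
#' or dose-reduction adjustment.
#'
#' @param regimen A [therapy_regimen()].
#' @return Expected per-patient drug cost in EUR.
#' @export
#' @examples
#' regimen_cost(therapy_regimen("ALK", "alectinib", 4027.2, 10))  # 40272
regimen_cost <- function(regimen) {
  stopifnot(inherits(regimen, "therapy_regimen"))
  cost <- regimen$monthly_cost * regimen$pfs_months
  sl <- regimen$second_line
  if (!is.null(sl)) {
    cost <- cost + sl$uptake * sl$monthly_cost * sl$pfs_months
  }
  cost
}

#' Cohort-level therapy cost summary
#'
#' @param regimens List of [therapy_regimen()] objects.
#' @param counts Integer vector, patients treated under each regimen
#'   (same length as `regimens`, all `>= 0`).
#' @return A `therapy_summary`: total EUR, number treated, mean per
#'   treated patient (`NA` and reported "undefined" when nobody is
#'   treated), and a per-regimen breakdown data frame.
#' @export
cohort_therapy_cost <- function(regimens, counts) {
  stopifnot(is.list(regimens), length(regimens) == length(counts),
            is.numeric(counts), all(counts >= 0))
  per_patient <- vapply(regimens, regimen_cost, numeric(1))
  genes <- vapply(regimens, function(r) r$gene, character(1))
  total <- sum(counts * per_patient)
  n <- sum(counts)
  structure(list(total = total, n_treated = n,
                 mean_per_treated = if (n > 0) total / n else NA_real_,
                 breakdown = data.frame(gene = genes, n = counts,
                                        per_patient = per_patient,
                                        subtotal = counts * per_patient,
                                        stringsAsFactors = FALSE)),
            class = "therapy_summary")
}

#' @export
print.therapy_summary <- function(x, ...) {
  cat("Targeted-therapy cost projection\n")
  print(x$breakdown, row.names = FALSE)
  mean_txt <- if (is.na(x$mean_per_treated)) "undefined"
              else format_eur(x$mean_per_treated)
  cat("  total:", format_eur(euro_floor(x$total), 0),
      " mean per treated patient:", mean_txt, "\n")
  invisible(x)
}

#' Diagnosis versus treatment cost shares
#'
#' Splits the combined diagnostic + therapeutic spend into two
#' percentage shares, `100 d/(d+t)` and `100 t/(d+t)`, at full precision.
#'
#' @param diagnostic_cost Diagnostic (molecular testing) cost, `>= 0`.
#' @param therapy_cost Therapy cost, `>= 0`; the two must not both be 0.
#' @return Named vector `c(diagnosis = , treatment = )` in percent.
#' @seealso [present_shares()] for the rounded one-decimal display.
#' @export
#' @examples
#' diagnosis_treatment_ratio(1048, 74363)  # ~ (1.39, 98.61)
diagnosis_treatment_ratio <- function(diagnostic_cost, therapy_cost) {
  stopifnot(is.numeric(diagnostic_cost), diagnostic_cost >= 0,
            is.numeric(therapy_cost), therapy_cost >= 0)
  denom <- diagnostic_cost + therapy_cost
  if (denom == 0) stop("both costs are zero; ratio undefined",
                       call. = FALSE)
  c(diagnosis = 100 * diagnostic_cost / denom,
    treatment = 100 * therapy_cost / denom)
}

#' Round percentage shares to one decimal, preserving the 100% sum
#'
#' Each share is rounded to one decimal; any residual from rounding is
#' assigned to the larger share so the displayed pair always sums to
#' exactly 100.0.
#'
#' @param shares Named numeric vector of percentages summing to 100.
#' @return Rounded shares summing to exactly 100.
#' @export
present_shares <- function(shares) {
  stopifnot(is.numeric(shares), abs(sum(shares) - 100) < 1e-6)
  r <- round(shares, 1)
  resid <- 100 - sum(r)
  if (abs(resid) > 1e-9) {
    big <- which.max(shares)
    r[big] <- r[big] + resid
  }
  r
}
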