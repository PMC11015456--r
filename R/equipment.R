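#' A piece of laboratory equipment
#'
#' Annualized with straight-line depreciation and zero residual value:
#' the VAT-inclusive purchase price is spread over the depreciation period
#' (5 years for main platforms; ancillary instruments such as microscopes
#' or microtomes conventionally use 10), annual maintenance/technical
#' support is added, and the annual total is divided by the number of
#' samples the platform processes in a year.
#'
#' @param name Equipment name.
#' @param purchase_price Purchase price in EUR, `>= 0`.
#' @param vat_rate VAT rate for the purchase, default `0.22`.
#' @param vat_included Is `purchase_price` already VAT-inclusive?
#' @param annual_maintenance Annual maintenance + technical assistance in
#'   EUR. Whether such contracts are quoted gross is supplier-dependent,
#'   so the flag `maintenance_vat_included` is explicit (default `TRUE`).
#' @param maintenance_vat_included Is the maintenance figure VAT-inclusive?
#' @param depreciation_years Depreciation period; 5 or 10 years.
#' @param annual_samples Samples processed on the platform per year; `> 0`.
#' @return An `equipment` object.
#' @export
equipment <- function(name, purchase_price, vat_rate = 0.22,
                      vat_included = FALSE, annual_maintenance = 0,
                      maintenance_vat_included = TRUE,
                      depreciation_years = 5L, annual_samples) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(purchase_price) || !is.finite(purchase_price) ||
      purchase_price < 0) {
    stop("purchase_price must be finite and >= 0", call. = FALSE)
  }
  check_vat_rate(vat_rate)
  dep <- as.integer(depreciation_years)
  if (is.na(dep) || !dep %in% c(5L, 10L)) {
    stop("depreciation_years must be 5 or 10", call. = FALSE)
  }
  ann <- as.integer(annual_samples)
  if (is.na(ann) || ann <= 0L) {
    stop("annual_samples must be an integer > 0", call. = FALSE)
  }
  if (!is.numeric(annual_maintenance) || annual_maintenance < 0) {
    stop("annual_maintenance must be >= 0", call. = FALSE)
  }
  structure(list(name = name, purchase_price = as.numeric(purchase_price),
                 vat_rate = vat_rate, vat_included = isTRUE(vat_included),
                 annual_maintenance = as.numeric(annual_maintenance),
                 maintenance_vat_included = isTRUE(maintenance_vat_included),
                 depreciation_years = dep, annual_samples = ann),
            class = "equipment")
}

#' Annual cost of a piece of equipment
#'
#' VAT-inclusive purchase price / depreciation years + annual
#' maintenance (grossed up if quoted net).
#'
#' @param equip An [equipment()] object.
#' @return Annual cost in EUR.
#' @export
equipment_annual_cost <- function(equip) {
  stopifnot(inherits(equip, "equipment"))
  gross <- if (equip$vat_included) equip$purchase_price
           else apply_vat(equip$purchase_price, equip$vat_rate)
  maint <- if (equip$maintenance_vat_included) equip$annual_maintenance
           else apply_vat(equip$annual_maintenance, equip$vat_rate)
  gross / equip$depreciation_years + maint
}

#' Per-sample equipment (platform) cost
#'
#' Annual cost divided by annual samples; satisfies the conservation
#' identity `equipment_cost_per_sample(e) * e$annual_samples ==
#' equipment_annual_cost(e)`.
#'
#' @param equip An [equipment()] object.
#' @return Per-sample cost in EUR.
#' @export
#' @examples
#' seq_platform <- equipment("sequencer", 250000, annual_maintenance = 19000,
#'                           annual_samples = 500)
#' equipment_cost_per_sample(seq_platform)  # 160
equipment_cost_per_sample <- function(equip) {
  equipment_annual_cost(equip) / equip$annual_samples
}

#' Is a piece of equipment negligible?
#'
#' Ancillary instruments (microscopes, microtomes, water baths, cooling
#' plates, quantification devices) whose per-sample cost falls under a
#' threshold are excluded from the platform component, mirroring common
#' costing practice where high annual throughput makes their contribution
#' immaterial. The comparison is a strict less-than, so an item exactly at
#' the threshold is kept.
#'
#' @param equip An [equipment()] object.
#' @param threshold Per-sample EUR threshold, `>= 0` (default 0.50).
#' @return `TRUE` iff `equipment_cost_per_sample(equip) < threshold`.
#' @export
is_negligible_equipment <- function(equip, threshold = 0.50) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  equipment_cost_per_sample(equip) < threshold
}
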