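#' A consumable item
#'
#' One consumable (kit, chip, reagent pack) entering a per-sample cost.
#' Two prorating rules exist:
#'
#' * per-pack items ("reagent saturation"): the pack price is divided by
#'   the number of samples the pack can actually process;
#' * per-run items ("machine saturation", `per_run = TRUE`): the price is
#'   divided by the billable samples per run, i.e. run capacity minus the
#'   positive/negative control slots, taken from a [run_profile()].
#'
#' Prices may be entered net of VAT (default, uplifted by `vat_rate`) or
#' already VAT-inclusive (`vat_included = TRUE`, stored as-is; applying
#' VAT again is rejected, see [apply_vat()]).
#'
#' @param name Item name.
#' @param pack_price Pack (or per-run) price in EUR, `>= 0`.
#' @param vat_rate VAT rate for goods, default `0.22`.
#' @param samples_per_pack Reagent saturation; integer `>= 1`.
#' @param vat_included Is `pack_price` already VAT-inclusive?
#' @param per_run Prorate by billable samples per run instead of per pack?
#' @return A `consumable_item` object.
#' @export
consumable_item <- function(name, pack_price, vat_rate = 0.22,
                            samples_per_pack = 1L, vat_included = FALSE,
                            per_run = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(pack_price) || length(pack_price) != 1L ||
      !is.finite(pack_price) || pack_price < 0) {
    stop("pack_price must be a single finite number >= 0", call. = FALSE)
  }
  check_vat_rate(vat_rate)
  spp <- as.integer(samples_per_pack)
  if (is.na(spp) || spp < 1L) {
    stop("samples_per_pack must be an integer >= 1", call. = FALSE)
  }
  structure(list(name = name, pack_price = as.numeric(pack_price),
                 vat_rate = vat_rate, samples_per_pack = spp,
                 vat_included = isTRUE(vat_included),
                 per_run = isTRUE(per_run)),
            class = "consumable_item")
}

#' Gross (VAT-inclusive) price of a consumable item
#' @param item A [consumable_item()].
#' @return Price in EUR including VAT.
#' @export
item_gross_price <- function(item) {
  stopifnot(inherits(item, "consumable_item"))
  if (item$vat_included) item$pack_price
  else apply_vat(item$pack_price, item$vat_rate)
}

#' Sequencing/assay run profile (machine saturation)
#'
#' @param capacity Samples per run, integer `>= 1`.
#' @param controls Positive/negative control slots per run; must leave at
#'   least one billable sample (`0 <= controls < capacity`).
#' @return A `run_profile` with `$billable = capacity - controls`.
#' @export
run_profile <- function(capacity, controls = 0L) {
  cap <- as.integer(capacity)
  ctl <- as.integer(controls)
  if (is.na(cap) || cap < 1L) stop("capacity must be >= 1", call. = FALSE)
  if (is.na(ctl) || ctl < 0L) stop("controls must be >= 0", call. = FALSE)
  if (ctl >= cap) stop("no billable samples per run", call. = FALSE)
  structure(list(capacity = cap, controls = ctl, billable = cap - ctl),
            class = "run_profile")
}

#' Per-sample consumable cost
#'
#' Sums VAT-inclusive item prices prorated by reagent saturation (per-pack
#' items) or machine saturation (per-run items, divided by the billable
#' samples of `run`). An empty item list costs zero.
#'
#' @param items List of [consumable_item()] objects.
#' @param run A [run_profile()]; required if any item is `per_run`.
#' @return Per-sample consumable cost in EUR (VAT-inclusive).
#' @export
#' @examples
#' consumable_cost_per_sample(
#'   list(consumable_item("kit", 100, samples_per_pack = 10)))  # 12.20
consumable_cost_per_sample <- function(items, run = NULL) {
  stopifnot(is.list(items))
  if (length(items) == 0L) return(0)
  total <- 0
  for (it in items) {
    if (!inherits(it, "consumable_item")) {
      stop("items must be consumable_item objects", call. = FALSE)
    }
    gross <- item_gross_price(it)
    if (it$per_run) {
      if (is.null(run)) {
        stop("item '", it$name,
             "' is run-scoped but no run profile was given", call. = FALSE)
      }
      stopifnot(inherits(run, "run_profile"))
      total <- total + gross / run$billable
    } else {
      total <- total + gross / it$samples_per_pack
    }
  }
  total
}
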