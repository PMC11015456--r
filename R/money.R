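#' Monetary helpers: VAT and presentation rounding
#'
#' All costs in this package are handled in euros (EUR) at full double
#' precision internally; rounding happens only at presentation. VAT is
#' applied to goods (reagents, platforms, drugs), never to labor.
#'
#' @name money
#' @keywords internal
NULL

#' Apply VAT to a net price
#'
#' Returns the VAT-inclusive (gross) price `net * (1 + rate)`. Prices that
#' are already flagged VAT-inclusive must not be uplifted again: passing
#' `vat_included = TRUE` is an error, which guards against double taxation
#' when configurations mix net and gross figures.
#'
#' @param net Net (VAT-exclusive) amount in EUR.
#' @param rate VAT rate as a fraction in `[0, 1)`, e.g. `0.22` for goods.
#' @param vat_included Flag carried by the price; must be `FALSE` here.
#' @return Gross amount in EUR.
#' @seealso [remove_vat()]
#' @export
#' @examples
#' apply_vat(100, 0.22)   # 122
apply_vat <- function(net, rate, vat_included = FALSE) {
  check_vat_rate(rate)
  if (isTRUE(vat_included)) {
    stop("price is already VAT-inclusive; refusing to apply VAT again",
         call. = FALSE)
  }
  stopifnot(is.numeric(net), all(is.finite(net)))
  net * (1 + rate)
}

#' Remove VAT from a gross price
#'
#' @param gross VAT-inclusive amount in EUR.
#' @param rate VAT rate as a fraction in `[0, 1)`.
#' @return Net amount in EUR; `remove_vat(apply_vat(x, r), r)` round-trips
#'   to machine precision.
#' @export
remove_vat <- function(gross, rate) {
  check_vat_rate(rate)
  gross / (1 + rate)
}

check_vat_rate <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0 || rate >= 1) {
    stop("VAT rate must be a single fraction in [0, 1), got: ",
         format(rate), call. = FALSE)
  }
  invisible(rate)
}

#' Round to euro cents, half to even
#'
#' Presentation rounding used for all printed unit costs. Ties at exactly
#' half a cent go to the even cent (banker's rounding), evaluated on the
#' decimal cents scale with a small tolerance so that decimal ties that are
#' not exactly representable in binary (e.g. 1048.325) are still treated
#' as ties: 1048.325 -> 1048.32, 198.125 -> 198.12, 68.2625 -> 68.26.
#'
#' @param x Numeric vector of EUR amounts.
#' @return `x` rounded to 2 decimals.
#' @export
round_cents <- function(x) {
  stopifnot(is.numeric(x))
  cents <- x * 100
  lo <- floor(cents)
  frac <- cents - lo
  tie <- abs(frac - 0.5) < 1e-6
  out <- ifelse(tie,
                ifelse(lo %% 2 == 0, lo, lo + 1),  # to even cent
                round(cents))
  out / 100
}

#' Truncate to whole euros
#'
#' Cohort-level figures are reported truncated (floored) to whole euros,
#' e.g. 171924.48 -> 171924. A tiny tolerance guards against amounts that
#' are whole euros up to floating-point error.
#'
#' @param x Numeric vector of EUR amounts (non-negative use intended).
#' @return Whole-euro values.
#' @export
euro_floor <- function(x) {
  stopifnot(is.numeric(x))
  floor(x + 1e-9)
}

#' Format an EUR amount for display
#' @param x Numeric EUR amount.
#' @param digits Decimals to show (default cents).
#' @return Character vector like `"EUR 1048.32"`.
#' @keywords internal
format_eur <- function(x, digits = 2) {
  paste0("EUR ", formatC(x, format = "f", digits = digits, big.mark = ","))
}
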