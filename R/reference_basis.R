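#' Reference basis: international reference prices, PPP rates, discounting
#'
#' Bundles everything needed to put a local procurement price and an
#' international reference price (IRP) on the same 2013-CNY scale:
#' per-unit IRPs in USD for the reference period 2011-2013, purchasing-power
#' -parity conversion rates (CNY per international dollar) per year, and
#' discount factors that deflate 2014-2016 prices back to the 2013 price
#' level. When no explicit discount-factor table is supplied, factors are
#' derived from a constant annual rate `r` as \eqn{DF(y) = (1+r)^{2013-y}}.
#'
#' @param irp Tibble with `drug_id`, `year` (2011-2013), `irp_usd_per_unit`
#'   (USD per reference-strength unit, all positive).
#' @param ppp Tibble with `year`, `rate` (CNY per international dollar).
#' @param df Optional tibble with `year`, `df` giving explicit discount
#'   factors to the 2013 basis; must satisfy `df == 1` at 2013 if present.
#' @param discount_rate Annual discount rate used when `df` is `NULL`
#'   (default 0.03).
#' @return An object of class `reference_basis`.
#' @examples
#' b <- reference_basis(
#'   irp = tibble::tibble(drug_id = "amoxicillin", year = 2011:2013,
#'                        irp_usd_per_unit = 0.03),
#'   ppp = tibble::tibble(year = 2011:2013, rate = c(3.506, 3.524, 3.545))
#' )
#' discount_factor(2016, b) # (1.03)^-3
#' @export
reference_basis <- function(irp, ppp, df = NULL, discount_rate = 0.03) {
  irp <- tibble::as_tibble(irp)
  ppp <- tibble::as_tibble(ppp)
  stopifnot(all(c("drug_id", "year", "irp_usd_per_unit") %in% names(irp)),
            all(c("year", "rate") %in% names(ppp)))
  if (any(irp$irp_usd_per_unit <= 0)) rlang::abort("IRPs must be positive")
  if (any(ppp$rate <= 0)) rlang::abort("PPP rates must be positive")
  if (is.null(df)) {
    df <- tibble::tibble(year = 2011:2016,
                         df = (1 + discount_rate)^(2013 - 2011:2016))
  } else {
    df <- tibble::as_tibble(df)
    stopifnot(all(c("year", "df") %in% names(df)))
    if (2013 %in% df$year && abs(df$df[df$year == 2013] - 1) > 1e-12) {
      rlang::abort("discount factor at 2013 must equal 1")
    }
  }
  structure(list(irp = irp, ppp = ppp, df = df,
                 discount_rate = discount_rate),
            class = "reference_basis")
}

#' @export
print.reference_basis <- function(x, ...) {
  cat("<reference_basis>\n")
  cat("  IRPs: ", length(unique(x$irp$drug_id)), " drugs, years ",
      paste(range(x$irp$year), collapse = "-"), "\n", sep = "")
  cat("  PPP years: ", paste(sort(x$ppp$year), collapse = ", "), "\n",
      sep = "")
  cat("  DF years: ", paste(sort(x$df$year), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Discount factor to the 2013 basis
#'
#' @param year Integer vector of years.
#' @param basis A [reference_basis()].
#' @return Numeric vector of discount factors; `DF(2013) == 1`.
#' @export
discount_factor <- function(year, basis) {
  i <- match(year, basis$df$year)
  if (anyNA(i)) {
    rlang::abort(paste0("no discount factor for year ",
                        paste(year[is.na(i)], collapse = ", ")))
  }
  basis$df$df[i]
}

#' Convert an international reference price to CNY
#'
#' Multiplies a USD-per-unit IRP by the purchasing-power-parity conversion
#' rate of its year.
#'
#' @param irp_usd USD per reference unit.
#' @param year Year of the IRP (a PPP rate must exist for it).
#' @param basis A [reference_basis()].
#' @return CNY per reference unit.
#' @export
irp_to_cny <- function(irp_usd, year, basis) {
  i <- match(year, basis$ppp$year)
  if (anyNA(i)) {
    rlang::abort(paste0("no PPP rate for year ",
                        paste(unique(year[is.na(i)]), collapse = ", ")))
  }
  irp_usd * basis$ppp$rate[i]
}

#' Deflate a price to the 2013 basis
#'
#' Prices from 2013 or earlier are returned unchanged; prices from later
#' years are multiplied by that year's discount factor.
#'
#' @param price Price in CNY of `year`.
#' @param year Year the price was observed.
#' @param basis A [reference_basis()].
#' @return Price expressed at the 2013 price level.
#' @export
deflate_price <- function(price, year, basis) {
  out <- price
  late <- year > 2013
  if (any(late)) out[late] <- price[late] * discount_factor(year[late], basis)
  out
}

#' Deflate a batch of unit prices exactly once
#'
#' Adds a `price_2013` column to a unit-price tibble (see
#' [smallest_unit_price()]). The batch is flagged, and deflating it a second
#' time is an error: double deflation is a silent way to understate recent
#' prices.
#'
#' @param unit_prices Unit-price tibble with `price_per_unit` and `year`.
#' @param basis A [reference_basis()].
#' @return The tibble with `price_2013` added and a `price_basis` attribute
#'   set to `"2013"`.
#' @export
deflate_prices <- function(unit_prices, basis) {
  if (identical(attr(unit_prices, "price_basis"), "2013")) {
    rlang::abort("prices already deflated to the 2013 basis")
  }
  unit_prices$price_2013 <- deflate_price(unit_prices$price_per_unit,
                                          unit_prices$year, basis)
  attr(unit_prices, "price_basis") <- "2013"
  unit_prices
}
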