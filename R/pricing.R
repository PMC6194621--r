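#' Median unit price of one stratum
#'
#' Two-level (facility-first) median: each hospital contributes the median
#' of its own transactions, and the stratum value is the median of those
#' hospital medians. Facility-level medians are the WHO/HAI convention and
#' keep a hospital with many transactions from dominating the stratum. Set
#' `aggregate = "transactions"` to pool all transactions instead.
#'
#' @param unit_prices Unit-price tibble (one row per transaction) with a
#'   `hospital_id` column.
#' @param value Price column to aggregate (`"price_per_unit"`, or
#'   `"price_2013"` after [deflate_prices()]).
#' @param aggregate `"hospitals"` (default, two-level) or `"transactions"`.
#' @return The stratum median (a single number).
#' @export
median_unit_price <- function(unit_prices, value = "price_per_unit",
                              aggregate = c("hospitals", "transactions")) {
  aggregate <- match.arg(aggregate)
  if (nrow(unit_prices) == 0) rlang::abort("empty stratum")
  x <- unit_prices[[value]]
  if (aggregate == "transactions") return(stats::median(x))
  h <- tapply(x, unit_prices$hospital_id, stats::median)
  stats::median(as.numeric(h))
}

#' Median price ratio
#'
#' The ratio of a medicine's median local unit price to its international
#' reference price on the same currency basis. An MPR of 2 means the local
#' price is twice the international reference price; an MPR of 1 or less
#' indicates efficient procurement.
#'
#' @param median_price Median local price, CNY per reference unit (2013
#'   basis for post-2013 years).
#' @param irp_cny Reference price, CNY per reference unit.
#' @return Unitless ratio.
#' @examples
#' mpr(0.70, 0.35) # 2
#' @export
mpr <- function(median_price, irp_cny) {
  if (any(median_price <= 0) || any(irp_cny <= 0)) {
    rlang::abort("prices and reference prices must be positive")
  }
  median_price / irp_cny
}

#' @noRd
irp_cny_lookup <- function(basis, drug_ids, years) {
  grid <- tidyr::crossing(drug_id = drug_ids, year = years)
  ref_year <- pmin(grid$year, 2013)
  i <- match(paste(grid$drug_id, ref_year),
             paste(basis$irp$drug_id, basis$irp$year))
  grid$irp_cny <- ifelse(
    is.na(i), NA_real_,
    irp_to_cny(basis$irp$irp_usd_per_unit[i], ref_year, basis)
  )
  grid
}

#' Stratified median-price-ratio table
#'
#' Produces MPR cells over the full stratification grid. Prices must have
#' been deflated once with [deflate_prices()]: 2011-2013 prices are compared
#' with their same-year reference prices, 2014-2016 prices (now on the 2013
#' basis) with the 2013 reference prices.
#'
#' @param unit_prices Deflated unit-price tibble.
#' @param basis A [reference_basis()].
#' @param drugs Drug ids to tabulate (default: all with a reference price).
#' @param years Years (default: all present).
#' @param regions,brands Strata, as in [availability_table()].
#' @param aggregate Passed to [median_unit_price()].
#' @return Tibble of MPR cells: `drug_id, year, region, brand_status,
#'   n_hospitals, median_price_2013, irp_cny, mpr`.
#' @export
mpr_table <- function(unit_prices, basis, drugs = NULL, years = NULL,
                      regions = c("nationwide", region_levels()),
                      brands = c("all", "innovator_brand", "generic"),
                      aggregate = c("hospitals", "transactions")) {
  aggregate <- match.arg(aggregate)
  if (!identical(attr(unit_prices, "price_basis"), "2013")) {
    rlang::abort("unit prices must be deflated with deflate_prices() first")
  }
  if (is.null(years)) years <- sort(unique(unit_prices$year))
  with_irp <- intersect(unique(unit_prices$drug_id),
                        unique(basis$irp$drug_id))
  if (is.null(drugs)) {
    drugs <- sort(with_irp)
  } else if (length(setdiff(drugs, with_irp))) {
    rlang::warn(paste0("dropping drug(s) without reference price: ",
                       paste(setdiff(drugs, with_irp), collapse = ", ")))
    drugs <- intersect(drugs, with_irp)
  }
  if (!length(drugs)) rlang::abort("no drugs with a reference price")
  irp <- irp_cny_lookup(basis, drugs, years)

  grid <- tidyr::crossing(region = regions, brand_status = brands)
  cells <- purrr::pmap(grid, function(region, brand_status) {
    up <- unit_prices[unit_prices$drug_id %in% drugs &
                        unit_prices$year %in% years, ]
    if (region != "nationwide") up <- up[up$region == region, ]
    if (brand_status != "all") up <- up[up$brand_status == brand_status, ]
    if (nrow(up) == 0) return(NULL)
    med <- up |>
      dplyr::group_by(.data$drug_id, .data$year, .data$hospital_id) |>
      dplyr::summarise(h_med = stats::median(.data$price_2013),
                       .groups = "drop_last")
    med <- if (aggregate == "hospitals") {
      dplyr::summarise(med, median_price_2013 = stats::median(.data$h_med),
                       n_hospitals = dplyr::n(), .groups = "drop")
    } else {
      up |>
        dplyr::group_by(.data$drug_id, .data$year) |>
        dplyr::summarise(
          median_price_2013 = stats::median(.data$price_2013),
          n_hospitals = dplyr::n_distinct(.data$hospital_id),
          .groups = "drop"
        )
    }
    med$region <- region
    med$brand_status <- brand_status
    med
  })
  dplyr::bind_rows(cells) |>
    dplyr::left_join(irp, by = c("drug_id", "year")) |>
    dplyr::mutate(mpr = mpr(.data$median_price_2013, .data$irp_cny)) |>
    dplyr::select("drug_id", "year", "region", "brand_status",
                  "n_hospitals", "median_price_2013", "irp_cny", "mpr") |>
    dplyr::arrange(.data$drug_id, .data$year, .data$region,
                   .data$brand_status)
}

#' Basket median MPR
#'
#' @param x Numeric vector of per-drug MPRs.
#' @return Median with the even-count (mean of central pair) convention.
#' @export
median_mpr <- function(x) median_availability(x)

#' Product-specific delta MPR
#'
#' Same contract as [delta_product_specific()], applied to MPR cells.
#'
#' @inheritParams delta_product_specific
#' @export
delta_mpr <- function(cells, year_pair = NULL) {
  delta_product_specific(cells, value = "mpr", year_pair = year_pair)
}

#' Innovator-brand to generic MPR ratio
#'
#' @param mpr_ib Median MPR of innovator-brand products.
#' @param mpr_g Median MPR of generic products.
#' @param digits Round the ratio (half-to-even) for reporting; `NULL`
#'   (default) keeps full precision.
#' @return `mpr_ib / mpr_g`.
#' @examples
#' ib_generic_ratio(29.51, 8.06, digits = 2) # 3.66
#' @export
ib_generic_ratio <- function(mpr_ib, mpr_g, digits = NULL) {
  if (any(mpr_ib <= 0) || any(mpr_g <= 0)) {
    rlang::abort("MPRs must be positive")
  }
  r <- mpr_ib / mpr_g
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Published national median MPRs by brand status
#'
#' Median price ratios for innovator-brand and generic essential medicines
#' as published in a national survey of Chinese secondary and tertiary
#' hospitals, 2011-2016, together with the printed innovator/generic ratio
#' column. Shipped so that the ratio arithmetic can be reproduced without
#' any external data.
#'
#' @return Tibble with `year`, `mpr_innovator_brand`, `mpr_generic`,
#'   `printed_ratio`.
#' @export
published_mpr_summary <- function() {
  path <- system.file("extdata", "published_mpr_summary.csv",
                      package = "medaccess", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
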