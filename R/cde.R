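#' Daily treatment cost from a unit price and a defined daily dose
#'
#' The cost of one treatment day is the price per reference-strength unit
#' scaled by how many reference units the defined daily dose (DDD)
#' represents:
#' `daily = price_per_unit * ddd / reference_strength` (after expressing the
#' DDD in the reference-strength unit).
#'
#' @param price_per_unit CNY per reference-strength unit.
#' @param def One-row drug definition (or vectors recycled against
#'   `price_per_unit`) with `ddd_value`, `ddd_unit`,
#'   `reference_strength_value`, `reference_strength_unit`.
#' @return CNY per treatment day.
#' @examples
#' daily_cost(0.5, dplyr::filter(default_drug_list(), drug_id == "metformin"))
#' @export
daily_cost <- function(price_per_unit, def) {
  if (any(is.na(def$ddd_value))) {
    rlang::abort(paste0("missing DDD for: ",
                        paste(unique(def$drug_id[is.na(def$ddd_value)]),
                              collapse = ", ")))
  }
  if (any(price_per_unit <= 0)) rlang::abort("unit price must be positive")
  ddd_ref <- convert_units(def$ddd_value, def$ddd_unit,
                           def$reference_strength_unit)
  price_per_unit * ddd_ref / def$reference_strength_value
}

#' Annualize a daily treatment cost
#'
#' Chronic treatments are costed as lifelong daily therapy over a 365-day
#' year.
#'
#' @param daily CNY per day.
#' @param days Days per year (default 365).
#' @return CNY per year.
#' @export
annualize <- function(daily, days = 365) {
  if (any(daily < 0)) rlang::abort("daily cost must be non-negative")
  daily * days
}

#' Incidence of catastrophic drug expenditure
#'
#' A person with income `x` spends a share `annual_cost / x` of income on
#' the drug; the share is at least `threshold` exactly when
#' `x <= annual_cost / threshold`. Incidence is therefore the population
#' fraction at or below that income,
#' `100 * cdf(annual_cost / threshold)` per cent. The threshold boundary is
#' closed ("a share of 10 per cent or more").
#'
#' @param annual_cost Annual drug cost, CNY/year (non-negative).
#' @param dist An [fit_income_distribution()] result.
#' @param threshold Budget-share threshold in (0, 1); conventionally 0.10
#'   with 0.075 and 0.125 as sensitivity settings.
#' @return Incidence in per cent, vectorised over `annual_cost`.
#' @examples
#' tab <- income_group_table(2013, "urban", rep(0.2, 5),
#'                           lognormal_group_means(9.2, 0.5, rep(0.2, 5)))
#' d <- fit_income_distribution(tab)
#' cde_incidence(1000, d, 0.10)
#' @export
cde_incidence <- function(annual_cost, dist, threshold) {
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must be a single fraction in (0, 1)")
  }
  if (any(annual_cost < 0)) rlang::abort("annual cost must be non-negative")
  100 * dist$cdf(annual_cost / threshold)
}

#' Catastrophic-drug-expenditure grid
#'
#' Composes [daily_cost()], [annualize()] and [cde_incidence()] over a full
#' treatment-by-brand-by-year-by-sector-by-threshold grid. Prices are
#' nominal same-year prices compared with same-year incomes (the 2013-basis
#' deflation exists only to bridge the missing post-2013 reference prices
#' in the MPR chain, not to restate expenditures).
#'
#' @param price_cells Tibble with `drug_id`, `brand_status`, `year` and a
#'   nominal median unit-price column named `price_per_unit`.
#' @param income_dists List of [fit_income_distribution()] results covering
#'   the `(year, sector)` combinations required.
#' @param drugs Drug-definition table supplying DDDs.
#' @param thresholds Budget-share thresholds (default `c(0.075, 0.10,
#'   0.125)`).
#' @param sectors Sectors to tabulate (default urban and rural).
#' @param days Days per year for annualization.
#' @return Tibble of CDE cells: `drug_id, brand_status, threshold, year,
#'   sector, annual_cost, incidence_pct`, deterministically ordered.
#' @export
cde_table <- function(price_cells, income_dists, drugs,
                      thresholds = c(0.075, 0.10, 0.125),
                      sectors = c("urban", "rural"), days = 365) {
  keys <- vapply(income_dists, function(d) paste(d$year, d$sector),
                 character(1))
  need <- c("drug_id", "brand_status", "year", "price_per_unit")
  stopifnot(all(need %in% names(price_cells)))
  def <- drugs[match(price_cells$drug_id, drugs$drug_id), ]
  price_cells$annual_cost <- annualize(
    daily_cost(price_cells$price_per_unit, def), days = days
  )
  grid <- tidyr::crossing(
    price_cells[, c("drug_id", "brand_status", "year", "annual_cost")],
    sector = sectors,
    threshold = sort(thresholds)
  )
  i <- match(paste(grid$year, grid$sector), keys)
  if (anyNA(i)) {
    miss <- unique(paste(grid$year, grid$sector)[is.na(i)])
    rlang::abort(paste0("no income distribution for: ",
                        paste(miss, collapse = "; ")))
  }
  grid$incidence_pct <- vapply(seq_len(nrow(grid)), function(r) {
    cde_incidence(grid$annual_cost[r], income_dists[[i[r]]],
                  grid$threshold[r])
  }, numeric(1))
  dplyr::arrange(grid, .data$drug_id, .data$brand_status, .data$threshold,
                 .data$year, .data$sector)
}
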