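#' Availability of surveyed medicines across a hospital panel
#'
#' Availability of a medicine in a stratum-year is the percentage of panel
#' hospitals with at least one procurement record of that medicine in the
#' calendar-year window. The denominator is always the full panel roster of
#' the stratum — hospitals with no records at all still count — so panel
#' attrition cannot inflate availability. Brand-specific availability uses
#' the same denominator as overall availability.
#'
#' @param records Procurement-record tibble.
#' @param panel Panel roster tibble with `hospital_id`, `tier`, `region`
#'   (one row per member hospital).
#' @param drugs Character vector of drug ids to tabulate; defaults to all
#'   drugs present in `records`.
#' @param years Integer years; defaults to all years present in `records`.
#' @param regions Strata over regions: `"nationwide"` and/or region names.
#' @param brands `"all"` (either version counts) and/or specific brand
#'   statuses.
#' @param tiers `"all"` or specific hospital tiers.
#' @return A tibble of availability cells: `drug_id, year, region,
#'   brand_status, tier, n_hospitals` (panel size of the stratum),
#'   `n_stocking`, `availability_pct`.
#' @export
availability_table <- function(records, panel, drugs = NULL, years = NULL,
                               regions = c("nationwide", region_levels()),
                               brands = c("all", "innovator_brand", "generic"),
                               tiers = "all") {
  if (is.null(drugs)) drugs <- sort(unique(records$drug_id))
  if (is.null(years)) years <- sort(unique(records$year))
  if (!length(drugs)) rlang::abort("no drugs to tabulate")
  grid <- tidyr::crossing(region = regions, brand_status = brands,
                          tier = tiers)
  cells <- purrr::pmap(grid, function(region, brand_status, tier) {
    ph <- panel
    if (region != "nationwide") ph <- ph[ph$region == region, ]
    if (tier != "all") ph <- ph[ph$tier == tier, ]
    if (nrow(ph) == 0) {
      rlang::abort(paste0("empty stratum: region=", region, ", tier=", tier))
    }
    rr <- records[records$hospital_id %in% ph$hospital_id &
                    records$drug_id %in% drugs &
                    records$year %in% years, ]
    if (brand_status != "all") rr <- rr[rr$brand_status == brand_status, ]
    counts <- dplyr::count(
      dplyr::distinct(rr, .data$drug_id, .data$year, .data$hospital_id),
      .data$drug_id, .data$year, name = "n_stocking"
    )
    tidyr::crossing(drug_id = drugs, year = years) |>
      dplyr::left_join(counts, by = c("drug_id", "year")) |>
      dplyr::mutate(
        n_stocking = ifelse(is.na(.data$n_stocking), 0L, .data$n_stocking),
        region = region, brand_status = brand_status, tier = tier,
        n_hospitals = nrow(ph),
        availability_pct = 100 * .data$n_stocking / nrow(ph)
      )
  })
  dplyr::bind_rows(cells) |>
    dplyr::select("drug_id", "year", "region", "brand_status", "tier",
                  "n_hospitals", "n_stocking", "availability_pct") |>
    dplyr::arrange(.data$drug_id, .data$year, .data$region,
                   .data$brand_status, .data$tier)
}

#' Availability of one medicine in one stratum-year
#'
#' @inheritParams availability_table
#' @param drug_id Single drug id.
#' @param year Single survey year.
#' @param region `"nationwide"` or a region name.
#' @param brand_status `"all"` or a brand status.
#' @param tier `"all"` or a hospital tier.
#' @return One availability cell (tibble row), see [availability_table()].
#' @export
product_availability <- function(records, panel, drug_id, year,
                                 region = "nationwide", brand_status = "all",
                                 tier = "all") {
  availability_table(records, panel, drugs = drug_id, years = year,
                     regions = region, brands = brand_status, tiers = tier)
}

#' Median of a basket of per-drug values
#'
#' Median over the basket with the even-count convention (mean of the two
#' central order statistics). Used for the basket-level "median
#' availability" and "median MPR" summaries.
#'
#' @param x Numeric vector, one value per drug.
#' @return The median.
#' @export
median_availability <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) rlang::abort("empty basket")
  stats::median(x)
}

#' Product-specific year-on-year delta statistic
#'
#' For each pair of adjacent years, takes the difference of each product's
#' value between the two years and reports the median of those differences.
#' Products absent in either year of a pair are excluded from that pair's
#' median and counted in `n_excluded`.
#'
#' @param cells Tibble with columns `drug_id`, `year` and the value column —
#'   one stratum's worth of cells (filter or split beforehand).
#' @param value Name of the value column (e.g. `"availability_pct"`,
#'   `"mpr"`).
#' @param year_pair Optional length-2 integer vector restricting the
#'   computation to one `(from, to)` pair; default all adjacent pairs.
#' @return Tibble with `year_from`, `year_to`, `delta`, `n_drugs`,
#'   `n_excluded`.
#' @export
delta_product_specific <- function(cells, value = "availability_pct",
                                   year_pair = NULL) {
  stopifnot(value %in% names(cells))
  if (is.null(year_pair)) {
    ys <- sort(unique(cells$year))
    if (length(ys) < 2) rlang::abort("need at least two years")
    pairs <- cbind(ys[-length(ys)], ys[-1])
  } else {
    stopifnot(length(year_pair) == 2)
    pairs <- matrix(sort(year_pair), nrow = 1)
  }
  out <- apply(pairs, 1, function(p) {
    a <- cells[cells$year == p[1], c("drug_id", value)]
    b <- cells[cells$year == p[2], c("drug_id", value)]
    both <- intersect(a$drug_id, b$drug_id)
    n_union <- length(union(a$drug_id, b$drug_id))
    if (!length(both)) {
      rlang::abort(paste0("no drug present in both ", p[1], " and ", p[2]))
    }
    diffs <- b[[value]][match(both, b$drug_id)] -
      a[[value]][match(both, a$drug_id)]
    tibble::tibble(year_from = p[1], year_to = p[2],
                   delta = stats::median(diffs),
                   n_drugs = length(both),
                   n_excluded = n_union - length(both))
  })
  dplyr::bind_rows(out)
}

#' Stratified basket summary with delta columns
#'
#' Collapses per-drug availability cells to the familiar survey layout: one
#' row per stratum-year with the basket median and the product-specific
#' delta against the previous year.
#'
#' @param cells Output of [availability_table()] (or [mpr_table()] with
#'   `value = "mpr"`).
#' @param value Value column to summarise.
#' @return Tibble with `region`, `brand_status`, `tier` (when present),
#'   `year`, `median_value`, `delta`, `n_drugs`.
#' @export
summarize_availability <- function(cells, value = "availability_pct") {
  keys <- intersect(c("region", "brand_status", "tier"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      med <- df |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(median_value = median_availability(.data[[value]]),
                         n_drugs = dplyr::n(), .groups = "drop")
      if (length(unique(df$year)) > 1) {
        d <- delta_product_specific(df, value = value)
        med$delta <- d$delta[match(med$year, d$year_to)]
      } else {
        med$delta <- NA_real_
      }
      med
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(keys), "year", "median_value", "delta",
                  "n_drugs")
}
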