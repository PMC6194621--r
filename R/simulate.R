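#' Configuration for the synthetic procurement-panel generator
#'
#' Defines the study conditions of a simulated hospital procurement panel:
#' panel composition, per-drug stocking probabilities and price levels with
#' region / brand / year effects, transaction-level price dispersion, the
#' reference-price environment and grouped income tables with known
#' parameters. Every generated quantity is a deterministic function of
#' `seed`, and the analytic ground truth implied by the configuration is
#' returned alongside the data by [generate_panel()].
#'
#' Stocking probabilities are built per (drug, brand, region, year) as
#' `base * brand_factor^[innovator] * region_factor * year_factor +
#' year_offset`, truncated to `[0, 1]`; price levels (multiples of the
#' CNY reference price) as `base_level * brand_price_factor^[innovator] *
#' region_price_factor * year_price_factor`.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_secondary,n_tertiary Panel sizes by hospital tier.
#' @param drugs Drug-definition table ([default_drug_list()]).
#' @param years Survey years.
#' @param base_availability Named (by `drug_id`) vector of base generic
#'   stocking probabilities; default spreads 0.08-0.82 across the basket
#'   with azithromycin highest (0.85) and glibenclamide lowest (0.03).
#' @param brand_availability_factor Multiplier for innovator brands.
#' @param region_availability_factor Named multiplier per region.
#' @param year_availability_factor Named multiplier per year.
#' @param year_availability_offset Named additive probability offset per
#'   year (default 0; handy for injecting known uniform shifts).
#' @param base_price_level Named vector of generic price levels (multiples
#'   of the reference price); default log-spread 0.8-40.
#' @param brand_price_factor,region_price_factor,year_price_factor Price
#'   multipliers analogous to the availability factors.
#' @param price_dispersion Lognormal sigma of transaction prices around the
#'   cell's median price.
#' @param inflation Annual price inflation applied after 2013; the
#'   generated discount factors invert it exactly.
#' @param mean_monthly_records Poisson mean (truncated at 1, capped at 12)
#'   of monthly records per stocked hospital-drug-brand-year.
#' @param ppp Tibble `year`, `rate`: CNY per international dollar,
#'   2011-2013.
#' @param income Tibble `year`, `sector`, `meanlog`, `sdlog`, `n_groups`
#'   defining the per-capita income distributions; defaults echo published
#'   urban/rural per-capita incomes 2011-2014.
#' @param provinces Province-to-region table ([province_region_map()]).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 20211L,
    n_secondary = 396L, n_tertiary = 763L,
    drugs = default_drug_list(),
    years = 2011:2016,
    base_availability = NULL,
    brand_availability_factor = 0.7,
    region_availability_factor = c(eastern = 1.25, central = 0.90,
                                   western = 0.95),
    year_availability_factor = NULL,
    year_availability_offset = NULL,
    base_price_level = NULL,
    brand_price_factor = 4.5,
    region_price_factor = c(eastern = 2.1, central = 0.95, western = 0.95),
    year_price_factor = NULL,
    price_dispersion = 0.2,
    inflation = 0.03,
    mean_monthly_records = 6,
    ppp = default_ppp_table(),
    income = default_income_params(),
    provinces = province_region_map()) {
  drugs <- validate_drug_definitions(tibble::as_tibble(drugs))
  n <- nrow(drugs)
  if (is.null(base_availability)) {
    base_availability <- stats::setNames(seq(0.08, 0.82, length.out = n),
                                         drugs$drug_id)
    if ("azithromycin" %in% drugs$drug_id) {
      base_availability["azithromycin"] <- 0.85
    }
    if ("glibenclamide" %in% drugs$drug_id) {
      base_availability["glibenclamide"] <- 0.03
    }
  }
  if (is.null(base_price_level)) {
    base_price_level <- stats::setNames(
      rev(exp(seq(log(0.8), log(40), length.out = n))), drugs$drug_id)
  }
  if (is.null(year_availability_factor)) {
    defaults <- c(`2011` = 1, `2012` = 1.08, `2013` = 0.97, `2014` = 0.90,
                  `2015` = 1.05, `2016` = 0.93)
    year_availability_factor <- stats::setNames(
      ifelse(as.character(years) %in% names(defaults),
             defaults[as.character(years)], 1),
      as.character(years))
  }
  if (is.null(year_availability_offset)) {
    year_availability_offset <- stats::setNames(rep(0, length(years)),
                                                as.character(years))
  }
  if (is.null(year_price_factor)) {
    year_price_factor <- stats::setNames(rep(1, length(years)),
                                         as.character(years))
  }
  cfg <- list(
    seed = as.integer(seed),
    n_secondary = as.integer(n_secondary),
    n_tertiary = as.integer(n_tertiary),
    drugs = drugs, years = as.integer(years),
    base_availability = base_availability,
    brand_availability_factor = brand_availability_factor,
    region_availability_factor = region_availability_factor,
    year_availability_factor = year_availability_factor,
    year_availability_offset = year_availability_offset,
    base_price_level = base_price_level,
    brand_price_factor = brand_price_factor,
    region_price_factor = region_price_factor,
    year_price_factor = year_price_factor,
    price_dispersion = price_dispersion,
    inflation = inflation,
    mean_monthly_records = mean_monthly_records,
    ppp = tibble::as_tibble(ppp),
    income = tibble::as_tibble(income),
    provinces = tibble::as_tibble(provinces)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @noRd
validate_simulation_config <- function(cfg) {
  if (any(cfg$base_availability < 0 | cfg$base_availability > 1)) {
    rlang::abort("invalid probability: base_availability outside [0, 1]")
  }
  if (!setequal(names(cfg$base_availability), cfg$drugs$drug_id)) {
    rlang::abort("base_availability must be named by the drug ids")
  }
  if (!setequal(names(cfg$base_price_level), cfg$drugs$drug_id)) {
    rlang::abort("base_price_level must be named by the drug ids")
  }
  if (any(cfg$base_price_level <= 0)) {
    rlang::abort("price levels must be positive")
  }
  if (cfg$price_dispersion < 0) rlang::abort("dispersion must be >= 0")
  if (cfg$brand_availability_factor < 0 ||
      any(cfg$region_availability_factor < 0) ||
      any(cfg$year_availability_factor < 0)) {
    rlang::abort("invalid probability: negative availability factor")
  }
  if (cfg$inflation <= -1) rlang::abort("inflation must exceed -1")
  if (cfg$mean_monthly_records <= 0) {
    rlang::abort("mean_monthly_records must be positive")
  }
  stopifnot(all(c("year", "sector", "meanlog", "sdlog", "n_groups")
                %in% names(cfg$income)))
  if (any(cfg$income$sdlog <= 0)) rlang::abort("income sdlog must be > 0")
  invisible(cfg)
}

#' @noRd
default_ppp_table <- function() {
  tibble::tibble(year = 2011:2013, rate = c(3.506, 3.524, 3.545))
}

#' @noRd
default_income_params <- function() {
  urban_mean <- c(`2011` = 21810, `2012` = 24565, `2013` = 26955,
                  `2014` = 28844)
  rural_mean <- c(`2011` = 6977, `2012` = 7917, `2013` = 8896,
                  `2014` = 9892)
  dplyr::bind_rows(
    tibble::tibble(year = 2011:2014, sector = "urban",
                   meanlog = unname(log(urban_mean) - 0.5^2 / 2),
                   sdlog = 0.5, n_groups = 5L),
    tibble::tibble(year = 2011:2014, sector = "rural",
                   meanlog = unname(log(rural_mean) - 0.55^2 / 2),
                   sdlog = 0.55, n_groups = 5L)
  )
}

#' True stocking probabilities and price levels per cell
#'
#' @param config A [simulation_config()].
#' @return Tibble with `drug_id, brand_status, region, year, p_stock,
#'   price_level`.
#' @export
truth_cells <- function(config) {
  grid <- tidyr::crossing(
    drug_id = config$drugs$drug_id,
    brand_status = c("generic", "innovator_brand"),
    region = region_levels(),
    year = config$years
  )
  ib <- grid$brand_status == "innovator_brand"
  yr <- as.character(grid$year)
  p <- config$base_availability[grid$drug_id] *
    ifelse(ib, config$brand_availability_factor, 1) *
    config$region_availability_factor[grid$region] *
    config$year_availability_factor[yr] +
    config$year_availability_offset[yr]
  grid$p_stock <- pmin(1, pmax(0, unname(p)))
  grid$price_level <- unname(
    config$base_price_level[grid$drug_id] *
      ifelse(ib, config$brand_price_factor, 1) *
      config$region_price_factor[grid$region] *
      config$year_price_factor[yr]
  )
  grid
}

#' Generate the reference-price environment
#'
#' Draws one USD reference price per drug (held constant over 2011-2013),
#' attaches the configured PPP table, and derives discount factors that
#' exactly invert the configured post-2013 inflation:
#' `DF(y) = (1 + inflation)^(2013 - y)`.
#'
#' @param config A [simulation_config()].
#' @return A [reference_basis()].
#' @export
generate_reference_basis <- function(config) {
  set.seed(config$seed + 1L)
  usd <- exp(stats::rnorm(nrow(config$drugs), log(0.05), 0.8))
  irp <- tidyr::crossing(drug_id = config$drugs$drug_id, year = 2011:2013)
  irp$irp_usd_per_unit <- usd[match(irp$drug_id, config$drugs$drug_id)]
  df <- tibble::tibble(year = config$years,
                       df = (1 + config$inflation)^(2013 - config$years))
  reference_basis(irp = irp, ppp = config$ppp, df = df,
                  discount_rate = config$inflation)
}

#' @noRd
true_irp_cny_by_year <- function(config, basis) {
  # nominal CNY reference level each year: same-year PPP-converted IRP up to
  # 2013, then inflated at the configured rate (which DF inverts exactly)
  base <- irp_cny_lookup(basis, config$drugs$drug_id,
                         sort(unique(pmin(config$years, 2013))))
  out <- tidyr::crossing(drug_id = config$drugs$drug_id,
                         year = config$years)
  i2013 <- irp_cny_lookup(basis, config$drugs$drug_id, 2013)
  i <- match(paste(out$drug_id, pmin(out$year, 2013)),
             paste(base$drug_id, base$year))
  out$irp_cny_nominal <- base$irp_cny[i] *
    (1 + config$inflation)^pmax(0, out$year - 2013)
  out$irp_cny_2013 <- i2013$irp_cny[match(out$drug_id, i2013$drug_id)]
  out
}

#' Generate a synthetic procurement panel with ground truth
#'
#' Draws the hospital roster, then for every hospital-drug-brand-year cell a
#' Bernoulli stocking indicator with the configured probability; stocked
#' cells emit a truncated-Poisson number of monthly purchase lines whose
#' unit prices are lognormal around `price_level` times the nominal CNY
#' reference price of the year. Pack strength and size vary per line (one
#' or two reference strengths per pack unit) so that the smallest-unit
#' normalization is exercised; strengths of 1 g or more are expressed in
#' grams.
#'
#' @param config A [simulation_config()].
#' @param basis Optional [reference_basis()]; generated from `config` when
#'   `NULL`.
#' @return A list: `panel` (hospital roster), `records` (procurement
#'   records), `basis`, and `truth` (a `ground_truth` list with per-cell
#'   stocking probabilities, true median prices and MPR levels, panel
#'   availability truth including pooled-brand and nationwide cells, and
#'   the income parameters).
#' @export
generate_panel <- function(config, basis = NULL) {
  if (is.null(basis)) basis <- generate_reference_basis(config)
  set.seed(config$seed)
  n <- config$n_secondary + config$n_tertiary
  panel <- tibble::tibble(
    hospital_id = sprintf("H%04d", seq_len(n)),
    tier = rep(c("secondary", "tertiary"),
               c(config$n_secondary, config$n_tertiary)),
    province = sample(config$provinces$province, n, replace = TRUE)
  )
  panel$region <- config$provinces$region[
    match(panel$province, config$provinces$province)]

  truth <- truth_cells(config)
  irp_y <- true_irp_cny_by_year(config, basis)
  truth <- dplyr::left_join(truth, irp_y, by = c("drug_id", "year"))
  truth$true_median_price_nominal <- truth$price_level *
    truth$irp_cny_nominal
  truth$mpr_true <- truth$price_level

  set.seed(config$seed + 2L)
  grid <- tidyr::crossing(
    panel[, c("hospital_id", "tier", "province", "region")],
    dplyr::distinct(truth, .data$drug_id, .data$brand_status, .data$year)
  )
  grid <- dplyr::left_join(
    grid,
    truth[, c("drug_id", "brand_status", "region", "year", "p_stock",
              "true_median_price_nominal")],
    by = c("drug_id", "brand_status", "region", "year")
  )
  stocked <- grid[stats::runif(nrow(grid)) < grid$p_stock, ]

  k <- stats::rpois(nrow(stocked), config$mean_monthly_records)
  while (any(k == 0)) {
    k[k == 0] <- stats::rpois(sum(k == 0), config$mean_monthly_records)
  }
  stocked$n_rec <- pmin(12L, k)
  recs <- tidyr::uncount(stocked, .data$n_rec)
  m <- nrow(recs)

  recs$month <- sample.int(12L, m, replace = TRUE)
  unit_price <- recs$true_median_price_nominal *
    exp(stats::rnorm(m, 0, config$price_dispersion))

  dd <- config$drugs[match(recs$drug_id, config$drugs$drug_id), ]
  mult <- sample(c(1L, 2L), m, replace = TRUE)
  pack_size <- ifelse(mult == 1L, 30L, 10L)
  strength <- dd$reference_strength_value * mult
  unit <- dd$reference_strength_unit
  to_g <- unit == "mg" & strength >= 1000
  strength[to_g] <- strength[to_g] / 1000
  unit[to_g] <- "g"

  records <- tibble::tibble(
    hospital_id = recs$hospital_id,
    tier = recs$tier,
    province = recs$province,
    region = recs$region,
    year = recs$year,
    month = recs$month,
    drug_id = recs$drug_id,
    brand_status = recs$brand_status,
    dosage_form = dd$dosage_form,
    strength_value = strength,
    strength_unit = unit,
    pack_size = pack_size,
    pack_price = unit_price * mult * pack_size,
    manufacturer = sprintf("MFR%02d", sample.int(40L, m, replace = TRUE))
  ) |>
    dplyr::arrange(.data$hospital_id, .data$year, .data$month,
                   .data$drug_id, .data$brand_status)

  gt <- structure(
    list(cells = truth,
         availability = truth_availability(truth, panel),
         income = config$income,
         config = config),
    class = "ground_truth"
  )
  list(panel = panel, records = records, basis = basis, truth = gt)
}

#' Panel-level availability ground truth
#'
#' Expands per-(region, brand) stocking probabilities to the full reporting
#' grid: pooled-brand cells combine the two independent Bernoulli draws,
#' `p_all = 1 - (1 - p_ib)(1 - p_generic)`; nationwide cells weight the
#' region probabilities by the realized panel composition. `expected_count`
#' and `var_count` are the Poisson-binomial moments of the number of
#' stocking hospitals, from which normal-approximation intervals for the
#' availability estimate follow.
#'
#' @param truth Output of [truth_cells()] (p_stock per region cell).
#' @param panel Hospital roster with a `region` column.
#' @return Tibble with `drug_id, brand_status, region, year, p_true,
#'   n_hospitals, expected_count, var_count`.
#' @export
truth_availability <- function(truth, panel) {
  n_region <- dplyr::count(panel, .data$region, name = "n_hospitals")
  wide <- truth |>
    dplyr::select("drug_id", "brand_status", "region", "year", "p_stock") |>
    tidyr::pivot_wider(names_from = "brand_status",
                       values_from = "p_stock")
  wide$all <- 1 - (1 - wide$innovator_brand) * (1 - wide$generic)
  long <- wide |>
    tidyr::pivot_longer(c("generic", "innovator_brand", "all"),
                        names_to = "brand_status", values_to = "p_true") |>
    dplyr::inner_join(n_region, by = "region")
  nat <- long |>
    dplyr::group_by(.data$drug_id, .data$brand_status, .data$year) |>
    dplyr::summarise(
      expected_count = sum(.data$n_hospitals * .data$p_true),
      var_count = sum(.data$n_hospitals * .data$p_true * (1 - .data$p_true)),
      n_hospitals = sum(.data$n_hospitals),
      .groups = "drop"
    ) |>
    dplyr::mutate(region = "nationwide",
                  p_true = .data$expected_count / .data$n_hospitals)
  reg <- long |>
    dplyr::mutate(expected_count = .data$n_hospitals * .data$p_true,
                  var_count = .data$n_hospitals * .data$p_true *
                    (1 - .data$p_true))
  dplyr::bind_rows(reg, nat) |>
    dplyr::select("drug_id", "brand_status", "region", "year", "p_true",
                  "n_hospitals", "expected_count", "var_count") |>
    dplyr::arrange(.data$drug_id, .data$brand_status, .data$region,
                   .data$year)
}

#' Generate grouped income tables with known parameters
#'
#' Builds yearbook-style quintile tables for each configured year and
#' sector. Group means are the exact analytic conditional means of the
#' lognormal between its quintile cut-points (no sampling), so fitting them
#' back should recover the parameters up to optimizer tolerance.
#'
#' @param config A [simulation_config()].
#' @return A list: `tables` (tibble `year, sector, group_index,
#'   population_share, mean_income`) and `truth` (tibble `year, sector,
#'   meanlog, sdlog`).
#' @export
generate_income_tables <- function(config) {
  rows <- purrr::pmap(config$income, function(year, sector, meanlog, sdlog,
                                              n_groups) {
    shares <- rep(1 / n_groups, n_groups)
    tibble::tibble(year = year, sector = sector,
                   group_index = seq_len(n_groups),
                   population_share = shares,
                   mean_income = lognormal_group_means(meanlog, sdlog,
                                                       shares))
  })
  list(tables = dplyr::bind_rows(rows),
       truth = config$income[, c("year", "sector", "meanlog", "sdlog")])
}

#' Generate a full scenario
#'
#' Convenience wrapper bundling [generate_panel()],
#' [generate_reference_basis()] and [generate_income_tables()].
#'
#' @param config A [simulation_config()].
#' @return A list: `config`, `panel`, `records`, `basis`, `truth`,
#'   `income_tables`, `income_truth`.
#' @export
generate_scenario <- function(config) {
  basis <- generate_reference_basis(config)
  pan <- generate_panel(config, basis)
  inc <- generate_income_tables(config)
  list(config = config, panel = pan$panel, records = pan$records,
       basis = basis, truth = pan$truth, income_tables = inc$tables,
       income_truth = inc$truth)
}

#' Write a generated scenario to CSV files
#'
#' Emits `records.csv`, `panel.csv`, `irp.csv`, `ppp.csv`, `df.csv` and
#' `income.csv` into `dir`. Identical configurations produce byte-identical
#' files.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_procurement_records(scenario$records, file.path(dir, "records.csv"))
  readr::write_csv(scenario$panel, file.path(dir, "panel.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$basis$irp, file.path(dir, "irp.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$basis$ppp, file.path(dir, "ppp.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$basis$df, file.path(dir, "df.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$income_tables, file.path(dir, "income.csv"),
                   progress = FALSE)
  invisible(dir)
}
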