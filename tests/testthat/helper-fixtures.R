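# Shared fixtures: everything is built in code at test time.

small_config <- function(seed = 101, ndrugs = 6, n_secondary = 60,
                         n_tertiary = 60, years = 2011:2014, ...) {
  simulation_config(seed = seed, n_secondary = n_secondary,
                    n_tertiary = n_tertiary,
                    drugs = default_drug_list()[seq_len(ndrugs), ],
                    years = years, ...)
}

# a single valid procurement record, fields overridable
make_record <- function(...) {
  defaults <- tibble::tibble(
    hospital_id = "H0001", tier = "tertiary", province = "Beijing",
    year = 2012L, month = 3L, drug_id = "amoxicillin",
    brand_status = "generic", dosage_form = "capsule",
    strength_value = 250, strength_unit = "mg", pack_size = 10L,
    pack_price = 10, manufacturer = "MFR01"
  )
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults
}

write_records_csv <- function(df, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame())) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# flat-effects config: no region/brand/year structure unless asked for
flat_config <- function(seed = 11, ndrugs = 4, level = 2, sigma = 0,
                        p = 0.6, years = 2011:2016, n_secondary = 20,
                        n_tertiary = 20, inflation = 0.03, ...) {
  d <- default_drug_list()[seq_len(ndrugs), ]
  simulation_config(
    seed = seed, n_secondary = n_secondary, n_tertiary = n_tertiary,
    drugs = d, years = years,
    base_availability = stats::setNames(rep(p, ndrugs), d$drug_id),
    brand_availability_factor = 1,
    region_availability_factor = c(eastern = 1, central = 1, western = 1),
    year_availability_factor = stats::setNames(rep(1, length(years)),
                                               as.character(years)),
    base_price_level = stats::setNames(rep(level, ndrugs), d$drug_id),
    brand_price_factor = 1,
    region_price_factor = c(eastern = 1, central = 1, western = 1),
    price_dispersion = sigma, inflation = inflation, ...
  )
}

# nominal (undeflated) stratified median unit prices, facility-first
nominal_price_cells <- function(unit_prices, drugs, years) {
  up <- unit_prices[unit_prices$drug_id %in% drugs &
                      unit_prices$year %in% years, ]
  up |>
    dplyr::group_by(drug_id, brand_status, year, hospital_id) |>
    dplyr::summarise(h = stats::median(price_per_unit),
                     .groups = "drop_last") |>
    dplyr::summarise(price_per_unit = stats::median(h), .groups = "drop")
}
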