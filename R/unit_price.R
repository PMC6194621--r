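#' Normalize purchase lines to comparable smallest-unit prices
#'
#' Different strengths and pack sizes of one chemical entity are made
#' commensurable by converting every purchase line to a price per *reference
#' unit*: the price per unit mass (or activity) of active moiety, rescaled to
#' the drug's declared reference strength. For a pack of `pack_size` units of
#' strength `s`,
#' \deqn{p_{unit} = \frac{pack\_price}{pack\_size} \times \frac{s_{ref}}{s}}
#' after expressing `s` in the reference-strength unit. Pooling all strengths
#' of a drug at the same per-mg price therefore yields identical unit prices.
#'
#' @param records Tibble of procurement records.
#' @param drugs Drug-definition table, see [default_drug_list()]; every
#'   `drug_id` in `records` must appear in it.
#' @return A tibble of unit prices with the hospital metadata carried along:
#'   `drug_id, brand_status, hospital_id, tier, province, region, year,
#'   month, price_per_unit` (CNY per reference-strength unit).
#' @examples
#' recs <- tibble::tibble(
#'   hospital_id = "H1", tier = "tertiary", province = "Beijing",
#'   region = "eastern", year = 2012L, month = 3L, drug_id = "amoxicillin",
#'   brand_status = "generic", dosage_form = "capsule",
#'   strength_value = 500, strength_unit = "mg", pack_size = 10L,
#'   pack_price = 10, manufacturer = "M1"
#' )
#' smallest_unit_price(recs, default_drug_list())$price_per_unit # 0.5
#' @export
smallest_unit_price <- function(records, drugs) {
  unknown <- setdiff(unique(records$drug_id), drugs$drug_id)
  if (length(unknown)) {
    rlang::abort(paste0("drug(s) without definition: ",
                        paste(unknown, collapse = ", ")))
  }
  j <- dplyr::left_join(
    records,
    drugs[, c("drug_id", "reference_strength_value",
              "reference_strength_unit")],
    by = "drug_id"
  )
  strength_ref <- convert_units(j$strength_value, j$strength_unit,
                                j$reference_strength_unit)
  opt <- function(col) {
    if (col %in% names(j)) j[[col]] else rep(NA_character_, nrow(j))
  }
  tibble::tibble(
    drug_id = j$drug_id,
    brand_status = j$brand_status,
    hospital_id = j$hospital_id,
    tier = opt("tier"),
    province = opt("province"),
    region = opt("region"),
    year = j$year,
    month = j$month,
    price_per_unit = j$pack_price / j$pack_size *
      j$reference_strength_value / strength_ref
  )
}
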