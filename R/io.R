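
.record_required <- c("hospital_id", "tier", "province", "year", "month",
                      "drug_id", "brand_status", "dosage_form",
                      "strength_value", "strength_unit", "pack_size",
                      "pack_price", "manufacturer")
.record_columns <- c("hospital_id", "tier", "province", "region", "year",
                     "month", "drug_id", "brand_status", "dosage_form",
                     "strength_value", "strength_unit", "pack_size",
                     "pack_price", "manufacturer")

#' Read and validate a procurement-record file
#'
#' Reads a delimited file of hospital-month purchase lines and validates
#' every row against the record invariants (positive price and strength,
#' integer pack size of at least one, month 1-12, known tier and brand
#' status). Malformed rows never abort the run: they are collected into a
#' rejects report with the offending line number and a reason, and parsing
#' continues. An unknown province, by contrast, is a hard error naming the
#' province, because it means the region map is wrong for the whole file.
#' The `region` column is optional on disk and is filled from the province
#' map; when present it must agree with the map.
#'
#' @param path Path to a UTF-8 CSV with a header row. Required columns:
#'   `hospital_id, tier, province, year, month, drug_id, brand_status,
#'   dosage_form, strength_value, strength_unit, pack_size, pack_price,
#'   manufacturer`; `region` optional.
#' @param region_map Province-to-region table, see [province_region_map()].
#' @param years Permitted survey years; rows outside are rejected. `NULL`
#'   accepts any year.
#' @return A list with `records` (typed tibble of valid rows) and `rejects`
#'   (tibble with `line`, `reason` and the raw field values).
#' @export
read_procurement_records <- function(path, region_map = province_region_map(),
                                     years = 2011:2016) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.record_required, names(raw))
  if (length(missing)) {
    rlang::abort(paste0("header lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  validate_procurement_rows(raw, region_map = region_map, years = years)
}

#' @noRd
validate_procurement_rows <- function(raw, region_map, years) {
  n <- nrow(raw)
  raw <- tibble::as_tibble(raw)
  has_region <- "region" %in% names(raw)

  num <- function(x) suppressWarnings(as.numeric(x))
  strength <- num(raw$strength_value)
  pack_size <- num(raw$pack_size)
  price <- num(raw$pack_price)
  year <- num(raw$year)
  month <- num(raw$month)

  # hard error: a province absent from the map poisons every stratification
  known_prov <- is.na(raw$province) | raw$province %in% region_map$province
  if (!all(known_prov)) {
    bad <- unique(raw$province[!known_prov])
    rlang::abort(paste0("unknown province: ", paste(bad, collapse = ", ")))
  }

  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  core <- raw[, .record_required]
  add(Reduce(`|`, lapply(core, function(x) is.na(x) | x == "")),
      "missing field")
  add(is.na(price) | price <= 0, "nonpositive price")
  add(is.na(pack_size) | pack_size < 1 | pack_size != round(pack_size),
      "invalid pack size")
  add(is.na(strength) | strength <= 0, "nonpositive strength")
  add(is.na(month) | month < 1 | month > 12 | month != round(month),
      "invalid month")
  if (!is.null(years)) add(is.na(year) | !(year %in% years),
                           "year out of range")
  add(!is.na(raw$tier) & !(raw$tier %in% c("secondary", "tertiary")),
      "unknown tier")
  add(!is.na(raw$brand_status) &
        !(raw$brand_status %in% c("innovator_brand", "generic")),
      "unknown brand status")

  mapped_region <- region_map$region[match(raw$province, region_map$province)]
  if (has_region) {
    stated <- !is.na(raw$region) & raw$region != ""
    add(stated & raw$region != mapped_region, "region/province mismatch")
  }

  bad <- !vapply(reasons, is.null, logical(1))
  rejects <- raw[bad, , drop = FALSE]
  rejects$line <- which(bad) + 1L # header is line 1
  rejects$reason <- vapply(reasons[bad], paste, "", collapse = "; ")
  rejects <- dplyr::relocate(rejects, "line", "reason")

  ok <- raw[!bad, , drop = FALSE]
  records <- tibble::tibble(
    hospital_id = ok$hospital_id,
    tier = ok$tier,
    province = ok$province,
    region = mapped_region[!bad],
    year = as.integer(num(ok$year)),
    month = as.integer(num(ok$month)),
    drug_id = ok$drug_id,
    brand_status = ok$brand_status,
    dosage_form = ok$dosage_form,
    strength_value = num(ok$strength_value),
    strength_unit = ok$strength_unit,
    pack_size = as.integer(num(ok$pack_size)),
    pack_price = num(ok$pack_price),
    manufacturer = ok$manufacturer
  )
  list(records = records, rejects = rejects)
}

#' Write procurement records (or a rejects report) to CSV
#'
#' @param records A tibble of records as returned by
#'   [read_procurement_records()] or [generate_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_procurement_records <- function(records, path) {
  readr::write_csv(records[, intersect(.record_columns, names(records))],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_procurement_records
#' @param rejects Rejects tibble from [read_procurement_records()].
#' @export
write_rejects <- function(rejects, path) {
  readr::write_csv(rejects, path, progress = FALSE)
  invisible(path)
}
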