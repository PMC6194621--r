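#' Default basket of 30 surveyed essential medicines
#'
#' A survey basket of 30 medicines spanning 10 therapeutic classes,
#' 18 treating acute disorders and 12 treating chronic disorders, 27 of them
#' on the national essential-medicines list. Reference strengths are the
#' smallest commonly procured unit of each chemical entity; `ddd_value` is
#' the WHO defined daily dose (amount of active moiety per treatment day),
#' used to cost one day of treatment. Four chronic-disease medicines
#' (hydrochlorothiazide, nifedipine, diclofenac, metformin — hypertension,
#' rheumatoid arthritis, diabetes) carry `affordability = TRUE` and feed the
#' catastrophic-drug-expenditure analysis.
#'
#' @return A tibble, one row per medicine, with columns `drug_id`,
#'   `therapeutic_class`, `disorder_type`, `on_neml`, `affordability`,
#'   `dosage_form`, `reference_strength_value`, `reference_strength_unit`,
#'   `ddd_value`, `ddd_unit`.
#' @examples
#' dplyr::count(default_drug_list(), disorder_type)
#' @export
default_drug_list <- function() {
  d <- tibble::tribble(
    ~drug_id,              ~therapeutic_class, ~disorder_type, ~on_neml, ~dosage_form, ~reference_strength_value, ~reference_strength_unit, ~ddd_value, ~ddd_unit,
    "amoxicillin",         "antibacterial",    "acute",   TRUE,  "capsule",  250,  "mg", 1500, "mg",
    "azithromycin",        "antibacterial",    "acute",   TRUE,  "tablet",   250,  "mg",  300, "mg",
    "ceftriaxone",         "antibacterial",    "acute",   TRUE,  "injection", 1000, "mg", 2000, "mg",
    "ciprofloxacin",       "antibacterial",    "acute",   TRUE,  "tablet",   250,  "mg", 1000, "mg",
    "cefalexin",           "antibacterial",    "acute",   TRUE,  "capsule",  250,  "mg", 2000, "mg",
    "doxycycline",         "antibacterial",    "acute",   TRUE,  "tablet",   100,  "mg",  100, "mg",
    "cefuroxime",          "antibacterial",    "acute",   FALSE, "tablet",   250,  "mg",  500, "mg",
    "paracetamol",         "analgesic",        "acute",   TRUE,  "tablet",   500,  "mg", 3000, "mg",
    "ibuprofen",           "analgesic",        "acute",   TRUE,  "tablet",   200,  "mg", 1200, "mg",
    "aspirin",             "analgesic",        "acute",   TRUE,  "tablet",   100,  "mg", 3000, "mg",
    "ranitidine",          "gastrointestinal", "acute",   TRUE,  "tablet",   150,  "mg",  300, "mg",
    "omeprazole",          "gastrointestinal", "acute",   TRUE,  "capsule",  20,   "mg",   20, "mg",
    "cimetidine",          "gastrointestinal", "acute",   TRUE,  "tablet",   200,  "mg",  800, "mg",
    "metoclopramide",      "gastrointestinal", "acute",   TRUE,  "tablet",   10,   "mg",   30, "mg",
    "salbutamol",          "respiratory",      "acute",   TRUE,  "inhaler",  0.1,  "mg",  0.8, "mg",
    "aminophylline",       "respiratory",      "acute",   FALSE, "tablet",   100,  "mg",  600, "mg",
    "furosemide",          "diuretic",         "acute",   TRUE,  "tablet",   20,   "mg",   40, "mg",
    "prednisolone",        "corticosteroid",   "acute",   TRUE,  "tablet",   5,    "mg",   10, "mg",
    "metformin",           "antidiabetic",     "chronic", TRUE,  "tablet",   250,  "mg", 2000, "mg",
    "glibenclamide",       "antidiabetic",     "chronic", TRUE,  "tablet",   2.5,  "mg",   10, "mg",
    "gliclazide",          "antidiabetic",     "chronic", FALSE, "tablet",   80,   "mg",  160, "mg",
    "insulin",             "antidiabetic",     "chronic", TRUE,  "injection", 100, "IU",   40, "IU",
    "nifedipine",          "antihypertensive", "chronic", TRUE,  "tablet",   10,   "mg",   30, "mg",
    "captopril",           "antihypertensive", "chronic", TRUE,  "tablet",   25,   "mg",   50, "mg",
    "enalapril",           "antihypertensive", "chronic", TRUE,  "tablet",   10,   "mg",   10, "mg",
    "amlodipine",          "antihypertensive", "chronic", TRUE,  "tablet",   5,    "mg",    5, "mg",
    "hydrochlorothiazide", "diuretic",         "chronic", TRUE,  "tablet",   25,   "mg",   25, "mg",
    "diclofenac",          "antirheumatic",    "chronic", TRUE,  "tablet",   25,   "mg",  100, "mg",
    "beclometasone",       "respiratory",      "chronic", TRUE,  "inhaler",  0.1,  "mg",  0.8, "mg",
    "simvastatin",         "lipid_lowering",   "chronic", TRUE,  "tablet",   20,   "mg",   30, "mg"
  )
  d$affordability <- d$drug_id %in%
    c("hydrochlorothiazide", "nifedipine", "diclofenac", "metformin")
  validate_drug_definitions(d)
  d
}

#' Read a drug-definition table from CSV
#'
#' @param path Path to a CSV with the columns of [default_drug_list()]
#'   (`affordability` optional, defaults to `FALSE`).
#' @return A validated tibble of drug definitions.
#' @export
read_drug_definitions <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"affordability" %in% names(d)) d$affordability <- FALSE
  validate_drug_definitions(d)
  tibble::as_tibble(d)
}

#' @noRd
validate_drug_definitions <- function(d) {
  needed <- c("drug_id", "therapeutic_class", "disorder_type", "on_neml",
              "reference_strength_value", "reference_strength_unit",
              "ddd_value", "ddd_unit")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    rlang::abort(paste0("drug table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(d$drug_id)) rlang::abort("duplicated drug_id")
  if (!all(d$disorder_type %in% c("acute", "chronic"))) {
    rlang::abort("disorder_type must be acute or chronic")
  }
  if (any(d$reference_strength_value <= 0)) {
    rlang::abort("reference_strength_value must be positive")
  }
  if (any(!is.na(d$ddd_value) & d$ddd_value <= 0)) {
    rlang::abort("ddd_value must be positive where defined")
  }
  # DDD must be expressible in the reference unit (errors if families differ)
  ok <- !is.na(d$ddd_value)
  if (any(ok)) convert_units(d$ddd_value[ok], d$ddd_unit[ok],
                             d$reference_strength_unit[ok])
  invisible(d)
}
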