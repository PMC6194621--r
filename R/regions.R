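#' Province-to-region lookup for mainland China
#'
#' The three-region grouping (eastern / central / western) follows the
#' standard Chinese statistical classification. Hainan, Qinghai and Tibet are
#' omitted because the hospital panel this package models does not cover
#' them, leaving 28 provinces, municipalities and autonomous regions.
#'
#' @param override Optional data frame with columns `province` and `region`
#'   whose rows replace or extend the packaged mapping (e.g. to add provinces
#'   or move one between regions).
#' @return A tibble with columns `province` and `region`
#'   (`"eastern"`, `"central"` or `"western"`).
#' @examples
#' province_region_map()
#' @export
province_region_map <- function(override = NULL) {
  map <- tibble::tribble(
    ~province,        ~region,
    "Beijing",        "eastern",
    "Tianjin",        "eastern",
    "Hebei",          "eastern",
    "Liaoning",       "eastern",
    "Shanghai",       "eastern",
    "Jiangsu",        "eastern",
    "Zhejiang",       "eastern",
    "Fujian",         "eastern",
    "Shandong",       "eastern",
    "Guangdong",      "eastern",
    "Shanxi",         "central",
    "Jilin",          "central",
    "Heilongjiang",   "central",
    "Anhui",          "central",
    "Jiangxi",        "central",
    "Henan",          "central",
    "Hubei",          "central",
    "Hunan",          "central",
    "Inner Mongolia", "western",
    "Guangxi",        "western",
    "Chongqing",      "western",
    "Sichuan",        "western",
    "Guizhou",        "western",
    "Yunnan",         "western",
    "Shaanxi",        "western",
    "Gansu",          "western",
    "Ningxia",        "western",
    "Xinjiang",       "western"
  )
  if (!is.null(override)) {
    override <- tibble::as_tibble(override)
    stopifnot(all(c("province", "region") %in% names(override)))
    if (!all(override$region %in% c("eastern", "central", "western"))) {
      rlang::abort("override regions must be eastern/central/western")
    }
    map <- dplyr::bind_rows(
      dplyr::anti_join(map, override, by = "province"),
      override
    )
  }
  map
}

#' @noRd
region_levels <- function() c("eastern", "central", "western")
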