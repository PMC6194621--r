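Package: medaccess
Title: Availability, Price and Affordability Indicators for Essential-Medicines
    Procurement Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the WHO/HAI-style access-to-medicines indicators from
    hospital drug-procurement panel data: percent availability of individual
    medicines across a facility panel, median price ratios against
    international reference prices (with purchasing-power-parity currency
    conversion and discount-factor deflation of post-reference-period prices),
    product-specific year-on-year delta statistics, rank-based group
    comparisons, and the incidence of catastrophic drug expenditure evaluated
    against per-capita income distributions reconstructed from grouped
    yearbook-style income tables. Includes a fully seeded synthetic
    procurement-panel generator with analytic ground truth so that every stage
    of the pipeline can be validated end to end without access to proprietary
    procurement databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
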