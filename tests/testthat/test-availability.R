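panel10 <- tibble::tibble(
  hospital_id = sprintf("H%02d", 1:10),
  tier = rep(c("secondary", "tertiary"), 5),
  region = rep(c("eastern", "central"), each = 5)
)

test_that("availability is the share of panel hospitals with any record", {
  recs <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_record(hospital_id = sprintf("H%02d", i), province = "Beijing")
  }))
  recs$region <- NULL
  recs$region <- ifelse(as.integer(substr(recs$hospital_id, 2, 3)) <= 5,
                        "eastern", "central")
  cell <- product_availability(recs, panel10, "amoxicillin", 2012)
  expect_equal(cell$availability_pct, 50)
  expect_equal(cell$n_hospitals, 10) # full roster, not stocking hospitals

  # a drug with no records at all is 0, with the same denominator
  none <- availability_table(recs, panel10, drugs = c("amoxicillin", "ghost"),
                             years = 2012, regions = "nationwide",
                             brands = "all")
  expect_equal(none$availability_pct[none$drug_id == "ghost"], 0)

  # duplicated records of one hospital do not double-count
  dup <- dplyr::bind_rows(recs, recs)
  expect_equal(product_availability(dup, panel10, "amoxicillin",
                                    2012)$availability_pct, 50)

  expect_error(
    product_availability(recs, panel10, "amoxicillin", 2012,
                         region = "western"),
    "empty stratum"
  )
})

test_that("basket medians use the mean-of-central-pair convention", {
  expect_equal(median_availability(c(40, 50, 60)), 50)
  expect_equal(median_availability(c(40, 60)), 50)
  expect_error(median_availability(numeric(0)), "empty")
  set.seed(1)
  x <- runif(30, 0, 100)
  s <- sort(x)
  expect_equal(median_availability(x), (s[15] + s[16]) / 2)
})

test_that("product-specific delta is the median of per-drug adjacent-year differences", {
  cells <- tibble::tibble(
    drug_id = rep(c("a", "b", "c"), 2),
    year = rep(c(2011, 2012), each = 3),
    availability_pct = c(10, 20, 30, 15.1, 23.6, 32.0)
  )
  d <- delta_product_specific(cells)
  expect_equal(d$delta, 3.6)
  expect_equal(d$n_drugs, 3)
  expect_equal(d$n_excluded, 0)

  same <- cells
  same$availability_pct[4:6] <- same$availability_pct[1:3]
  expect_equal(delta_product_specific(same)$delta, 0)

  # drugs absent in either year are excluded and counted
  gap <- cells[-4, ]
  d2 <- delta_product_specific(gap)
  expect_equal(d2$n_drugs, 2)
  expect_equal(d2$n_excluded, 1)
  expect_equal(d2$delta, median(c(3.6, 2.0)))

  disjoint <- tibble::tibble(drug_id = c("a", "b"), year = c(2011, 2012),
                             availability_pct = c(1, 2))
  expect_error(delta_product_specific(disjoint), "no drug present in both")
})

test_that("availability estimate lands in the 99% binomial interval of the truth", {
  set.seed(7)
  n <- 1159
  p <- 0.46
  panel <- tibble::tibble(hospital_id = sprintf("H%04d", 1:n),
                          tier = "tertiary", region = "eastern")
  stocked <- panel$hospital_id[runif(n) < p]
  recs <- dplyr::bind_rows(lapply(stocked, function(h) {
    make_record(hospital_id = h)
  }))
  recs$region <- "eastern"
  est <- product_availability(recs, panel, "amoxicillin",
                              2012)$availability_pct
  ci <- 100 * qbinom(c(0.005, 0.995), n, p) / n
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("availability is monotone in records and additive across regions", {
  cfg <- small_config(years = 2012:2013)
  sc <- generate_scenario(cfg)
  av_all <- availability_table(sc$records, sc$panel, regions = "nationwide",
                               brands = "all")
  half <- sc$records[seq_len(nrow(sc$records) %/% 2), ]
  av_half <- availability_table(half, sc$panel, regions = "nationwide",
                                brands = "all",
                                drugs = sort(unique(sc$records$drug_id)),
                                years = 2012:2013)
  j <- dplyr::inner_join(av_all, av_half, by = c("drug_id", "year"),
                         suffix = c("_all", "_half"))
  expect_true(all(j$availability_pct_all >= j$availability_pct_half))
  expect_true(all(av_all$availability_pct <= 100))

  # nationwide stocking counts are the sum of the regional stocking counts
  av_reg <- availability_table(sc$records, sc$panel,
                               regions = c("eastern", "central", "western"),
                               brands = "all")
  sums <- av_reg |>
    dplyr::group_by(drug_id, year) |>
    dplyr::summarise(n_stocking = sum(n_stocking), .groups = "drop")
  j2 <- dplyr::inner_join(av_all, sums, by = c("drug_id", "year"),
                          suffix = c("_nat", "_sum"))
  expect_equal(j2$n_stocking_nat, j2$n_stocking_sum)
})

test_that("95% binomial intervals cover the true stocking probability", {
  set.seed(123)
  n <- 150
  p <- 0.37
  hits <- vapply(1:200, function(i) {
    x <- rbinom(1, n, p)
    ci <- stats::binom.test(x, n)$conf.int
    p >= ci[1] && p <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("the stratified table equals composing the single-cell operation", {
  cfg <- small_config(years = 2012:2013, ndrugs = 4)
  sc <- generate_scenario(cfg)
  tab <- availability_table(sc$records, sc$panel)
  pick <- tab[sample(seq_len(nrow(tab)), 8), ]
  for (i in seq_len(nrow(pick))) {
    one <- product_availability(sc$records, sc$panel, pick$drug_id[i],
                                pick$year[i], region = pick$region[i],
                                brand_status = pick$brand_status[i])
    expect_equal(one$availability_pct, pick$availability_pct[i])
  }
  # summary table reports the basket median and its delta per stratum
  s <- summarize_availability(tab)
  one_stratum <- tab[tab$region == "nationwide" & tab$brand_status == "all" &
                       tab$year == 2012, ]
  expect_equal(
    s$median_value[s$region == "nationwide" & s$brand_status == "all" &
                     s$year == 2012],
    median(one_stratum$availability_pct)
  )
})
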