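basis_fix <- reference_basis(
  irp = tidyr::crossing(drug_id = c("amoxicillin", "ibuprofen"),
                        year = 2011:2013) |>
    dplyr::mutate(irp_usd_per_unit = ifelse(drug_id == "amoxicillin",
                                            0.10, 0.04)),
  ppp = tibble::tibble(year = 2011:2013, rate = c(3.5, 3.5, 3.5)),
  discount_rate = 0.03
)

test_that("reference prices convert to CNY by the PPP rate of their year", {
  expect_equal(irp_to_cny(0.10, 2011, basis_fix), 0.35)
  b1 <- reference_basis(basis_fix$irp,
                        ppp = tibble::tibble(year = 2011:2013, rate = 1))
  expect_equal(irp_to_cny(0.10, 2012, b1), 0.10)
  set.seed(5)
  for (i in 1:10) {
    u <- runif(1, 0.01, 2)
    y <- sample(2011:2013, 1)
    expect_equal(irp_to_cny(u, y, basis_fix),
                 u * basis_fix$ppp$rate[basis_fix$ppp$year == y])
  }
  expect_error(irp_to_cny(0.1, 2014, basis_fix), "2014")
})

test_that("deflation maps post-2013 prices onto the 2013 basis exactly once", {
  expect_equal(discount_factor(2013, basis_fix), 1)
  expect_equal(deflate_price(123.4, 2013, basis_fix), 123.4)
  expect_equal(deflate_price(55, 2011, basis_fix), 55) # pre-basis untouched
  expect_equal(deflate_price(1.03, 2014, basis_fix), 1.00)
  expect_equal(deflate_price(1.03^3, 2016, basis_fix), 1.00)
  expect_error(discount_factor(2017, basis_fix), "2017")

  up <- tibble::tibble(hospital_id = "H1", drug_id = "amoxicillin",
                       brand_status = "generic", region = "eastern",
                       year = 2015L, price_per_unit = 2.0)
  d1 <- deflate_prices(up, basis_fix)
  expect_equal(d1$price_2013, 2.0 / 1.03^2)
  expect_error(deflate_prices(d1, basis_fix), "already deflated")
})

test_that("stratum medians are facility-first (hospital-level) medians", {
  up <- tibble::tibble(
    hospital_id = c("A", "A", "A", "B"),
    price_per_unit = c(1, 1, 100, 3)
  )
  expect_equal(median_unit_price(up), 2.0) # hospital medians {1, 3}
  up2 <- tibble::tibble(hospital_id = c("A", "A", "A", "B"),
                        price_per_unit = c(10, 10, 10, 1))
  expect_equal(median_unit_price(up2), 5.5)
  expect_equal(median_unit_price(up2, aggregate = "transactions"), 10)
  expect_equal(median_unit_price(tibble::tibble(hospital_id = "A",
                                                price_per_unit = 2)), 2)
  expect_error(median_unit_price(up[0, ]), "empty stratum")
})

test_that("hospital-level medians estimate the true lognormal median", {
  set.seed(31)
  true_med <- 2
  up <- tibble::tibble(
    hospital_id = rep(sprintf("H%03d", 1:300), each = 5),
    price_per_unit = rlnorm(1500, log(true_med), 0.2)
  )
  expect_lt(abs(median_unit_price(up) / true_med - 1), 0.025)
})

test_that("the MPR is the worked definition and is scale invariant", {
  expect_equal(mpr(2 * 0.35, 0.35), 2.0) # twice the reference price
  expect_equal(mpr(0.35, 0.35), 1.0)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(1, 0.1, 10); r <- runif(1, 0.1, 10); c <- runif(1, 0.5, 100)
    expect_equal(mpr(c * p, c * r), mpr(p, r))
  }
  expect_error(mpr(-1, 2), "positive")
  expect_error(mpr(1, 0), "positive")
})

test_that("basket MPR medians, deltas and brand ratios follow the survey arithmetic", {
  expect_equal(median_mpr(c(4.2, 4.7, 5.4)), 4.7)
  cells <- tibble::tibble(drug_id = rep(c("a", "b", "c"), 2),
                          year = rep(2011:2012, each = 3),
                          mpr = c(1, 2, 3, 0.84, 1.90, 3.04))
  expect_equal(delta_mpr(cells)$delta, -0.10)
  expect_equal(ib_generic_ratio(5, 5), 1)
  expect_equal(ib_generic_ratio(29.51, 8.06, digits = 2), 3.66)
  expect_error(ib_generic_ratio(-1, 2), "positive")
})

test_that("a minority of 1000x outliers cannot move an interior basket median", {
  # 5 drugs with MPRs 1..5; corrupt 5 of 11 hospital prices of the middle one
  up <- tidyr::crossing(drug_id = letters[1:5],
                        hospital_id = sprintf("H%02d", 1:11)) |>
    dplyr::mutate(price_per_unit = match(drug_id, letters))
  med0 <- vapply(split(up, up$drug_id), median_unit_price, numeric(1))
  expect_equal(median(med0), 3)
  up$price_per_unit[up$drug_id == "c" & up$hospital_id <= "H05"] <- 3000
  med1 <- vapply(split(up, up$drug_id), median_unit_price, numeric(1))
  expect_equal(med1[["c"]], 3) # hospital-median rank unchanged
  expect_equal(median(med1), median(med0))
})

test_that("a drug priced exactly at the reference price has MPR 1 in every year", {
  cfg <- flat_config(level = 1, sigma = 0, inflation = 0.03)
  sc <- generate_scenario(cfg)
  up <- smallest_unit_price(sc$records, cfg$drugs) |>
    deflate_prices(sc$basis)
  mt <- mpr_table(up, sc$basis)
  expect_true(all(abs(mt$mpr - 1) < 1e-9))
  expect_setequal(unique(mt$year), 2011:2016)
})

test_that("mpr_table refuses undeflated prices and composes the stratified grid", {
  cfg <- flat_config(level = 2, sigma = 0.1, years = 2012:2013)
  sc <- generate_scenario(cfg)
  up <- smallest_unit_price(sc$records, cfg$drugs)
  expect_error(mpr_table(up, sc$basis), "deflate")
  upd <- deflate_prices(up, sc$basis)
  mt <- mpr_table(upd, sc$basis)
  # one cell recomputed independently: facility-first median over the stratum
  cell <- mt[mt$region == "eastern" & mt$brand_status == "generic" &
               mt$year == 2012 & mt$drug_id == "amoxicillin", ]
  sub <- upd[upd$region == "eastern" & upd$brand_status == "generic" &
               upd$year == 2012 & upd$drug_id == "amoxicillin", ]
  irp <- irp_to_cny(
    sc$basis$irp$irp_usd_per_unit[sc$basis$irp$drug_id == "amoxicillin" &
                                    sc$basis$irp$year == 2012][1],
    2012, sc$basis)
  expect_equal(cell$mpr, median_unit_price(sub, value = "price_2013") / irp)
})
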