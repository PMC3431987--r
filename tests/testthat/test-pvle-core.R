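test_that("working horizon has round(e) terms starting undiscounted at the start age", {
  ds <- const_dataset(e = 10)
  h <- working_horizon(ds, "male", 60)
  expect_identical(h$age, 60:69)
  expect_identical(h$offset, 0:9)
  expect_identical(h$weight, rep(1, 10))

  # e = 0.4 rounds to an empty horizon; ages past 75 use the age-75 entry
  ds0 <- const_dataset(e = 0.4)
  expect_identical(nrow(working_horizon(ds0, "female", 100)), 0L)
  expect_identical(pvle_total(ds0, "female", 100)$horizon_end_age, 99L)

  # e = 7.6 -> 8 terms (round half-to-even does not bite here)
  ds8 <- const_dataset(e = 7.6)
  h8 <- working_horizon(ds8, "male", 30)
  expect_identical(nrow(h8), 8L)
  expect_identical(h8$age, 30:37)

  expect_error(working_horizon(ds, "male", 17), "at least 18")
})

test_that("prorated horizon carries a fractional final-year weight", {
  ds <- const_dataset(e = 7.6, l = 1, W = 1, r = 0)
  h <- working_horizon(ds, "male", 30, pvle_control(horizon = "prorate"))
  expect_identical(nrow(h), 8L)
  expect_equal(h$weight, c(rep(1, 7), 0.6))
  expect_equal(pvle_paid(ds, "male", 30, pvle_control(horizon = "prorate")), 7.6)
})

test_that("pvle_paid matches hand-computed sums", {
  expect_equal(pvle_paid(const_dataset(e = 10, l = 1, W = 10000, r = 0),
                         "male", 40), 100000)
  expect_equal(pvle_paid(const_dataset(e = 10, l = 0, W = 10000, r = 0.05),
                         "female", 30), 0)
  expect_equal(pvle_paid(const_dataset(e = 3, l = 0.8, W = 50000, r = 0.05),
                         "male", 50),
               40000 * (1 + 1 / 1.05 + 1 / 1.05^2), tolerance = 1e-12)
})

test_that("ages 76 and older contribute no paid earnings", {
  ds <- const_dataset(e = 5, l = 1, W = 12000, r = 0)
  # start 74: horizon covers 74..78 but only 74 and 75 can earn
  expect_equal(pvle_paid(ds, "male", 74), 2 * 12000)
  # start above the input range: e taken at 75, zero earning ages
  expect_equal(pvle_paid(ds, "male", 80), 0)
})

test_that("pvle_household values non-participants' hours under both valuations", {
  ds <- const_dataset(e = 5, l = 1, hours = 2000, w_hour = 10, r = 0)
  expect_equal(pvle_household(ds, "male", 40), 0)

  ds0 <- const_dataset(e = 5, l = 0, hours = 2000, w_hour = 10, r = 0)
  expect_equal(pvle_household(ds0, "female", 40), 100000)
  expect_equal(pvle_household(ds0, "female", 40, valuation = "replacement_cost",
                              replacement_hourly_wage = 6), 60000)

  no_hh <- const_dataset(household = FALSE)
  expect_error(pvle_household(no_hh, "male", 40), "household data unavailable")
  expect_error(pvle_household(ds0, "male", 40, valuation = "replacement_cost"),
               "replacement_hourly_wage")
})

test_that("pvle_total is the exact sum of its components over one horizon", {
  ds <- random_fixture(13)
  for (age in c(18L, 26L, 49L, 70L)) {
    res <- pvle_total(ds, "female", age, include_household = TRUE)
    expect_identical(res$total, res$paid + res$household)
    expect_identical(res$paid, pvle_paid(ds, "female", age))
    expect_identical(res$household, pvle_household(ds, "female", age))
  }
  res0 <- pvle_total(ds, "male", 40)
  expect_identical(res0$household, 0)
  expect_identical(res0$total, res0$paid)
  ds_zero_hours <- const_dataset(e = 5, l = 0.5, hours = 0, r = 0)
  resz <- pvle_total(ds_zero_hours, "male", 40, include_household = TRUE)
  expect_identical(resz$total, resz$paid)
})

test_that("paid and household PVLE match the straight-loop oracle on random fixtures", {
  set.seed(101)
  for (i in 1:40) {
    ds <- random_fixture(i)
    sex <- sample(c("male", "female"), 1)
    age <- sample(18:90, 1)
    expect_equal(pvle_paid(ds, sex, age), oracle_pvle_paid(ds, sex, age),
                 tolerance = 1e-9)
    expect_equal(pvle_household(ds, sex, age),
                 oracle_pvle_household(ds, sex, age), tolerance = 1e-9)
  }
})

test_that("pvle_paid is non-increasing in the discount rate and monotone in inputs", {
  ds <- random_fixture(21)
  grid <- seq(0, 0.14, by = 0.02)
  for (sex in c("male", "female")) {
    vals <- sapply(grid, function(r) { d <- ds; d$discount_rate <- r
      pvle_paid(d, sex, 35) })
    expect_true(all(diff(vals) <= 1e-12))
  }
  # pointwise increase of a wage or participation value never lowers PVLE
  set.seed(5)
  base <- pvle_paid(ds, "male", 30)
  for (i in 1:20) {
    d <- ds
    a <- sample(18:75, 1)
    comp <- sample(c("wages_annual", "participation"), 1)
    idx <- match(a, d[[comp]]$ages)
    bump <- if (comp == "participation")
      min(1, d[[comp]]$values[idx, "male"] + runif(1, 0, 0.05))
    else d[[comp]]$values[idx, "male"] * (1 + runif(1, 0, 0.2))
    d[[comp]]$values[idx, "male"] <- bump
    expect_true(pvle_paid(d, "male", 30) >= base - 1e-12)
  }
})

test_that("age groupings partition ages with floor-of-midpoint representatives", {
  broad <- age_grouping("broad")
  expect_identical(broad$age_low, c(18L, 35L, 65L))
  expect_identical(broad$representative_age, c(26L, 49L, 70L))

  five <- age_grouping("five_year")
  expect_identical(five$age_low, c(18L, seq(20L, 75L, 5L)))
  expect_identical(five$age_high[1:2], c(19, 24))
  expect_identical(five$representative_age,
                   as.integer(floor((five$age_low +
                     ifelse(is.finite(five$age_high), five$age_high, 75)) / 2)))

  ten <- age_grouping("ten_year")
  for (g in list(broad, five, ten)) {
    covered <- integer(0)
    for (k in seq_len(nrow(g)))
      covered <- c(covered, g$age_low[k]:min(g$age_high[k], 110))
    expect_setequal(covered, 18:110)   # no gaps, and...
    expect_identical(anyDuplicated(covered), 0L)  # ...no overlaps
  }
  expect_identical(age_grouping("broad", pvle_control(open_bin_age = 72))$
                     representative_age[3], 72L)
})

test_that("group tables evaluate the representative age per bin for both sexes", {
  ds <- random_fixture(4)
  tab <- pvle_group_table(ds, "broad")
  expect_identical(nrow(tab), 6L)
  expect_setequal(tab$sex, c("male", "female"))
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$total[i],
                     pvle_total(ds, tab$sex[i], tab$representative_age[i])$total)
  five <- pvle_group_table(ds, "five_year")
  expect_identical(nrow(five), 2L * 13L)
})
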