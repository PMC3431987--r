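simple_schedule <- function(rows, cohort = 1000L, label = "test")
  mortality_schedule(rows, cohort_size = cohort, label = label)

test_that("mortality schedules enforce their domain contract", {
  ok <- data.frame(year_offset = 0L, age_at_death = 40L, sex = "male",
                   deaths = 10)
  expect_s3_class(simple_schedule(ok), "mortality_schedule")
  expect_error(simple_schedule(transform(ok, age_at_death = 17L)), "below 18")
  expect_error(simple_schedule(transform(ok, deaths = -1)), ">= 0")
  expect_error(simple_schedule(transform(ok, deaths = 2000)), "exceed cohort")
  expect_error(simple_schedule(transform(ok, sex = "other")), "unknown sex")
})

test_that("a single-cell schedule costs deaths times the per-death loss", {
  ds <- const_dataset(e = 10, l = 1, W = 10000, r = 0)
  ms <- simple_schedule(data.frame(year_offset = 0L, age_at_death = 40L,
                                   sex = "male", deaths = 10))
  res <- lifetime_productivity_cost(ms, ds, "human_capital")
  expect_equal(sum(res$cost), 10 * 100000)
  expect_equal(res$cost[res$sex == "male" & res$age_low == 35], 1000000)
  expect_equal(sum(res$deaths), 10)
  expect_identical(attr(res, "method"), "human_capital")
})

test_that("burden costs are linear in deaths and additive across disjoint schedules", {
  ds <- random_fixture(8)
  arms <- simulate_cohort_mortality(cohort_params(horizon_years = 20))
  ms <- arms$continuing_smokers
  res <- lifetime_productivity_cost(ms, ds, "human_capital")
  doubled <- ms
  doubled$deaths$deaths <- 2 * doubled$deaths$deaths
  res2 <- lifetime_productivity_cost(doubled, ds, "human_capital")
  expect_equal(res2$cost, 2 * res$cost)

  split1 <- ms; split1$deaths <- ms$deaths[1:20, ]
  split2 <- ms; split2$deaths <- ms$deaths[-(1:20), ]
  expect_equal(lifetime_productivity_cost(split1, ds, "human_capital")$cost +
                 lifetime_productivity_cost(split2, ds, "human_capital")$cost,
               res$cost)

  shuffled <- ms
  set.seed(3); shuffled$deaths <- shuffled$deaths[sample(nrow(shuffled$deaths)), ]
  rownames(shuffled$deaths) <- NULL
  expect_equal(lifetime_productivity_cost(shuffled, ds, "human_capital")$cost,
               res$cost)
})

test_that("two-term discounted sums match hand computation and the oracle", {
  ds <- const_dataset(e = 10, l = 1, W = 10000, r = 0.03)
  ms <- simple_schedule(data.frame(year_offset = c(0L, 10L),
                                   age_at_death = c(40L, 50L),
                                   sex = "female", deaths = c(5, 7)))
  res <- lifetime_productivity_cost(ms, ds, "human_capital")
  pv <- function(age) sum(10000 / 1.03^(0:9))
  expect_equal(sum(res$cost), 5 * pv(40) + 7 * pv(50) / 1.03^10,
               tolerance = 1e-12)
  expect_equal(sum(res$cost),
               oracle_burden_total(ms, ds, function(a, s)
                 oracle_pvle_paid(ds, s, a)), tolerance = 1e-12)
  # valuing deaths at time of death instead of baseline drops the (1+r)^-t
  undisc <- lifetime_productivity_cost(ms, ds, "human_capital",
                                       control = pvle_control(discount_deaths = FALSE))
  expect_equal(sum(undisc$cost), 5 * pv(40) + 7 * pv(50), tolerance = 1e-12)
})

test_that("setting all offsets to zero reduces to the undiscounted dot product", {
  ds <- random_fixture(16)
  arms <- simulate_cohort_mortality(cohort_params(horizon_years = 15))
  ms0 <- arms$quit_attempt
  ms0$deaths$year_offset <- 0L
  res <- lifetime_productivity_cost(ms0, ds, "human_capital")
  dot <- sum(mapply(function(a, s, d) d * oracle_pvle_paid(ds, s, a),
                    ms0$deaths$age_at_death, ms0$deaths$sex, ms0$deaths$deaths))
  expect_equal(sum(res$cost), dot, tolerance = 1e-9)
})

test_that("burden totals match the straight-loop oracle for both methods", {
  set.seed(55)
  for (i in 1:6) {
    ds <- random_fixture(300 + i)
    arms <- simulate_cohort_mortality(
      cohort_params(entry_age = sample(25:50, 1), horizon_years = 25))
    ms <- arms$continuing_smokers
    hc <- lifetime_productivity_cost(ms, ds, "human_capital")
    expect_equal(sum(hc$cost),
                 oracle_burden_total(ms, ds, function(a, s)
                   oracle_pvle_paid(ds, s, a)), tolerance = 1e-9)
    p <- friction_params(3, 4000, "SYN")
    fr <- lifetime_productivity_cost(ms, ds, "friction", params = p)
    expect_equal(sum(fr$cost),
                 oracle_burden_total(ms, ds, function(a, s)
                   oracle_friction_loss(ds, s, a, 3, 4000)), tolerance = 1e-9)
  }
})

test_that("cost_share follows the published share structure and stays in [0, 1]", {
  expect_identical(cost_share(75, 25), 0.75)
  expect_identical(cost_share(67, 33), 0.67)
  expect_identical(cost_share(0, 10), 0)
  expect_error(cost_share(0, 0), "undefined share")
  expect_error(cost_share(-1, 5), "non-negative")
  set.seed(2)
  p <- runif(100, 0, 1e7); d <- runif(100, 0, 1e7)
  s <- cost_share(p, d)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("productivity share is attached when direct costs are supplied", {
  ds <- const_dataset(e = 10, l = 1, W = 10000, r = 0)
  ms <- simple_schedule(data.frame(year_offset = 0L, age_at_death = 40L,
                                   sex = "male", deaths = 3))
  res <- lifetime_productivity_cost(ms, ds, "human_capital",
                                    direct_cost = 100000)
  expect_equal(attr(res, "productivity_share"), 300000 / 400000)
})

test_that("HC/friction ratios are >= 1 for working-age deaths and use an Inf sentinel", {
  ds <- random_fixture(12)
  p <- friction_params(3, 1000, "SYN")
  working <- simple_schedule(data.frame(
    year_offset = rep(0L, 4), age_at_death = c(30L, 40L, 50L, 60L),
    sex = rep(c("male", "female"), 2), deaths = rep(5, 4)))
  rat <- hc_friction_ratio(working, ds, p)
  busy <- rat[rat$deaths > 0, ]
  expect_true(all(busy$hc_friction_ratio >= 1))
  expect_true(all(rat$hc_friction_ratio[rat$deaths == 0] == Inf))

  # engineered identity: friction params making the loss equal PVLE at the
  # representative ages of a flat dataset give ratio 1 in occupied bins
  flat <- const_dataset(e = 1, l = 1, W = 12000, r = 0)
  ms1 <- simple_schedule(data.frame(year_offset = 0L, age_at_death = 49L,
                                    sex = "male", deaths = 10))
  rat1 <- hc_friction_ratio(ms1, flat, friction_params(12, 0))
  expect_equal(rat1$hc_friction_ratio[rat1$deaths > 0], 1)
})

test_that("the 65+ HC/friction ratio is far below working-age ratios on stylized fixtures", {
  ds <- random_fixture(18)
  p <- friction_params(3, 5000, "SYN")
  ms <- simple_schedule(data.frame(
    year_offset = rep(0L, 6),
    age_at_death = c(26L, 49L, 70L, 26L, 49L, 70L),
    sex = rep(c("male", "female"), each = 3), deaths = rep(5, 6)))
  rat <- hc_friction_ratio(ms, ds, p)
  for (s in c("male", "female")) {
    r65 <- rat$hc_friction_ratio[rat$sex == s & rat$age_low == 65]
    expect_true(all(rat$hc_friction_ratio[rat$sex == s & rat$age_low < 65] > r65))
  }
})
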