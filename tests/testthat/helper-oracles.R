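# Independent straight-loop reference implementations. These deliberately
# share no code with the package internals: horizons, lookups and
# discounting are all re-derived from first principles, one scalar term
# at a time.

oracle_lookup <- function(series, age, sex) {
  i <- which(series$ages == age)
  if (length(i) != 1L) stop("oracle: no unique value at age ", age)
  unname(series$values[i, sex])
}

oracle_horizon_length <- function(ds, sex, start_age) {
  e_age <- min(start_age, 75L)
  round(oracle_lookup(ds$life_expectancy, e_age, sex))
}

oracle_pvle_paid <- function(ds, sex, start_age) {
  E <- oracle_horizon_length(ds, sex, start_age)
  total <- 0
  if (E < 1) return(0)
  for (k in 0:(E - 1L)) {
    a <- start_age + k
    if (a >= 76) next  # participation defined 0 at 76+
    l <- oracle_lookup(ds$participation, a, sex)
    W <- oracle_lookup(ds$wages_annual, a, sex)
    total <- total + l * W / (1 + ds$discount_rate)^k
  }
  total
}

oracle_pvle_household <- function(ds, sex, start_age,
                                  valuation = "opportunity_cost",
                                  replacement_hourly_wage = NULL) {
  E <- oracle_horizon_length(ds, sex, start_age)
  total <- 0
  if (E < 1) return(0)
  for (k in 0:(E - 1L)) {
    a <- start_age + k
    l <- if (a >= 76) 0 else oracle_lookup(ds$participation, a, sex)
    h <- oracle_lookup(ds$household_hours, min(a, 75L), sex)
    v <- if (valuation == "opportunity_cost")
      oracle_lookup(ds$wages_hourly, min(a, 75L), sex)
    else replacement_hourly_wage
    total <- total + (1 - l) * h * v / (1 + ds$discount_rate)^k
  }
  total
}

oracle_friction_loss <- function(ds, sex, age, months, replacement_cost) {
  l <- if (age >= 76) 0 else oracle_lookup(ds$participation, age, sex)
  l * (oracle_lookup(ds$wages_annual, min(age, 75L), sex) * months / 12 +
         replacement_cost)
}

oracle_burden_total <- function(ms, ds, loss_fun) {
  total <- 0
  d <- ms$deaths
  for (i in seq_len(nrow(d)))
    total <- total + d$deaths[i] *
      loss_fun(d$age_at_death[i], d$sex[i]) /
      (1 + ds$discount_rate)^d$year_offset[i]
  total
}
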