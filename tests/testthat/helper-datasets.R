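# Constant-valued dataset builder: every schedule flat in age and sex,
# which makes hand arithmetic and closed forms exact.
const_dataset <- function(e = 10, l = 1, W = 10000, w_hour = 10,
                          hours = 2000, r = 0, currency = "TST",
                          household = TRUE) {
  n <- length(18:75)
  flat <- function(v, unit) age_sex_series(18:75, rep(v, n), rep(v, n), unit)
  country_dataset(
    country_code = "CONST", development_level = "advanced",
    discount_rate = r, currency = currency, price_year = 2009L,
    life_expectancy = flat(e, "years"),
    participation = flat(l, "proportion"),
    wages_annual = flat(W, "currency/year"),
    wages_hourly = flat(w_hour, "currency/hour"),
    household_hours = if (household) flat(hours, "hours/year"))
}

# Constant dataset whose remaining life expectancy varies by start age is
# not needed; to force a specific rounded horizon N at a given start age,
# set e = N exactly.

random_fixture <- function(seed) {
  level <- if (seed %% 2L == 0L) "advanced" else "emerging"
  generate_country_dataset(fixture_profile(level, seed = seed))
}
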