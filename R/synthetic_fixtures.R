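# Synthetic stand-ins so that every computation is testable fully
# offline: a country-dataset generator with controllable stylized
# structure, and a minimal three-state Markov cohort smoking-mortality
# simulator. The functional forms (logistic participation ramps, Gaussian
# wage hump, Gompertz baseline hazard) are package conventions for
# realistic-looking synthetic data, not estimates from any real source.

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Profile for the synthetic country-dataset generator
#'
#' Encodes the stylized regularities the generator reproduces: higher
#' life expectancy for females and for advanced economies, hump-shaped
#' participation and wages, higher male participation and wages, higher
#' female household hours.
#'
#' @param development_level `"advanced"` or `"emerging"`.
#' @param seed integer; identical seeds give bit-identical datasets.
#' @param wage_level overall annual wage scale (currency/year); default
#'   40000 for advanced, 12000 for emerging profiles.
#' @param male_female_wage_ratio male/female wage ratio, >= 1.
#' @param male_female_participation_gap absolute male-female gap in peak
#'   participation, in `[0, 1]`.
#' @param peak_age age at which wages peak.
#' @param discount_rate annual social discount rate; default 0.03 for
#'   advanced, 0.08 for emerging profiles (inside the published
#'   country ranges of roughly 2-9% and 4-14%).
#' @param currency currency label.
#' @return a list of class `fixture_profile`.
#' @export
fixture_profile <- function(development_level = c("advanced", "emerging"),
                            seed = 1L,
                            wage_level = NULL,
                            male_female_wage_ratio = 1.25,
                            male_female_participation_gap = 0.15,
                            peak_age = 48L,
                            discount_rate = NULL,
                            currency = "SYN") {
  development_level <- match.arg(development_level)
  if (is.null(wage_level))
    wage_level <- if (development_level == "advanced") 40000 else 12000
  if (is.null(discount_rate))
    discount_rate <- if (development_level == "advanced") 0.03 else 0.08
  stopifnot(male_female_wage_ratio >= 1,
            male_female_participation_gap >= 0,
            male_female_participation_gap <= 1,
            discount_rate >= 0, discount_rate < 1)
  structure(list(development_level = development_level,
                 seed = as.integer(seed), wage_level = wage_level,
                 male_female_wage_ratio = male_female_wage_ratio,
                 male_female_participation_gap = male_female_participation_gap,
                 peak_age = as.integer(peak_age),
                 discount_rate = discount_rate,
                 currency = as.character(currency)[1]),
            class = "fixture_profile")
}

#' Generate a synthetic country dataset
#'
#' Deterministic given the profile's seed, and guaranteed to pass
#' [validate_dataset()]. Life expectancy declines smoothly with age and
#' is higher for females and for advanced profiles; participation is
#' hump-shaped (ramp to the mid-20s, plateau, decline after the late
#' 50s, near zero past 65); wages follow a flat hump peaking at
#' `peak_age`; household hours are higher for females.
#'
#' @param profile a [fixture_profile()].
#' @return a valid [country_dataset()] covering ages 18-75.
#' @examples
#' ds <- generate_country_dataset(fixture_profile("emerging", seed = 7))
#' nrow(validate_dataset(ds))  # 0
#' @export
generate_country_dataset <- function(profile = fixture_profile()) {
  stopifnot(inherits(profile, "fixture_profile"))
  ages <- MODEL_AGES
  adv <- profile$development_level == "advanced"
  with_seed(profile$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    # remaining life expectancy: linear decline + small smooth wiggle,
    # kept well below the advanced-vs-emerging gap so orderings persist
    omega_m <- if (adv) 80 else 73
    le <- function(omega)
      pmax((omega - ages) * 0.95 + 1.5 + 0.2 * sin(ages / 7 + phase), 1.5)
    life_expectancy <- age_sex_series(ages, le(omega_m), le(omega_m + 4),
                                      unit = "years")
    # participation: logistic ramp-up by the mid 20s, logistic decline
    # centred at 60 so rates are near zero past 65, hard zero beyond 75
    shape <- stats::plogis((ages - 20) / 1.5) * (1 - stats::plogis((ages - 60) / 2.5))
    max_m <- 0.93
    max_f <- max(max_m - profile$male_female_participation_gap, 0)
    participation <- age_sex_series(ages, pmin(shape * max_m, 1),
                                    pmin(shape * max_f, 1),
                                    unit = "proportion")
    # wages: flat Gaussian hump (peak/edge ratio ~1.2) with a smooth
    # seeded multiplicative wiggle shared by both sexes
    hump <- 0.82 + 0.18 * exp(-((ages - profile$peak_age) / 15)^2)
    wiggle <- 1 + 0.02 * sin(ages / 5 + phase)
    w_f <- profile$wage_level * hump * wiggle
    w_m <- w_f * profile$male_female_wage_ratio
    wages_annual <- age_sex_series(ages, w_m, w_f, unit = "currency/year")
    hours_per_year <- 52 * 40
    wages_hourly <- age_sex_series(ages, w_m / hours_per_year,
                                   w_f / hours_per_year,
                                   unit = "currency/hour")
    # household hours: females carry most unpaid work; mild rise with age
    hh_f <- pmin(1500 + 6 * (ages - 18), 8760)
    hh_m <- pmin(800 + 3 * (ages - 18), 8760)
    household_hours <- age_sex_series(ages, hh_m, hh_f, unit = "hours/year")
    country_dataset(
      country_code = sprintf("SYN-%s-%d", toupper(substr(profile$development_level, 1, 3)),
                             profile$seed),
      development_level = profile$development_level,
      discount_rate = profile$discount_rate,
      currency = profile$currency,
      price_year = 2009L,
      life_expectancy = life_expectancy,
      participation = participation,
      wages_annual = wages_annual,
      wages_hourly = wages_hourly,
      household_hours = household_hours,
      provenance = list(generator = sprintf(
        "synthetic fixture (profile %s, seed %d); all values simulated",
        profile$development_level, profile$seed)))
  })
}

#' Parameters of the synthetic smoking-cessation cohort simulator
#'
#' A minimal three-state (current smoker / former smoker / dead)
#' expected-value Markov chain: a labelled synthetic stand-in producing
#' mortality schedules of the shape a published cessation cohort model
#' would emit, with no claim to real smoking epidemiology.
#'
#' @param entry_age cohort entry age (>= 18).
#' @param cohort_size cohort size (split evenly between sexes).
#' @param baseline_q `function(age, sex)` returning the annual baseline
#'   (never-smoker) death probability; the default is a Gompertz hazard
#'   with a lower female level.
#' @param smoker_rr relative mortality risk of current smokers, >= 1.
#' @param quit_success_prob probability that the single baseline quit
#'   attempt succeeds, in `[0, 1]`.
#' @param former_smoker_rr_decay_years years over which a former smoker's
#'   excess risk decays linearly back to 1.
#' @param horizon_years number of annual cycles simulated.
#' @param seed integer; only used by the optional stochastic mode.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(entry_age = 35L, cohort_size = 1000L,
                          baseline_q = NULL, smoker_rr = 2,
                          quit_success_prob = 0.1,
                          former_smoker_rr_decay_years = 10L,
                          horizon_years = 40L, seed = 1L) {
  if (is.null(baseline_q))
    baseline_q <- function(age, sex)
      pmin(9e-5 * exp(0.085 * age) * ifelse(sex == "female", 0.55, 1), 1)
  stopifnot(entry_age >= MIN_ADULT_AGE, cohort_size >= 1,
            smoker_rr >= 1, quit_success_prob >= 0, quit_success_prob <= 1,
            former_smoker_rr_decay_years >= 0, horizon_years >= 1)
  structure(list(entry_age = as.integer(entry_age),
                 cohort_size = as.integer(cohort_size),
                 baseline_q = baseline_q, smoker_rr = smoker_rr,
                 quit_success_prob = quit_success_prob,
                 former_smoker_rr_decay_years = as.integer(former_smoker_rr_decay_years),
                 horizon_years = as.integer(horizon_years),
                 seed = as.integer(seed)),
            class = "cohort_params")
}

run_cohort_arm <- function(p, quit_fraction, label, stochastic = FALSE) {
  n_sex <- p$cohort_size / 2
  rows <- list()
  occupancy_error <- 0
  for (s in SEXES) {
    smoker <- n_sex * (1 - quit_fraction)
    former <- n_sex * quit_fraction
    dead <- 0
    for (t in seq_len(p$horizon_years) - 1L) {
      age <- p$entry_age + t
      q0 <- p$baseline_q(age, s)
      decay <- if (p$former_smoker_rr_decay_years > 0)
        min(1, t / p$former_smoker_rr_decay_years) else 1
      rr_former <- p$smoker_rr - (p$smoker_rr - 1) * decay
      q_s <- min(1, q0 * p$smoker_rr)
      q_f <- min(1, q0 * rr_former)
      if (stochastic) {
        d_s <- stats::rbinom(1, round(smoker), q_s)
        d_f <- stats::rbinom(1, round(former), q_f)
      } else {
        d_s <- smoker * q_s
        d_f <- former * q_f
      }
      smoker <- smoker - d_s
      former <- former - d_f
      dead <- dead + d_s + d_f
      occupancy_error <- max(occupancy_error,
                             abs(smoker + former + dead - n_sex))
      rows[[length(rows) + 1L]] <- data.frame(
        year_offset = t, age_at_death = age, sex = s,
        deaths = d_s + d_f, stringsAsFactors = FALSE)
    }
  }
  ms <- mortality_schedule(do.call(rbind, rows), cohort_size = p$cohort_size,
                           label = label)
  attr(ms, "occupancy_error") <- occupancy_error
  ms
}

#' Simulate smoking-cohort mortality for a quit-attempt and a
#' continuing-smoker arm
#'
#' Expected-value propagation (deterministic; `stochastic = TRUE`
#' switches to seeded binomial sampling for property tests). In the
#' quit-attempt arm a fraction `quit_success_prob` becomes former
#' smokers at baseline; former-smoker excess mortality decays linearly
#' to the never-smoker level over `former_smoker_rr_decay_years`.
#' State occupancies conserve the cohort size exactly at every cycle.
#'
#' @param p a [cohort_params()].
#' @param stochastic draw integer deaths binomially instead of
#'   propagating expectations.
#' @return a list of two [mortality_schedule()]s, `quit_attempt` and
#'   `continuing_smokers`; each carries its maximum occupancy
#'   conservation error in the `"occupancy_error"` attribute.
#' @export
simulate_cohort_mortality <- function(p = cohort_params(), stochastic = FALSE) {
  stopifnot(inherits(p, "cohort_params"))
  runner <- function() list(
    quit_attempt = run_cohort_arm(p, p$quit_success_prob,
                                  "quit attempt (synthetic cohort)", stochastic),
    continuing_smokers = run_cohort_arm(p, 0,
                                        "continuing smokers (synthetic cohort)",
                                        stochastic))
  if (stochastic) with_seed(p$seed, runner()) else runner()
}
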