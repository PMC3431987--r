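#' Friction-cost method parameters
#'
#' The friction-cost method values a premature death only over the period
#' until the vacated job is refilled (the friction period, conventionally
#' three months) plus the employer's hiring-and-training cost for the
#' replacement worker.
#'
#' @param friction_period_months friction period length in months, in
#'   `(0, 24]`; default 3.
#' @param replacement_cost hiring/training cost per replaced worker, in
#'   the dataset's currency. Shipped defaults for case studies:
#'   [us_replacement_cost] (8819, 2009 USD) and
#'   [brazil_replacement_cost] (3659, 2009 Reals).
#' @param currency currency label; must match the dataset the parameters
#'   are used with.
#' @return a list of class `friction_params`.
#' @export
friction_params <- function(friction_period_months = 3,
                            replacement_cost = 0, currency = "") {
  if (!is.finite(friction_period_months) || friction_period_months <= 0 ||
      friction_period_months > 24)
    stop("friction_period_months must lie in (0, 24]")
  if (replacement_cost < 0) stop("replacement_cost must be >= 0")
  structure(list(friction_period_months = friction_period_months,
                 replacement_cost = replacement_cost,
                 currency = as.character(currency)[1]),
            class = "friction_params")
}

#' Published per-worker hiring-and-training replacement costs
#'
#' Printed constants for the two case-study countries (2009 price level);
#' the Brazilian figure is a published derived value and is not
#' recomputed here because its derivation inputs are not available.
#' @format single numbers.
#' @export
us_replacement_cost <- 8819

#' @rdname us_replacement_cost
#' @export
brazil_replacement_cost <- 3659

#' Friction-method productivity loss for one death
#'
#' Wage loss over the friction period plus the replacement cost, both
#' weighted by the labor force participation rate at the age of death (a
#' death outside the labor force vacates no job; set
#' `weight_replacement = FALSE` in [pvle_control()] to charge the
#' replacement cost unconditionally). No discounting is applied within
#' the short friction period. Participation is 0 from age 76 on, so
#' those deaths cost 0 under the default weighting.
#'
#' @param ds a [country_dataset()].
#' @param sex `"male"` or `"female"`.
#' @param age integer age at death (>= 18).
#' @param params a [friction_params()].
#' @param control a [pvle_control()].
#' @return a single currency amount.
#' @export
friction_loss_per_death <- function(ds, sex, age, params,
                                    control = pvle_control()) {
  stopifnot(inherits(ds, "country_dataset"), inherits(params, "friction_params"))
  check_sex(sex)
  age <- as.integer(age)
  if (age < MIN_ADULT_AGE) stop("age must be at least ", MIN_ADULT_AGE)
  if (nzchar(params$currency) && params$currency != ds$currency)
    stop("currency mismatch: friction params in '", params$currency,
         "', dataset in '", ds$currency, "'")
  l <- lookup_capped(ds$participation, age, sex)
  W <- lookup_capped(ds$wages_annual, age, sex) * control$parttime_factor
  wage_term <- l * W * params$friction_period_months / 12
  repl_term <- (if (control$weight_replacement) l else 1) *
    params$replacement_cost
  wage_term + repl_term
}

#' Friction-method loss table by sex and age group
#'
#' Per-bin friction loss evaluated at each bin's representative age, the
#' same convention as [pvle_group_table()].
#'
#' @inheritParams friction_loss_per_death
#' @param grouping `"broad"`, `"five_year"`, `"ten_year"`, or a bin
#'   data.frame from [age_grouping()].
#' @return a data.frame of class `pvle_table` with a `cost` column.
#' @export
friction_group_table <- function(ds, params, grouping = "broad",
                                 control = pvle_control()) {
  bins <- if (is.data.frame(grouping)) grouping else
    age_grouping(grouping, control)
  rows <- list()
  for (s in SEXES) {
    for (k in seq_len(nrow(bins))) {
      rows[[length(rows) + 1L]] <- data.frame(
        country = ds$country_code, sex = s,
        age_low = bins$age_low[k], age_high = bins$age_high[k],
        representative_age = bins$representative_age[k],
        cost = friction_loss_per_death(ds, s, bins$representative_age[k],
                                       params, control),
        currency = ds$currency, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pvle_table", "data.frame")
  out
}
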