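#' Convention switches for the PVLE computations
#'
#' The printed model leaves several conventions open; each is pinned to a
#' documented default here and can be changed per call.
#'
#' @param horizon `"round"` (default): the number of earning-year terms is
#'   the remaining life expectancy rounded half-to-even, so total earning
#'   years equal rounded remaining life expectancy; `"prorate"`: full years
#'   plus a final fractional-weight term.
#' @param open_bin_age representative age for an open-ended age bin;
#'   `NULL` (default) uses the floor of the midpoint between the bin's
#'   lower bound and 75, the last input age (so 70 for the broad 65+ bin).
#' @param household_beyond_75 include household work past age 75 (weight
#'   `1 - participation = 1`) with hours and hourly wage carried at their
#'   age-75 values; default `TRUE`.
#' @param weight_replacement multiply the employer replacement cost by the
#'   participation rate in the friction method (a death of a
#'   non-participant vacates no job); default `TRUE`.
#' @param discount_deaths discount losses from deaths at future year
#'   offsets back to baseline at the dataset's discount rate; default
#'   `TRUE` (lifetime costs as present values).
#' @param parttime_factor scalar in `(0, 1]` applied to annual wages; the
#'   default 1 is the full-time assumption, smaller values implement a
#'   proportionate part-time adjustment.
#' @return a list of class `pvle_control`.
#' @export
pvle_control <- function(horizon = c("round", "prorate"),
                         open_bin_age = NULL,
                         household_beyond_75 = TRUE,
                         weight_replacement = TRUE,
                         discount_deaths = TRUE,
                         parttime_factor = 1) {
  horizon <- match.arg(horizon)
  stopifnot(parttime_factor > 0, parttime_factor <= 1)
  structure(list(horizon = horizon, open_bin_age = open_bin_age,
                 household_beyond_75 = household_beyond_75,
                 weight_replacement = weight_replacement,
                 discount_deaths = discount_deaths,
                 parttime_factor = parttime_factor),
            class = "pvle_control")
}

MAX_INPUT_AGE <- 75L
MIN_ADULT_AGE <- 18L

#' Expected working/earning horizon for a starting age
#'
#' Remaining life expectancy at the starting age (ages above 75 use the
#' age-75 life-table entry) fixes the number of future years over which
#' earnings are summed. Under the default rounding convention, `E =
#' round(e)` (half-to-even) consecutive years at discount offsets
#' `0..E-1`, the first year undiscounted; under proration, `floor(e)` full
#' years plus one fractional-weight year.
#'
#' @param ds a [country_dataset()].
#' @param sex `"male"` or `"female"`.
#' @param start_age integer starting age (>= 18).
#' @param control a [pvle_control()].
#' @return data.frame with columns `age`, `offset`, `weight` (zero rows
#'   when rounded life expectancy is 0).
#' @export
working_horizon <- function(ds, sex, start_age,
                            control = pvle_control()) {
  stopifnot(inherits(ds, "country_dataset"))
  check_sex(sex)
  start_age <- as.integer(start_age)
  if (start_age < MIN_ADULT_AGE)
    stop("start_age must be at least ", MIN_ADULT_AGE)
  e <- series_value(ds$life_expectancy, min(start_age, MAX_INPUT_AGE), sex)
  if (control$horizon == "round") {
    n_terms <- as.integer(round(e))
    weight <- rep(1, n_terms)
  } else {
    full <- floor(e)
    frac <- e - full
    weight <- c(rep(1, full), if (frac > 0) frac)
    n_terms <- length(weight)
  }
  if (n_terms == 0L)
    return(data.frame(age = integer(0), offset = integer(0),
                      weight = numeric(0)))
  offs <- seq_len(n_terms) - 1L
  data.frame(age = start_age + offs, offset = offs, weight = weight)
}

# participation is defined as 0 from age 76 on; other schedules may be
# carried at their age-75 value (carry = TRUE) or zeroed beyond 75
lookup_capped <- function(series, ages, sex, carry = FALSE) {
  out <- numeric(length(ages))
  over <- ages > MAX_INPUT_AGE
  if (any(!over)) out[!over] <- series_value(series, ages[!over], sex)
  if (any(over) && carry)
    out[over] <- series_value(series, MAX_INPUT_AGE, sex)
  out
}

discount_factors <- function(rate, offsets) (1 + rate)^(-offsets)

#' Present value of lifetime paid-work earnings
#'
#' The human capital approach: expected future labor income foregone when
#' a person of the given sex dies at `start_age`,
#' \deqn{\sum_{k=0}^{E-1} l_{a+k} W_{a+k} (1+r)^{-k},}
#' the participation-weighted annual wage over the remaining-life-
#' expectancy horizon, discounted at the country's social rate.
#' Participation is 0 for ages 76 and older, so those years contribute
#' nothing.
#'
#' @inheritParams working_horizon
#' @return a single currency amount (0 for an empty horizon).
#' @export
pvle_paid <- function(ds, sex, start_age, control = pvle_control()) {
  h <- working_horizon(ds, sex, start_age, control)
  if (nrow(h) == 0L) return(0)
  l <- lookup_capped(ds$participation, h$age, sex)
  W <- lookup_capped(ds$wages_annual, h$age, sex) * control$parttime_factor
  sum(h$weight * l * W * discount_factors(ds$discount_rate, h$offset))
}

#' Present value of lifetime household (unpaid) work
#'
#' Values the unpaid household production of the fraction of each year of
#' life spent outside the labor force:
#' \deqn{\sum_{k=0}^{E-1} (1 - l_{a+k}) h_{a+k} v_{a+k} (1+r)^{-k},}
#' where `v` is the person's own market hourly wage under the
#' opportunity-cost valuation, or a flat hired-substitute wage (child
#' care workers, personal care aides, housekeepers) under the
#' replacement-cost valuation. Beyond age 75 participation is 0 (weight
#' 1) and hours/hourly wage are carried at their age-75 values by
#' default.
#'
#' @inheritParams working_horizon
#' @param valuation `"opportunity_cost"` or `"replacement_cost"`.
#' @param replacement_hourly_wage flat hourly wage of hired substitutes;
#'   required for the replacement-cost valuation.
#' @return a single currency amount.
#' @export
pvle_household <- function(ds, sex, start_age,
                           valuation = c("opportunity_cost", "replacement_cost"),
                           replacement_hourly_wage = NULL,
                           control = pvle_control()) {
  valuation <- match.arg(valuation)
  if (is.null(ds$household_hours))
    stop("household data unavailable for dataset '", ds$country_code, "'")
  if (valuation == "replacement_cost" && is.null(replacement_hourly_wage))
    stop("replacement_cost valuation requires replacement_hourly_wage")
  if (valuation == "opportunity_cost" && is.null(ds$wages_hourly))
    stop("opportunity_cost valuation requires hourly wages in the dataset")
  h <- working_horizon(ds, sex, start_age, control)
  if (nrow(h) == 0L) return(0)
  l <- lookup_capped(ds$participation, h$age, sex)
  hours <- lookup_capped(ds$household_hours, h$age, sex,
                         carry = control$household_beyond_75)
  v <- if (valuation == "opportunity_cost")
    lookup_capped(ds$wages_hourly, h$age, sex,
                  carry = control$household_beyond_75)
  else rep(replacement_hourly_wage, nrow(h))
  sum(h$weight * (1 - l) * hours * v *
        discount_factors(ds$discount_rate, h$offset))
}

#' Combined PVLE for paid and household work
#'
#' Paid and household components are computed over the same horizon and
#' discount rate; the total is their exact sum.
#'
#' @inheritParams pvle_household
#' @param include_household add the household-work component (requires
#'   household data in the dataset).
#' @return an object of class `pvle_result`: a list with elements `paid`,
#'   `household`, `total`, `horizon_end_age`, `discount_rate_used`,
#'   `currency`, `sex`, `start_age`.
#' @examples
#' ds <- generate_country_dataset(fixture_profile(seed = 1))
#' pvle_total(ds, "male", 40)
#' @export
pvle_total <- function(ds, sex, start_age, include_household = FALSE,
                       valuation = c("opportunity_cost", "replacement_cost"),
                       replacement_hourly_wage = NULL,
                       control = pvle_control()) {
  paid <- pvle_paid(ds, sex, start_age, control)
  household <- if (include_household)
    pvle_household(ds, sex, start_age, valuation,
                   replacement_hourly_wage, control)
  else 0
  h <- working_horizon(ds, sex, start_age, control)
  structure(
    list(paid = paid, household = household, total = paid + household,
         horizon_end_age = if (nrow(h)) max(h$age) else as.integer(start_age) - 1L,
         discount_rate_used = ds$discount_rate, currency = ds$currency,
         sex = sex, start_age = as.integer(start_age)),
    class = "pvle_result")
}

#' @export
print.pvle_result <- function(x, ...) {
  cat(sprintf("PVLE (%s, start age %d, horizon to age %d, r = %.3f):\n",
              x$sex, x$start_age, x$horizon_end_age, x$discount_rate_used))
  cat(sprintf("  paid      %14.2f %s\n", x$paid, x$currency))
  cat(sprintf("  household %14.2f %s\n", x$household, x$currency))
  cat(sprintf("  total     %14.2f %s\n", x$total, x$currency))
  invisible(x)
}

#' Age-grouping schemes
#'
#' Bins partitioning adult ages, each with an integer representative age
#' (floor of the bin midpoint; the open-ended last bin uses the midpoint
#' with 75, the last input age). The broad scheme is 18-34, 35-64, 65+.
#'
#' @param kind `"broad"`, `"five_year"` or `"ten_year"`.
#' @param control a [pvle_control()]; `open_bin_age` overrides the
#'   open-bin representative age.
#' @return data.frame with columns `age_low`, `age_high` (`Inf` for the
#'   open bin), `representative_age`.
#' @export
age_grouping <- function(kind = c("broad", "five_year", "ten_year"),
                         control = pvle_control()) {
  kind <- match.arg(kind)
  lows <- switch(kind,
                 broad = c(18L, 35L, 65L),
                 five_year = c(18L, seq(20L, 75L, by = 5L)),
                 ten_year = c(18L, seq(25L, 65L, by = 10L), 75L))
  highs <- c(lows[-1] - 1L, Inf)
  rep_age <- ifelse(is.finite(highs),
                    (lows + highs) %/% 2L,
                    (lows + MAX_INPUT_AGE) %/% 2L)
  if (!is.null(control$open_bin_age))
    rep_age[!is.finite(highs)] <- as.integer(control$open_bin_age)
  data.frame(age_low = lows, age_high = highs,
             representative_age = as.integer(rep_age))
}

bin_label <- function(age_low, age_high)
  ifelse(is.finite(age_high), paste0(age_low, "-", age_high),
         paste0(age_low, "+"))

assign_bins <- function(ages, bins) {
  idx <- rep(NA_integer_, length(ages))
  for (k in seq_len(nrow(bins)))
    idx[ages >= bins$age_low[k] &
          (ages <= bins$age_high[k] | !is.finite(bins$age_high[k]))] <- k
  idx
}

#' PVLE table by sex and age group
#'
#' Evaluates [pvle_total()] at each bin's representative age for both
#' sexes, the form in which country results are reported.
#'
#' @inheritParams pvle_total
#' @param grouping `"broad"`, `"five_year"`, `"ten_year"`, or a bin
#'   data.frame as returned by [age_grouping()].
#' @return a data.frame of class `pvle_table` with columns `country`,
#'   `sex`, `age_low`, `age_high`, `representative_age`, `paid`,
#'   `household`, `total`, `currency`.
#' @export
pvle_group_table <- function(ds, grouping = "broad", include_household = FALSE,
                             valuation = c("opportunity_cost", "replacement_cost"),
                             replacement_hourly_wage = NULL,
                             control = pvle_control()) {
  bins <- if (is.data.frame(grouping)) grouping else
    age_grouping(grouping, control)
  rows <- list()
  for (s in SEXES) {
    for (k in seq_len(nrow(bins))) {
      res <- pvle_total(ds, s, bins$representative_age[k], include_household,
                        valuation, replacement_hourly_wage, control)
      rows[[length(rows) + 1L]] <- data.frame(
        country = ds$country_code, sex = s,
        age_low = bins$age_low[k], age_high = bins$age_high[k],
        representative_age = bins$representative_age[k],
        paid = res$paid, household = res$household, total = res$total,
        currency = ds$currency, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pvle_table", "data.frame")
  out
}

#' @export
print.pvle_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$age_group <- bin_label(y$age_low, y$age_high)
  cols <- intersect(c("country", "sex", "age_group", "representative_age",
                      "paid", "household", "total", "cost", "deaths",
                      "currency"), names(y))
  for (col in intersect(c("paid", "household", "total", "cost"), names(y)))
    y[[col]] <- round(y[[col]])
  print.data.frame(y[cols], row.names = FALSE)
  invisible(x)
}

#' @export
plot.pvle_table <- function(x, what = "total", ...) {
  lab <- bin_label(x$age_low, x$age_high)
  m <- tapply(x[[what]], list(x$sex, lab), identity)
  m <- m[, unique(lab[order(x$age_low)]), drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = paste0(what, " (", x$currency[1], ")"),
                    xlab = "age group", ...)
  invisible(x)
}
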