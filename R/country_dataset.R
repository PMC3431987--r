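#' Assemble a per-country model input dataset
#'
#' Bundles every age/sex-stratified economic and demographic input the PVLE
#' model needs for one country, plus the scalar parameters. All series
#' should densely cover ages 18-75 after bracket expansion; the
#' constructor is deliberately lenient (so that flawed datasets can be
#' built and inspected) and [validate_dataset()] is the contract check.
#'
#' @param country_code short country label (free string).
#' @param development_level `"advanced"` or `"emerging"`.
#' @param discount_rate annual social discount rate in `[0, 1)`.
#' @param currency currency label (free string, e.g. `"2009 USD"`).
#' @param price_year integer price year all wages are expressed in.
#' @param life_expectancy [age_sex_series()] of remaining life expectancy
#'   (years), ages 18-75.
#' @param participation [age_sex_series()] of labor force participation
#'   (proportion in `[0, 1]`); participation at ages 76 and older is
#'   defined to be 0 and is not stored.
#' @param wages_annual [age_sex_series()] of annual wages (currency/year).
#' @param wages_hourly optional [age_sex_series()] of hourly wages
#'   (currency/hour); required for opportunity-cost household valuation.
#' @param household_hours optional [age_sex_series()] of annual unpaid
#'   household-work hours; many countries lack time-use data, in which
#'   case household-work operations signal an error.
#' @param provenance named list of free-text notes per component.
#' @return an object of class `country_dataset`.
#' @export
country_dataset <- function(country_code, development_level, discount_rate,
                            currency, price_year,
                            life_expectancy, participation, wages_annual,
                            wages_hourly = NULL, household_hours = NULL,
                            provenance = list()) {
  for (s in list(life_expectancy, participation, wages_annual))
    stopifnot(inherits(s, "age_sex_series"))
  if (!is.null(wages_hourly)) stopifnot(inherits(wages_hourly, "age_sex_series"))
  if (!is.null(household_hours)) stopifnot(inherits(household_hours, "age_sex_series"))
  structure(
    list(country_code = as.character(country_code)[1],
         development_level = as.character(development_level)[1],
         discount_rate = as.numeric(discount_rate)[1],
         currency = as.character(currency)[1],
         price_year = as.integer(price_year)[1],
         life_expectancy = life_expectancy,
         participation = participation,
         wages_annual = wages_annual,
         wages_hourly = wages_hourly,
         household_hours = household_hours,
         provenance = provenance),
    class = "country_dataset")
}

MODEL_AGES <- 18:75

#' Validate a country dataset against the model's input contract
#'
#' Report-based by default: every invariant violation is returned as one
#' row (component, age, sex, severity, message) and nothing is raised, so
#' real-world inputs with benign anomalies can still be inspected. With
#' `strict = TRUE` the first error-severity violation raises. A decreasing
#' sanity check on life expectancy is reported at `"warning"` severity
#' only, since real tables can violate it at bracket boundaries.
#'
#' @param ds a [country_dataset()].
#' @param strict raise an error on the first violation instead of
#'   reporting.
#' @return a data.frame of violations (zero rows when the dataset is
#'   valid), class `pvle_validation`.
#' @export
validate_dataset <- function(ds, strict = FALSE) {
  stopifnot(inherits(ds, "country_dataset"))
  v <- list()
  add <- function(component, age, sex, severity, message)
    v[[length(v) + 1L]] <<- data.frame(component = component,
                                       age = as.integer(age), sex = sex,
                                       severity = severity, message = message,
                                       stringsAsFactors = FALSE)

  if (!ds$development_level %in% c("advanced", "emerging"))
    add("development_level", NA, NA, "error",
        sprintf("unknown development level '%s'", ds$development_level))
  if (!is.finite(ds$discount_rate) || ds$discount_rate < 0 || ds$discount_rate >= 1)
    add("discount_rate", NA, NA, "error",
        sprintf("discount rate %g outside [0, 1)", ds$discount_rate))

  check_series <- function(series, component, required = TRUE) {
    if (is.null(series)) return(invisible())
    missing_ages <- setdiff(MODEL_AGES, series$ages)
    for (a in missing_ages)
      add(component, a, NA, "error",
          sprintf("age %d not covered by %s", a, component))
    for (s in SEXES) {
      bad <- series$ages[series$values[, s] < 0]
      for (a in bad)
        add(component, a, s, "error",
            sprintf("negative value at age %d (%s)", a, s))
    }
  }
  check_series(ds$life_expectancy, "life_expectancy")
  check_series(ds$participation, "participation")
  check_series(ds$wages_annual, "wages_annual")
  check_series(ds$wages_hourly, "wages_hourly")
  check_series(ds$household_hours, "household_hours")

  for (s in SEXES) {
    le <- ds$life_expectancy
    bad <- le$ages[le$values[, s] <= 0]
    for (a in bad)
      add("life_expectancy", a, s, "error",
          sprintf("remaining life expectancy must be > 0 at age %d (%s)", a, s))
    inc <- which(diff(le$values[, s]) > 0)
    for (k in inc)
      add("life_expectancy", le$ages[k + 1L], s, "warning",
          sprintf("remaining life expectancy increases from age %d to %d (%s)",
                  le$ages[k], le$ages[k + 1L], s))
    p <- ds$participation
    bad <- p$ages[p$values[, s] < 0 | p$values[, s] > 1]
    for (a in bad)
      add("participation", a, s, "error",
          sprintf("participation %g at age %d (%s) outside [0, 1]",
                  p$values[match(a, p$ages), s], a, s))
    if (!is.null(ds$household_hours)) {
      h <- ds$household_hours
      bad <- h$ages[h$values[, s] > 8760]
      for (a in bad)
        add("household_hours", a, s, "error",
            sprintf("household hours exceed 8760/year at age %d (%s)", a, s))
    }
  }

  report <- if (length(v)) do.call(rbind, v) else
    data.frame(component = character(0), age = integer(0), sex = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  report <- unique(report)
  if (strict && any(report$severity == "error"))
    stop("dataset validation failed: ",
         report$message[report$severity == "error"][1])
  class(report) <- c("pvle_validation", "data.frame")
  report
}

#' @export
print.pvle_validation <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat(sprintf("%d violations (%d errors, %d warnings)\n", nrow(x), n_err, n_warn))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.country_dataset <- function(x, ...) {
  cat(sprintf("<country_dataset> %s (%s), discount rate %.3f, %s (price year %d)\n",
              x$country_code, x$development_level, x$discount_rate,
              x$currency, x$price_year))
  comps <- c("life_expectancy", "participation", "wages_annual",
             "wages_hourly", "household_hours")
  present <- vapply(comps, function(k) !is.null(x[[k]]), logical(1))
  cat("  components:", paste(comps[present], collapse = ", "), "\n")
  if (any(!present)) cat("  absent:", paste(comps[!present], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.country_dataset <- function(object, ...) {
  print(object)
  rep <- validate_dataset(object)
  cat(sprintf("  validation: %d violations\n", nrow(rep)))
  for (s in SEXES) {
    cat(sprintf("  %s: e(18)=%.1fy, participation peak %.2f, mean annual wage %.0f\n",
                s, series_value(object$life_expectancy, 18L, s),
                max(object$participation$values[, s]),
                mean(object$wages_annual$values[, s])))
  }
  invisible(rep)
}

#' Rescale all wages in a dataset to a new price year
#'
#' Applies [adjust_cpi()] to the annual (and, when present, hourly) wage
#' schedules and records the new price year.
#'
#' @param ds a [country_dataset()].
#' @param cpi_source_year,cpi_target_year annual CPI index values.
#' @param new_price_year integer year to record.
#' @return the dataset with adjusted wages.
#' @export
adjust_dataset_cpi <- function(ds, cpi_source_year, cpi_target_year,
                               new_price_year) {
  stopifnot(inherits(ds, "country_dataset"))
  scale_series <- function(s) {
    if (is.null(s)) return(NULL)
    s$values <- adjust_cpi(s$values, cpi_source_year, cpi_target_year)
    s
  }
  ds$wages_annual <- scale_series(ds$wages_annual)
  ds$wages_hourly <- scale_series(ds$wages_hourly)
  ds$price_year <- as.integer(new_price_year)
  ds$provenance$cpi <- sprintf("wages CPI-adjusted %g -> %g (price year %d)",
                               cpi_source_year, cpi_target_year,
                               as.integer(new_price_year))
  ds
}
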