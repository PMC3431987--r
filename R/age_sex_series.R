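#' Dense per-age, per-sex numeric schedule
#'
#' The common currency of all model inputs: one non-negative value per
#' integer age and sex over a contiguous age range. Remaining life
#' expectancy, labor force participation, wages and household hours are all
#' stored in this form after bracket expansion.
#'
#' @param ages integer vector of consecutive ages (e.g. `18:75`).
#' @param male,female numeric vectors of values, one per age.
#' @param unit free-text unit label (`"years"`, `"proportion"`,
#'   `"currency/year"`, `"currency/hour"`, `"hours/year"`).
#' @return an object of class `age_sex_series`.
#' @examples
#' s <- age_sex_series(18:75, rep(1, 58), rep(0.9, 58), unit = "proportion")
#' series_value(s, 30, "female")
#' @export
age_sex_series <- function(ages, male, female, unit = "") {
  ages <- as.integer(ages)
  if (length(ages) == 0L) stop("age_sex_series needs at least one age")
  if (any(diff(ages) != 1L)) stop("ages must be consecutive integers")
  if (length(male) != length(ages) || length(female) != length(ages))
    stop("male/female value vectors must have one entry per age")
  male <- as.numeric(male)
  female <- as.numeric(female)
  if (any(!is.finite(male)) || any(!is.finite(female)))
    stop("all values must be finite")
  structure(
    list(ages = ages,
         values = cbind(male = male, female = female),
         unit = as.character(unit)[1]),
    class = "age_sex_series")
}

SEXES <- c("male", "female")

check_sex <- function(sex) {
  if (!all(sex %in% SEXES))
    stop("unknown sex label: ", paste(setdiff(sex, SEXES), collapse = ", "),
         " (expected 'male' or 'female')")
  sex
}

#' Look up values in an age/sex series
#'
#' @param x an [age_sex_series()].
#' @param age integer age(s); must lie inside the series' range.
#' @param sex `"male"` or `"female"` (scalar).
#' @return numeric vector of values, one per age.
#' @export
series_value <- function(x, age, sex) {
  stopifnot(inherits(x, "age_sex_series"))
  check_sex(sex)
  if (length(age) == 0L) return(numeric(0))
  idx <- match(as.integer(age), x$ages)
  if (anyNA(idx))
    stop("age(s) ", paste(age[is.na(idx)], collapse = ", "),
         " not covered by series (range ", min(x$ages), "-", max(x$ages), ")")
  unname(x$values[idx, sex])
}

#' @export
as.data.frame.age_sex_series <- function(x, ...) {
  data.frame(age = rep(x$ages, 2L),
             sex = rep(SEXES, each = length(x$ages)),
             value = c(x$values[, "male"], x$values[, "female"]),
             stringsAsFactors = FALSE)
}

#' @export
print.age_sex_series <- function(x, ...) {
  cat(sprintf("<age_sex_series> ages %d-%d, unit '%s'\n",
              min(x$ages), max(x$ages), x$unit))
  cat(sprintf("  male:   range [%g, %g]\n",
              min(x$values[, "male"]), max(x$values[, "male"])))
  cat(sprintf("  female: range [%g, %g]\n",
              min(x$values[, "female"]), max(x$values[, "female"])))
  invisible(x)
}

#' Expand bracketed input rows to a dense per-age series
#'
#' Source statistics are often reported for age brackets (e.g. 20-24
#' in 5-year groups); the model works on single ages. Each age in
#' `age_range` receives the value of its enclosing bracket; bracket bounds
#' are inclusive on both ends, so a 20-24 bracket covers ages 20, 21, 22,
#' 23 and 24. When rows exist for only one sex, the values are replicated
#' to the other sex (recorded in the `"replicated_sex"` attribute so
#' provenance can note it).
#'
#' @param brackets data.frame with columns `age_low`, `age_high`, `sex`,
#'   `value`; brackets must be non-overlapping per sex and jointly cover
#'   `age_range`.
#' @param age_range inclusive integer bounds, default `c(18, 75)`.
#' @param unit unit label for the resulting series.
#' @return an [age_sex_series()] covering `age_range` densely.
#' @export
expand_brackets <- function(brackets, age_range = c(18L, 75L), unit = "") {
  required <- c("age_low", "age_high", "sex", "value")
  if (!all(required %in% names(brackets)))
    stop("brackets must have columns ", paste(required, collapse = ", "))
  check_sex(brackets$sex)
  ages <- seq.int(age_range[1], age_range[2])
  sexes_present <- unique(brackets$sex)
  out <- matrix(NA_real_, nrow = length(ages), ncol = 2L,
                dimnames = list(NULL, SEXES))
  for (s in sexes_present) {
    b <- brackets[brackets$sex == s, , drop = FALSE]
    hit <- matrix(FALSE, nrow = length(ages), ncol = nrow(b))
    for (k in seq_len(nrow(b)))
      hit[, k] <- ages >= b$age_low[k] & ages <= b$age_high[k]
    n_hit <- rowSums(hit)
    if (any(n_hit > 1L))
      stop("ambiguous bracket: ages ", paste(ages[n_hit > 1L], collapse = ", "),
           " covered by more than one ", s, " bracket")
    if (any(n_hit == 0L))
      stop("missing bracket: ages ", paste(ages[n_hit == 0L], collapse = ", "),
           " not covered by any ", s, " bracket")
    out[, s] <- b$value[apply(hit, 1L, which)]
  }
  replicated <- setdiff(SEXES, sexes_present)
  for (s in replicated) out[, s] <- out[, sexes_present[1]]
  res <- age_sex_series(ages, out[, "male"], out[, "female"], unit = unit)
  if (length(replicated)) attr(res, "replicated_sex") <- replicated
  res
}

#' Consumer-price-index adjustment of a monetary amount
#'
#' Rescales `amount` from the price level of one year to another by the
#' ratio of annual CPI index values, the standard deflator used to put all
#' wages of a dataset on one price year.
#'
#' @param amount monetary amount(s).
#' @param cpi_source_year CPI index in the source year (> 0).
#' @param cpi_target_year CPI index in the target year (> 0).
#' @return `amount * cpi_target_year / cpi_source_year`.
#' @examples
#' adjust_cpi(250, 95.3, 104.1)
#' @export
adjust_cpi <- function(amount, cpi_source_year, cpi_target_year) {
  if (any(cpi_source_year <= 0) || any(cpi_target_year <= 0))
    stop("CPI indices must be positive")
  amount * cpi_target_year / cpi_source_year
}
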