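#' Mortality schedule of a closed cohort
#'
#' Expected deaths by year offset from baseline, age at death, and sex —
#' the form in which a Markov cohort disease model (e.g. a smoking
#' cessation model) reports its mortality output. Deaths are expected
#' (fractional) counts.
#'
#' @param deaths data.frame with columns `year_offset` (integer >= 0),
#'   `age_at_death` (integer >= 18), `sex`, `deaths` (non-negative real).
#' @param cohort_size positive integer the schedule refers to (e.g. 1000
#'   smokers).
#' @param label free-text description.
#' @return an object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(deaths, cohort_size, label = "") {
  required <- c("year_offset", "age_at_death", "sex", "deaths")
  if (!all(required %in% names(deaths)))
    stop("deaths must have columns ", paste(required, collapse = ", "))
  check_sex(deaths$sex)
  if (any(deaths$age_at_death < MIN_ADULT_AGE))
    stop("age_at_death below ", MIN_ADULT_AGE, " not supported")
  if (any(deaths$year_offset < 0)) stop("year_offset must be >= 0")
  if (any(deaths$deaths < 0)) stop("death counts must be >= 0")
  cohort_size <- as.integer(cohort_size)
  stopifnot(cohort_size > 0)
  for (s in SEXES) {
    tot <- sum(deaths$deaths[deaths$sex == s])
    if (tot > cohort_size + 1e-9)
      stop("total ", s, " deaths (", tot, ") exceed cohort size ", cohort_size)
  }
  deaths <- deaths[required]
  deaths$year_offset <- as.integer(deaths$year_offset)
  deaths$age_at_death <- as.integer(deaths$age_at_death)
  rownames(deaths) <- NULL
  structure(list(deaths = deaths, cohort_size = cohort_size,
                 label = as.character(label)[1]),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat(sprintf("<mortality_schedule> '%s': cohort %d, %d cells, %.2f expected deaths\n",
              x$label, x$cohort_size, nrow(x$deaths), sum(x$deaths$deaths)))
  invisible(x)
}

#' Read/write a mortality schedule as CSV
#'
#' Plain CSV with header `year_offset,age_at_death,sex,deaths`; cohort
#' size and label are carried in leading `#`-prefixed metadata lines.
#'
#' @param path CSV file path.
#' @param cohort_size override for files without metadata.
#' @param label override for files without metadata.
#' @return a [mortality_schedule()].
#' @export
read_mortality_schedule <- function(path, cohort_size = NULL, label = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else NULL
  }
  if (is.null(cohort_size)) cohort_size <- as.integer(get_meta("cohort_size"))
  if (is.null(label)) label <- get_meta("label")
  if (is.null(label)) label <- ""
  if (is.null(cohort_size) || is.na(cohort_size))
    stop("cohort_size neither supplied nor present in file metadata")
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  mortality_schedule(tab, cohort_size = cohort_size, label = label)
}

#' @rdname read_mortality_schedule
#' @param ms a [mortality_schedule()].
#' @export
write_mortality_schedule <- function(ms, path) {
  stopifnot(inherits(ms, "mortality_schedule"))
  lines <- c(sprintf("# cohort_size: %d", ms$cohort_size),
             sprintf("# label: %s", ms$label),
             "year_offset,age_at_death,sex,deaths",
             sprintf("%d,%d,%s,%s", ms$deaths$year_offset,
                     ms$deaths$age_at_death, ms$deaths$sex,
                     formatC(ms$deaths$deaths, digits = 17, format = "g")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Lifetime productivity cost of a mortality schedule
#'
#' Attaches a per-death loss — the full human-capital PVLE or the
#' friction-method loss — to every cell of a mortality schedule and
#' aggregates to sex/age-group bins:
#' \deqn{cost(sex, bin) = \sum_{(t,a,sex) \in bin} d_{t,a} \,
#'   loss(a, sex) \, (1+r)^{-t},}
#' where the loss is evaluated at the age at death and deaths at future
#' offsets are discounted to baseline by default (the result is a present
#' value at the schedule's baseline). Results are totals for the
#' schedule's cohort.
#'
#' @param ms a [mortality_schedule()].
#' @param ds a [country_dataset()].
#' @param method `"human_capital"` or `"friction"`.
#' @param params a [friction_params()]; required for the friction method.
#' @param grouping bin scheme, as in [pvle_group_table()].
#' @param direct_cost optional exogenous direct (medical) cost for the
#'   same cohort; enables the productivity-share computation.
#' @param include_household include household work in the human-capital
#'   loss (default `FALSE`).
#' @param control a [pvle_control()]; `discount_deaths = FALSE` values
#'   deaths at time of death without baseline discounting.
#' @param ... further arguments passed to [pvle_total()].
#' @return a data.frame of class `c("burden_result", "pvle_table")` with
#'   columns `country`, `sex`, `age_low`, `age_high`, `deaths`, `cost`,
#'   `currency`, and attributes `method`, `cohort_size`, `direct_cost`,
#'   `productivity_share`.
#' @export
lifetime_productivity_cost <- function(ms, ds,
                                       method = c("human_capital", "friction"),
                                       params = NULL, grouping = "broad",
                                       direct_cost = NULL,
                                       include_household = FALSE,
                                       control = pvle_control(), ...) {
  stopifnot(inherits(ms, "mortality_schedule"), inherits(ds, "country_dataset"))
  method <- match.arg(method)
  if (method == "friction" && !inherits(params, "friction_params"))
    stop("friction method requires friction_params")
  bins <- if (is.data.frame(grouping)) grouping else
    age_grouping(grouping, control)
  d <- ms$deaths
  loss_at <- function(age, sex) {
    if (method == "human_capital")
      pvle_total(ds, sex, age, include_household = include_household,
                 control = control, ...)$total
    else
      friction_loss_per_death(ds, sex, age, params, control)
  }
  key <- paste(d$age_at_death, d$sex)
  uk <- !duplicated(key)
  loss_map <- mapply(loss_at, d$age_at_death[uk], d$sex[uk])
  names(loss_map) <- key[uk]
  disc <- if (control$discount_deaths)
    discount_factors(ds$discount_rate, d$year_offset) else rep(1, nrow(d))
  cell_cost <- d$deaths * loss_map[key] * disc
  bin_idx <- assign_bins(d$age_at_death, bins)
  rows <- list()
  for (s in SEXES) {
    for (k in seq_len(nrow(bins))) {
      sel <- !is.na(bin_idx) & bin_idx == k & d$sex == s
      rows[[length(rows) + 1L]] <- data.frame(
        country = ds$country_code, sex = s,
        age_low = bins$age_low[k], age_high = bins$age_high[k],
        deaths = sum(d$deaths[sel]), cost = sum(cell_cost[sel]),
        currency = ds$currency, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("burden_result", "pvle_table", "data.frame")
  attr(out, "method") <- method
  attr(out, "cohort_size") <- ms$cohort_size
  if (!is.null(direct_cost)) {
    attr(out, "direct_cost") <- direct_cost
    attr(out, "productivity_share") <- cost_share(sum(out$cost), direct_cost)
  }
  out
}

#' Productivity share of total lifetime costs
#'
#' The fraction of total (productivity + direct medical) lifetime costs
#' attributable to lost productivity.
#'
#' @param productivity total productivity cost (>= 0).
#' @param direct total direct medical cost (>= 0).
#' @return `productivity / (productivity + direct)`, in `[0, 1]`.
#' @examples
#' cost_share(75, 25)  # 0.75
#' @export
cost_share <- function(productivity, direct) {
  if (any(productivity < 0) || any(direct < 0))
    stop("costs must be non-negative")
  if (any(productivity + direct == 0))
    stop("undefined share: productivity and direct costs are both zero")
  productivity / (productivity + direct)
}

#' Human-capital vs friction-cost ratio by sex and age group
#'
#' Element-wise ratio of the human-capital to the friction-method bin
#' costs for the same mortality schedule; bins with zero friction cost
#' report `Inf` as a sentinel.
#'
#' @inheritParams lifetime_productivity_cost
#' @return the human-capital [lifetime_productivity_cost()] table with an
#'   additional `friction_cost` and `hc_friction_ratio` column.
#' @export
hc_friction_ratio <- function(ms, ds, params, grouping = "broad",
                              control = pvle_control(), ...) {
  hc <- lifetime_productivity_cost(ms, ds, "human_capital",
                                   grouping = grouping, control = control, ...)
  fr <- lifetime_productivity_cost(ms, ds, "friction", params = params,
                                   grouping = grouping, control = control)
  hc$friction_cost <- fr$cost
  hc$hc_friction_ratio <- ifelse(fr$cost == 0, Inf, hc$cost / fr$cost)
  hc
}
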