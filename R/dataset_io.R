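# On-disk layout: either a directory containing dataset.json (scalars +
# provenance) and one CSV per component with header age_low,age_high,sex,value
# (bracketed rows allowed), or a single all-in-one JSON file with the tables
# embedded as row lists. All text UTF-8, comma-delimited, dot decimals.

COMPONENT_FILES <- c(life_expectancy = "life_expectancy.csv",
                     participation = "participation.csv",
                     wages_annual = "wages_annual.csv",
                     wages_hourly = "wages_hourly.csv",
                     household_hours = "household_hours.csv")

COMPONENT_UNITS <- c(life_expectancy = "years",
                     participation = "proportion",
                     wages_annual = "currency/year",
                     wages_hourly = "currency/hour",
                     household_hours = "hours/year")

read_bracket_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("age_low", "age_high", "sex", "value")
  if (!all(required %in% names(tab)))
    stop("malformed table ", path, ": expected columns ",
         paste(required, collapse = ","), ", found ",
         paste(names(tab), collapse = ","))
  bad <- which(!tab$sex %in% SEXES)
  if (length(bad))
    stop("malformed table ", path, ": unknown sex label '", tab$sex[bad[1]],
         "' at data row ", bad[1])
  if (!is.numeric(tab$value) || anyNA(tab$value))
    stop("malformed table ", path, ": non-numeric value field")
  tab
}

series_to_rows <- function(series) {
  df <- as.data.frame(series)
  data.frame(age_low = df$age, age_high = df$age, sex = df$sex,
             value = df$value, stringsAsFactors = FALSE)
}

write_bracket_csv <- function(series, path) {
  rows <- series_to_rows(series)
  # %.17g keeps doubles bit-exact through a text round trip
  lines <- c("age_low,age_high,sex,value",
             sprintf("%d,%d,%s,%s", rows$age_low, rows$age_high, rows$sex,
                     formatC(rows$value, digits = 17, format = "g")))
  writeLines(lines, path, useBytes = TRUE)
}

#' Read a country dataset from disk
#'
#' Accepts either a dataset directory (`dataset.json` plus component CSVs)
#' or a single all-in-one `.json` file as written by [write_dataset()].
#' Bracketed CSV rows are expanded to dense per-age series via
#' [expand_brackets()].
#'
#' @param path directory or `.json` file path.
#' @return a [country_dataset()].
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "dataset.json")
    if (!file.exists(meta_path)) stop("no dataset.json in ", path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    tables <- list()
    for (comp in names(COMPONENT_FILES)) {
      f <- file.path(path, COMPONENT_FILES[[comp]])
      if (file.exists(f)) tables[[comp]] <- read_bracket_csv(f)
    }
  } else if (file.exists(path)) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    tables <- meta$tables
    meta$tables <- NULL
    for (comp in names(tables)) {
      tab <- as.data.frame(tables[[comp]], stringsAsFactors = FALSE)
      check_sex(tab$sex)
      tables[[comp]] <- tab
    }
  } else stop("dataset path not found: ", path)

  for (k in c("country_code", "development_level", "discount_rate",
              "currency", "price_year"))
    if (is.null(meta[[k]])) stop("dataset metadata missing key '", k, "'")
  for (comp in c("life_expectancy", "participation", "wages_annual"))
    if (is.null(tables[[comp]])) stop("dataset missing required table ", comp)

  series <- lapply(names(tables), function(comp)
    expand_brackets(tables[[comp]], age_range = range(MODEL_AGES),
                    unit = COMPONENT_UNITS[[comp]]))
  names(series) <- names(tables)
  prov <- meta$provenance
  if (is.null(prov)) prov <- list() else prov <- as.list(prov)
  for (comp in names(series)) {
    rep_sex <- attr(series[[comp]], "replicated_sex")
    if (!is.null(rep_sex)) {
      prov[[comp]] <- paste(c(prov[[comp]],
        sprintf("values replicated to %s (single-sex source)",
                paste(rep_sex, collapse = "/"))), collapse = "; ")
      attr(series[[comp]], "replicated_sex") <- NULL
    }
  }
  country_dataset(country_code = meta$country_code,
                  development_level = meta$development_level,
                  discount_rate = meta$discount_rate,
                  currency = meta$currency,
                  price_year = meta$price_year,
                  life_expectancy = series$life_expectancy,
                  participation = series$participation,
                  wages_annual = series$wages_annual,
                  wages_hourly = series$wages_hourly,
                  household_hours = series$household_hours,
                  provenance = prov)
}

#' Write a country dataset to disk
#'
#' A `.json` destination produces a single all-in-one file; any other path
#' is treated as a dataset directory (created if needed). The write/read
#' round trip is lossless: all numeric values survive bit-identically.
#'
#' @param ds a [country_dataset()].
#' @param path destination directory or `.json` file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "country_dataset"))
  meta <- list(country_code = ds$country_code,
               development_level = ds$development_level,
               discount_rate = ds$discount_rate,
               currency = ds$currency,
               price_year = ds$price_year,
               provenance = ds$provenance)
  if (grepl("\\.json$", path)) {
    meta$tables <- list()
    for (comp in names(COMPONENT_FILES))
      if (!is.null(ds[[comp]]))
        meta$tables[[comp]] <- series_to_rows(ds[[comp]])
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(meta, file.path(path, "dataset.json"),
                         auto_unbox = TRUE, digits = I(17))
    for (comp in names(COMPONENT_FILES))
      if (!is.null(ds[[comp]]))
        write_bracket_csv(ds[[comp]], file.path(path, COMPONENT_FILES[[comp]]))
  }
  invisible(path)
}
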