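#' Daily environmental series
#'
#' Construct a date-indexed table of daily environmental measurements
#' (meteorology and air-pollutant concentrations). The object is a plain
#' `data.frame` whose first column is `date` (class `Date`, strictly
#' increasing, no duplicates) with one numeric column per variable, plus a
#' `units` attribute mapping variable names to unit strings. Missing calendar
#' days between the first and last date are tolerated but recorded in the
#' `gaps` attribute so downstream lag alignment can refuse to pair
#' non-adjacent days silently.
#'
#' @param dates vector coercible to `Date`; strictly increasing.
#' @param values numeric matrix or data.frame, one row per date, one column
#'   per variable; column names mandatory and unique.
#' @param units optional named character vector, `variable -> unit string`
#'   (e.g. `"ug/m3"`, `"hPa"`, `"degC"`).
#' @return an object of class `env_series` (a `data.frame`).
#' @seealso [visit_series()], [read_env_csv()], [lag_align()]
#' @export
env_series <- function(dates, values, units = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates in 'dates'")
  values <- as.data.frame(values)
  if (is.null(colnames(values)) || any(!nzchar(colnames(values))))
    stop("all variable columns must be named")
  if (anyDuplicated(colnames(values)))
    stop("duplicated variable names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (nrow(values) != length(dates))
    stop("'values' must have one row per date")
  if (length(dates) > 1 && any(diff(dates) <= 0)) {
    bad <- which(diff(dates) <= 0)[1]
    stop("dates must be strictly increasing (violation at row ", bad + 1,
         ", date ", format(dates[bad + 1]), ")")
  }
  for (v in colnames(values)) {
    if (!is.numeric(values[[v]])) stop("variable '", v, "' is not numeric")
  }
  out <- data.frame(date = dates, values, check.names = FALSE)
  attr(out, "units") <- .normalize_units(units, colnames(values))
  attr(out, "gaps") <- .date_gaps(dates)
  class(out) <- c("env_series", "data.frame")
  out
}

#' Daily visit-count series
#'
#' Date-indexed non-negative integer daily counts of clinical visits
#' (the outcome of the causal analysis).
#'
#' @param dates vector coercible to `Date`; strictly increasing.
#' @param counts non-negative integers, one per date.
#' @return an object of class `visit_series` (a `data.frame` with columns
#'   `date` and `visits`).
#' @export
visit_series <- function(dates, counts) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates in 'dates'")
  if (length(counts) != length(dates))
    stop("'counts' must have one entry per date")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(dates) > 1 && any(diff(dates) <= 0))
    stop("dates must be strictly increasing")
  out <- data.frame(date = dates, visits = as.integer(round(counts)))
  attr(out, "gaps") <- .date_gaps(dates)
  class(out) <- c("visit_series", "data.frame")
  out
}

.normalize_units <- function(units, vars) {
  out <- setNames(rep(NA_character_, length(vars)), vars)
  if (!is.null(units)) {
    unknown <- setdiff(names(units), vars)
    if (length(unknown))
      stop("units given for unknown variables: ", paste(unknown, collapse = ", "))
    out[names(units)] <- units
  }
  out
}

.date_gaps <- function(dates) {
  if (length(dates) < 2) return(as.Date(character()))
  full <- seq(min(dates), max(dates), by = "day")
  full[!full %in% dates]
}

#' @export
print.env_series <- function(x, ...) {
  vars <- setdiff(colnames(x), "date")
  cat("Daily environmental series: ", nrow(x), " days (",
      format(min(x$date)), " to ", format(max(x$date)), "), ",
      length(vars), " variables\n", sep = "")
  cat("  variables:", paste(vars, collapse = ", "), "\n")
  ng <- length(attr(x, "gaps"))
  if (ng) cat("  calendar gaps:", ng, "missing day(s)\n")
  NextMethod()
}

#' @export
print.visit_series <- function(x, ...) {
  cat("Daily visit counts: ", nrow(x), " days (",
      format(min(x$date)), " to ", format(max(x$date)), "), total ",
      sum(x$visits), " visits\n", sep = "")
  NextMethod()
}

# ---- CSV input/output -------------------------------------------------------

.parse_date_column <- function(raw, path) {
  d <- as.Date(raw, format = "%Y-%m-%d")
  # as.Date() silently "rolls over" some impossible dates on certain platforms;
  # round-trip formatting catches e.g. 2014-02-30.
  bad <- is.na(d) | format(d, "%Y-%m-%d") != raw
  if (any(bad)) {
    line <- which(bad)[1] + 1L  # header is line 1
    stop("unparseable date '", raw[which(bad)[1]], "' in ", path,
         " at line ", line)
  }
  if (anyDuplicated(d)) {
    stop("duplicated date ", format(d[duplicated(d)][1]), " in ", path)
  }
  d
}

#' Read and write environmental series CSV
#'
#' The on-disk format is a CSV with a mandatory header, a first column
#' `date` in ISO 8601 (`YYYY-MM-DD`) and one numeric column per variable.
#' A write followed by a read reproduces the values to full precision.
#' Missing cells are reported with their row and column.
#'
#' @param path file path.
#' @param units optional named character vector of units (see [env_series()]).
#' @return `read_env_csv` returns an [env_series()]; `write_env_csv` returns
#'   `path` invisibly.
#' @export
read_env_csv <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"date" %in% colnames(df)) stop("no 'date' column in ", path)
  d <- .parse_date_column(df$date, path)
  vars <- setdiff(colnames(df), "date")
  vals <- lapply(vars, function(v) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    miss <- which(is.na(x) & nzchar(trimws(df[[v]])) |
                    !nzchar(trimws(df[[v]])))
    if (length(miss))
      stop("missing or non-numeric cell(s) in ", path, ": column '", v,
           "', row(s) ", paste(utils::head(miss, 5), collapse = ", "))
    x
  })
  names(vals) <- vars
  o <- order(d)
  env_series(d[o], as.data.frame(vals, check.names = FALSE)[o, , drop = FALSE],
             units = units)
}

#' @rdname read_env_csv
#' @param env an [env_series()] to write.
#' @export
write_env_csv <- function(env, path) {
  stopifnot(inherits(env, "env_series"))
  out <- as.data.frame(env)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write daily visit-count CSV
#'
#' CSV with header and columns `date` (ISO 8601) and `visits`
#' (non-negative integers).
#'
#' @param path file path.
#' @return `read_visits_csv` returns a [visit_series()]; `write_visits_csv`
#'   returns `path` invisibly.
#' @export
read_visits_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("date", "visits") %in% colnames(df)))
    stop("visit CSV needs 'date' and 'visits' columns: ", path)
  d <- .parse_date_column(df$date, path)
  v <- suppressWarnings(as.numeric(df$visits))
  if (anyNA(v)) stop("non-numeric visit count in ", path,
                     " at line ", which(is.na(v))[1] + 1L)
  o <- order(d)
  visit_series(d[o], v[o])
}

#' @rdname read_visits_csv
#' @param visits a [visit_series()] to write.
#' @export
write_visits_csv <- function(visits, path) {
  stopifnot(inherits(visits, "visit_series"))
  out <- data.frame(date = format(visits$date, "%Y-%m-%d"),
                    visits = visits$visits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write patient-level visit records CSV
#'
#' Columns: `patient_id`, `visit_date` (ISO 8601), `age` (years),
#' `sex` (`M`/`F`).
#'
#' @param path file path.
#' @return a `data.frame` of patient records.
#' @export
read_patients_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("patient_id", "visit_date", "age", "sex")
  if (!all(need %in% colnames(df)))
    stop("patient CSV needs columns ", paste(need, collapse = ", "))
  df$visit_date <- .parse_patient_dates(df$visit_date, path)
  df$age <- as.numeric(df$age)
  if (any(df$age < 0 | df$age >= 18, na.rm = TRUE))
    stop("pediatric ages must satisfy 0 <= age < 18")
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  df
}

.parse_patient_dates <- function(raw, path) {
  d <- as.Date(raw, format = "%Y-%m-%d")
  bad <- is.na(d) | format(d, "%Y-%m-%d") != raw
  if (any(bad))
    stop("unparseable visit_date '", raw[which(bad)[1]], "' in ", path,
         " at line ", which(bad)[1] + 1L)
  d
}

#' @rdname read_patients_csv
#' @param records patient records `data.frame`.
#' @export
write_patients_csv <- function(records, path) {
  out <- records
  out$visit_date <- format(as.Date(out$visit_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
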