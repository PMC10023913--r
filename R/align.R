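#' Collapse repeat visits into index visits
#'
#' Reduces patient-level visit records to index visits: per patient,
#' same-day duplicates collapse to a single record, and any visit falling
#' within `followup_window_days` calendar days after a retained index visit
#' is treated as a scheduled follow-up and dropped. The first visit beyond
#' the window opens a new index visit. This mirrors the usual exclusion of
#' scheduled follow-ups within a week of an acute asthma visit when counting
#' attacks rather than encounters.
#'
#' @param records `data.frame` with at least `patient_id` and `visit_date`
#'   (coercible to `Date`); extra columns are carried through.
#' @param followup_window_days non-negative integer; `0` removes only
#'   same-day duplicates.
#' @return the retained records, in chronological order (ties broken by
#'   patient id). Idempotent: applying twice equals applying once.
#' @export
deduplicate_visits <- function(records, followup_window_days = 7) {
  if (length(followup_window_days) != 1 || is.na(followup_window_days) ||
      followup_window_days < 0)
    stop("'followup_window_days' must be a single non-negative integer")
  stopifnot(is.data.frame(records),
            all(c("patient_id", "visit_date") %in% colnames(records)))
  records$visit_date <- as.Date(records$visit_date)
  if (nrow(records) == 0) return(records)

  ord <- order(records$patient_id, records$visit_date)
  rec <- records[ord, , drop = FALSE]
  keep <- logical(nrow(rec))
  ids <- rec$patient_id
  dts <- as.integer(rec$visit_date)
  index_day <- NA_integer_
  cur_id <- NULL
  for (i in seq_len(nrow(rec))) {
    if (is.null(cur_id) || ids[i] != cur_id) {
      cur_id <- ids[i]
      index_day <- dts[i]
      keep[i] <- TRUE
    } else if (dts[i] == index_day) {
      keep[i] <- FALSE            # same-day duplicate of the index
    } else if (dts[i] - index_day <= followup_window_days) {
      keep[i] <- FALSE            # follow-up within the window
    } else {
      index_day <- dts[i]         # window elapsed: new index visit
      keep[i] <- TRUE
    }
  }
  out <- rec[keep, , drop = FALSE]
  out <- out[order(out$visit_date, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate patient records to daily counts
#'
#' @param records patient-level records with a `visit_date` column.
#' @param full_range if `TRUE` (default), days with zero visits between the
#'   first and last visit date are included with count 0.
#' @return a [visit_series()].
#' @export
count_visits <- function(records, full_range = TRUE) {
  d <- as.Date(records$visit_date)
  if (!length(d)) stop("no records")
  tab <- table(d)
  dates <- as.Date(names(tab))
  counts <- as.integer(tab)
  if (full_range) {
    full <- seq(min(dates), max(dates), by = "day")
    counts <- counts[match(full, dates)]
    counts[is.na(counts)] <- 0L
    dates <- full
  }
  visit_series(dates, counts)
}

#' Align lagged exposures with daily outcomes
#'
#' Pairs the outcome on day `t` with the exposures measured `lag` calendar
#' days earlier (day `t - lag`): exposure precedes outcome, the standard
#' epidemiologic lag convention. Rows for which either side is missing are
#' dropped, so on contiguous overlapping series of length `m` the aligned
#' table has `m - lag` rows. Because pairing is by calendar date, gaps in
#' either series never cause non-adjacent days to be paired.
#'
#' @param env an [env_series()].
#' @param visits a [visit_series()].
#' @param lag non-negative integer number of days the exposure precedes the
#'   outcome.
#' @return a `data.frame` with columns `date` (the outcome day `t`),
#'   `visits` (`Y_t`), and one column per environmental variable holding
#'   `X_{t-lag}`.
#' @export
lag_align <- function(env, visits, lag) {
  stopifnot(inherits(env, "env_series"), inherits(visits, "visit_series"))
  if (length(lag) != 1 || is.na(lag) || lag < 0 || lag != round(lag))
    stop("'lag' must be a single non-negative integer")
  lag <- as.integer(lag)
  exposure_day <- visits$date - lag
  idx <- match(exposure_day, env$date)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no overlap between exposure and outcome series at lag ",
                     lag)
  vars <- setdiff(colnames(env), "date")
  out <- data.frame(date = visits$date[ok], visits = visits$visits[ok])
  for (v in vars) out[[v]] <- env[[v]][idx[ok]]
  out
}

#' Interquartile range
#'
#' Q3 - Q1 with quartiles by linear interpolation between order statistics
#' (type 7, the `stats::quantile()` default). Used as the exposure-scaling
#' base: a per-unit effect times the variable's IQR gives the per-IQR
#' causal effect.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return a single non-negative number.
#' @export
compute_iqr <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 4)
    stop("compute_iqr needs at least 4 finite values, got ", length(x))
  unname(stats::quantile(x, 0.75, type = 7) - stats::quantile(x, 0.25, type = 7))
}
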