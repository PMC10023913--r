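.season_of_month <- function(month) {
  # Mar-May spring, Jun-Aug summer, Sep-Nov autumn, Dec-Feb winter
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}

.pct <- function(count, total) round(100 * count / total, 2)

#' Assemble a cohort summary from count margins
#'
#' Builds the standard descriptive table -- total, sex, season and yearly
#' counts each with two-decimal percents, plus age quartiles -- from
#' already-tabulated margins. Used by [summarize_cohort()] and directly
#' applicable to published count tables. Season and yearly counts must
#' each sum to the total (conservation is enforced).
#'
#' @param year_counts named integer vector, names are years.
#' @param sex_counts optional named vector with names `male`, `female`.
#' @param season_counts optional named vector with names `spring`,
#'   `summer`, `autumn`, `winter`.
#' @param age_quartiles optional numeric triple `(Q1, median, Q3)` in
#'   years.
#' @return an object of class `cohort_summary`.
#' @export
cohort_summary_from_counts <- function(year_counts, sex_counts = NULL,
                                       season_counts = NULL,
                                       age_quartiles = NULL) {
  total <- sum(year_counts)
  if (total <= 0) stop("empty cohort")
  check_sum <- function(x, what) {
    if (!is.null(x) && sum(x) != total)
      stop(what, " counts sum to ", sum(x), ", expected total ", total)
  }
  check_sum(season_counts, "season")
  check_sum(sex_counts, "sex")
  structure(list(
    total = total,
    year_counts = year_counts,
    year_percent = .pct(year_counts, total),
    sex_counts = sex_counts,
    sex_percent = if (!is.null(sex_counts)) .pct(sex_counts, total),
    season_counts = season_counts,
    season_percent = if (!is.null(season_counts))
      .pct(season_counts, total),
    age_quartiles = age_quartiles),
    class = "cohort_summary")
}

#' Summarize a visit cohort
#'
#' Descriptive statistics of patient-level visit records: total visits,
#' sex split, seasonal distribution (March-May spring, June-August summer,
#' September-November autumn, December-February winter), yearly counts,
#' and the age median and quartiles (linear-interpolation quantiles, the
#' same convention as [compute_iqr()]). Percents are printed to two
#' decimals.
#'
#' @param records `data.frame` with `visit_date` (coercible to `Date`) and
#'   optionally `sex` (`M`/`F`) and `age` columns.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || !nrow(records))
    stop("'records' must be a nonempty data.frame")
  if (!"visit_date" %in% colnames(records))
    stop("'records' needs a 'visit_date' column")
  d <- as.Date(records$visit_date)
  year <- format(d, "%Y")
  season <- .season_of_month(as.integer(format(d, "%m")))
  count_by <- function(f, levels) {
    tab <- table(factor(f, levels = levels))
    stats::setNames(as.integer(tab), names(tab))
  }
  year_counts <- count_by(year, sort(unique(year)))
  season_counts <- count_by(season, c("spring", "summer", "autumn",
                                      "winter"))
  sex_counts <- if ("sex" %in% colnames(records)) {
    s <- count_by(records$sex, c("M", "F"))
    stats::setNames(s, c("male", "female"))
  }
  age_quartiles <- if ("age" %in% colnames(records)) {
    unname(stats::quantile(records$age, c(0.25, 0.5, 0.75), type = 7))
  }
  cohort_summary_from_counts(year_counts, sex_counts, season_counts,
                             age_quartiles)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: ", format(x$total, big.mark = ","),
      " visits\n", sep = "")
  if (!is.null(x$age_quartiles))
    cat(sprintf("  Age median [Q1, Q3]: %.0f [%.0f, %.0f] years\n",
                x$age_quartiles[2], x$age_quartiles[1], x$age_quartiles[3]))
  block <- function(title, counts, pct) {
    if (is.null(counts)) return(invisible())
    cat("  ", title, ":\n", sep = "")
    for (nm in names(counts))
      cat(sprintf("    %-8s %9s (%.2f%%)\n", nm,
                  format(counts[[nm]], big.mark = ","), pct[[nm]]))
  }
  block("Sex", x$sex_counts, x$sex_percent)
  block("Season", x$season_counts, x$season_percent)
  block("Year", x$year_counts, x$year_percent)
  invisible(x)
}
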