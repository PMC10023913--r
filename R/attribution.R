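#' Annual visits attributable to a pollutant concentration change
#'
#' Converts a multi-year decline in a pollutant's concentration into the
#' implied annual change in visits:
#' `((conc_start - conc_end) / iqr) * causal_effect_iqr * days_per_year`.
#' The concentration change is expressed in IQR units, multiplied by the
#' per-IQR causal effect (visits/day per IQR), and accumulated over a
#' year. The sign of the concentration change is preserved, so an
#' increasing concentration yields a negative "reduction". When both a
#' concentration unit and an IQR unit tag are supplied they must agree --
#' mixing, say, mg/m3 concentrations with a ug/m3 IQR is refused rather
#' than silently scaled.
#'
#' @param conc_start,conc_end mean concentrations at the start and end of
#'   the period (same units as the IQR). Alternatively give `delta`
#'   directly.
#' @param iqr the variable's interquartile range (> 0).
#' @param causal_effect_iqr per-IQR causal effect (visits/day per IQR).
#' @param days_per_year days per year (default 365).
#' @param delta optional concentration decline `conc_start - conc_end`;
#'   overrides the endpoint pair.
#' @param unit_conc,unit_iqr optional unit tags; if both given they must
#'   match.
#' @return attributable visits per year (a single number).
#' @export
attributable_visits <- function(conc_start = NULL, conc_end = NULL, iqr,
                                causal_effect_iqr, days_per_year = 365,
                                delta = NULL, unit_conc = NULL,
                                unit_iqr = NULL) {
  if (length(iqr) != 1 || !is.finite(iqr) || iqr <= 0)
    stop("'iqr' must be a single positive number")
  if (!is.null(unit_conc) && !is.null(unit_iqr) &&
      !identical(unit_conc, unit_iqr))
    stop("unit mismatch: concentrations in '", unit_conc,
         "' but IQR in '", unit_iqr, "'")
  if (is.null(delta)) {
    if (is.null(conc_start) || is.null(conc_end))
      stop("give either 'delta' or both 'conc_start' and 'conc_end'")
    delta <- conc_start - conc_end
  }
  (delta / iqr) * causal_effect_iqr * days_per_year
}

#' Share of an observed reduction explained by an attributable reduction
#'
#' @param attributable attributable annual visits (from
#'   [attributable_visits()]).
#' @param real_reduction the observed annual reduction (nonzero).
#' @return the share in percent, `100 * attributable / real_reduction`.
#' @export
reduction_share <- function(attributable, real_reduction) {
  if (any(real_reduction == 0)) stop("'real_reduction' must be nonzero")
  100 * attributable / real_reduction
}

#' Observed reduction in annual visits between two years
#'
#' @param visits_year_a,visits_year_b annual totals (>= 0); an increase
#'   yields a negative reduction.
#' @return `visits_year_a - visits_year_b`.
#' @export
real_reduction <- function(visits_year_a, visits_year_b) {
  if (any(c(visits_year_a, visits_year_b) < 0))
    stop("annual visit counts must be >= 0")
  visits_year_a - visits_year_b
}

#' Attribution table across pollutants
#'
#' Builds the stacked-contribution summary: for each pollutant the
#' concentration change, its attributable annual visits, and (when an
#' observed reduction is supplied) the share of that reduction explained.
#'
#' @param pollutants data.frame with columns `pollutant`, `conc_start`,
#'   `conc_end`, `iqr`, `causal_effect_iqr`, and optionally `unit`.
#' @param observed_reduction optional observed annual reduction against
#'   which shares are computed.
#' @param days_per_year days per year (default 365).
#' @return a `data.frame` with columns `pollutant`, `conc_start`,
#'   `conc_end`, `delta`, `iqr`, `causal_effect_iqr`,
#'   `attributable_visits_per_year`, and `share_of_real_reduction`
#'   (percent, `NA` when no observed reduction is given).
#' @export
attribute_reductions <- function(pollutants, observed_reduction = NULL,
                                 days_per_year = 365) {
  need <- c("pollutant", "conc_start", "conc_end", "iqr",
            "causal_effect_iqr")
  missing <- setdiff(need, colnames(pollutants))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  att <- mapply(attributable_visits,
                conc_start = pollutants$conc_start,
                conc_end = pollutants$conc_end,
                iqr = pollutants$iqr,
                causal_effect_iqr = pollutants$causal_effect_iqr,
                MoreArgs = list(days_per_year = days_per_year))
  share <- if (is.null(observed_reduction)) rep(NA_real_, length(att))
           else reduction_share(att, observed_reduction)
  out <- data.frame(pollutant = pollutants$pollutant,
                    conc_start = pollutants$conc_start,
                    conc_end = pollutants$conc_end,
                    delta = pollutants$conc_start - pollutants$conc_end,
                    iqr = pollutants$iqr,
                    causal_effect_iqr = pollutants$causal_effect_iqr,
                    attributable_visits_per_year = att,
                    share_of_real_reduction = share)
  rownames(out) <- NULL
  out
}

#' Pick the causal effect that feeds attribution
#'
#' From a lag sweep, selects for one treatment the maximum significant
#' per-IQR causal effect across lags -- the effect a burden calculation
#' carries forward. Errors if the treatment is never significant.
#'
#' @param object a [lagcausal()] fit.
#' @param treatment treatment name.
#' @return a list with `lag` and `causal_effect`.
#' @export
max_significant_effect <- function(object, treatment) {
  .check_identified(object)
  est <- object$estimates
  rows <- est[est$treatment == treatment & est$significant %in% TRUE, ,
              drop = FALSE]
  if (!nrow(rows))
    stop("treatment '", treatment, "' has no significant causal effect ",
         "at any lag")
  best <- rows[which.max(rows$causal_effect), ]
  list(lag = best$lag, causal_effect = best$causal_effect)
}
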