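# Variable inventory: 8 meteorological + 7 air-pollution variables, the
# standard daily panel from a national monitoring network plus NCEI-style
# weather records.
MET_VARS <- c("temperature", "feels_like", "dew", "humidity",
              "precipitation", "wind_speed", "visibility",
              "sea_level_pressure")
POLLUTANT_VARS <- c("SO2", "NO2", "CO", "O3", "PM2.5", "PM10", "AQI")

DEFAULT_UNITS <- c(
  temperature = "degC", feels_like = "degC", dew = "degC", humidity = "%",
  precipitation = "mm", wind_speed = "km/h", visibility = "km",
  sea_level_pressure = "hPa",
  SO2 = "ug/m3", NO2 = "ug/m3", CO = "mg/m3", O3 = "ug/m3",
  "PM2.5" = "ug/m3", PM10 = "ug/m3", AQI = "index")

# Deterministic substream seeds so environment, visits and cohort draws are
# independent given one user seed.
.substream <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629)
}

.ar1_noise <- function(n, ar, sd) {
  if (sd == 0) return(rep(0, n))
  innov <- stats::rnorm(n, 0, sd)
  init <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
  as.numeric(stats::filter(innov, ar, method = "recursive", init = init))
}

#' Configuration of the synthetic data-generating process
#'
#' Builds the configuration for [generate_environment()] and
#' [generate_visits()]. The defaults emulate an eight-year (2014-2021)
#' daily environmental panel for a subtropical-monsoon city:
#' meteorology as an annual sinusoid plus AR(1) noise; each pollutant as an
#' intercept plus linear couplings to meteorological/pollutant anomalies
#' (settling by precipitation and humidity, diffusion by wind, thermal
#' forcing by temperature, interconversion SO2/NO2/CO -> PM2.5 -> PM10 ->
#' AQI), a linear multi-year decline, and AR(1) noise, truncated at zero.
#' Default true effect: visits respond to SO2 five days earlier at 1.63
#' expected visits per ug/m3, on a baseline of 54 visits/day, which puts the
#' mean daily count near 75.
#'
#' @param n_days number of days (default 2922, eight years including two
#'   leap years).
#' @param start_date first calendar day.
#' @param met data.frame of per-variable seasonal/AR parameters; columns
#'   `variable`, `mean`, `amplitude`, `peak_doy` (day of year of the
#'   seasonal maximum), `ar`, `sd`.
#' @param pollutants data.frame with columns `variable`, `intercept`,
#'   `trend` (units/day), `ar`, `sd`.
#' @param coupling data.frame with columns `target`, `driver`, `coef`; each
#'   pollutant receives `coef` times the driver's anomaly (deviation from
#'   its own series mean), so `intercept` remains the pollutant's mean level.
#' @param true_effects data.frame with columns `variable`, `lag`, `effect`:
#'   the ground-truth per-unit effects on expected daily visits.
#' @param baseline_rate baseline of the visit process, on the link scale
#'   (expected visits/day under the identity link).
#' @param link `"identity"` (additive counts per unit, the default) or
#'   `"log"`.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_days = 2922L,
                         start_date = as.Date("2014-01-01"),
                         met = default_met_params(),
                         pollutants = default_pollutant_params(),
                         coupling = default_coupling(),
                         true_effects = data.frame(
                           variable = "SO2", lag = 5L, effect = 1.63),
                         baseline_rate = 54,
                         link = c("identity", "log")) {
  link <- match.arg(link)
  if (length(n_days) != 1 || n_days < 1 || n_days != round(n_days))
    stop("'n_days' must be a positive integer")
  if (any(!is.finite(met$ar)) || any(abs(met$ar) >= 1) ||
      any(!is.finite(pollutants$ar)) || any(abs(pollutants$ar) >= 1))
    stop("AR coefficients must lie strictly inside (-1, 1)")
  if (any(met$sd < 0) || any(pollutants$sd < 0))
    stop("noise standard deviations must be >= 0")
  if (any(!is.finite(coupling$coef)))
    stop("non-finite coupling coefficient for target(s): ",
         paste(coupling$target[!is.finite(coupling$coef)], collapse = ", "))
  if (baseline_rate <= 0 && link == "identity")
    stop("'baseline_rate' must be > 0")
  if (nrow(true_effects) &&
      (any(true_effects$lag < 0) || any(!is.finite(true_effects$effect))))
    stop("true_effects lags must be >= 0 and effects finite")
  structure(list(n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 met = met, pollutants = pollutants, coupling = coupling,
                 true_effects = true_effects,
                 baseline_rate = baseline_rate, link = link),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_met_params <- function() {
  data.frame(
    variable  = MET_VARS,
    mean      = c(17, 17.5, 12, 73, 4.5, 9.5, 11, 1016),
    amplitude = c(10.5, 12, 10, 6, 2.5, 1.5, 2.5, 9),
    peak_doy  = c(198, 198, 198, 166, 166, 91, 213, 15),
    ar        = c(0.80, 0.80, 0.80, 0.60, 0.30, 0.40, 0.50, 0.85),
    sd        = c(1.8, 2.0, 2.2, 7.0, 4.0, 2.8, 3.2, 2.5))
}

#' @rdname synth_config
#' @export
default_pollutant_params <- function() {
  # Trends reproduce eight-year declines of roughly SO2 20 -> 6 ug/m3,
  # NO2 -12.25 ug/m3, CO 0.89 -> 0.65 mg/m3, and milder PM/AQI declines.
  data.frame(
    variable  = POLLUTANT_VARS,
    intercept = c(20.08, 47, 0.89, 85, 45, 70, 88),
    trend     = c(-14.25, -12.25, -0.24, 0, -25, -25, -20) / 2921,
    ar        = c(0.65, 0.70, 0.70, 0.60, 0.65, 0.60, 0.60),
    sd        = c(1.6, 6.0, 0.07, 15, 9, 12, 10))
}

#' @rdname synth_config
#' @export
default_coupling <- function() {
  couple <- function(target, driver, coef)
    data.frame(target = target, driver = driver, coef = coef)
  rbind(
    # settling / diffusion / thermal forcing on the primary pollutants
    couple("SO2",   c("wind_speed", "precipitation", "humidity", "temperature"),
           c(-0.15, -0.12, -0.05, -0.10)),
    couple("NO2",   c("wind_speed", "precipitation", "humidity", "temperature"),
           c(-0.50, -0.30, -0.15, -0.35)),
    couple("CO",    c("wind_speed", "precipitation", "humidity", "temperature"),
           c(-0.010, -0.005, -0.002, -0.006)),
    couple("O3",    c("temperature", "wind_speed", "humidity"),
           c(1.5, 0.3, -0.4)),
    # interconversion chain into the particulates and the composite index
    couple("PM2.5", c("SO2", "NO2", "CO", "wind_speed", "precipitation",
                      "humidity"),
           c(0.8, 0.4, 15, -0.6, -0.5, -0.2)),
    couple("PM10",  c("PM2.5", "wind_speed", "precipitation"),
           c(0.9, -0.5, -0.6)),
    couple("AQI",   c("PM10", "PM2.5", "O3"),
           c(0.5, 0.4, 0.1)))
}

#' Generate a synthetic daily environmental series
#'
#' Draws the meteorological and pollutant series described by a
#' [synth_config()]. Identical `(config, seed)` pairs give bitwise-identical
#' output. Pollutant concentrations are truncated at zero after noise.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return an [env_series()] with `config$n_days` rows.
#' @export
generate_environment <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "environment"))

  out <- list()
  for (i in seq_len(nrow(config$met))) {
    p <- config$met[i, ]
    seasonal <- p$mean + p$amplitude * cos(2 * pi * (doy - p$peak_doy) / 365.25)
    out[[p$variable]] <- seasonal + .ar1_noise(n, p$ar, p$sd)
  }
  day_index <- seq_len(n) - 1L
  for (i in seq_len(nrow(config$pollutants))) {
    p <- config$pollutants[i, ]
    x <- p$intercept + p$trend * day_index + .ar1_noise(n, p$ar, p$sd)
    cp <- config$coupling[config$coupling$target == p$variable, , drop = FALSE]
    for (j in seq_len(nrow(cp))) {
      drv <- out[[cp$driver[j]]]
      if (is.null(drv))
        stop("coupling driver '", cp$driver[j], "' not yet generated; ",
             "drivers must precede their targets")
      x <- x + cp$coef[j] * (drv - mean(drv))
    }
    out[[p$variable]] <- pmax(x, 0)
  }
  env_series(dates, as.data.frame(out, check.names = FALSE),
             units = DEFAULT_UNITS[names(out)])
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Generate daily visit counts from lagged exposures
#'
#' Draws `Y_t ~ Poisson(lambda_t)` with linear predictor
#' `eta_t = baseline + sum_j effect_j * X_{v_j, t - k_j}`. Under the
#' identity link `lambda_t = max(eta_t, 1e-8)`; under the log link
#' `lambda_t = exp(eta_t)` (so `baseline` is then on the log scale). Terms
#' whose lagged day falls before the start of the series are omitted, so
#' the first `max(lag)` days are driven by the available lags only.
#'
#' @param env an [env_series()].
#' @param effects data.frame with columns `variable`, `lag`, `effect`; may
#'   have zero rows.
#' @param baseline_rate baseline on the link scale.
#' @param link `"identity"` or `"log"`.
#' @param seed integer seed.
#' @return a [visit_series()] aligned to `env`'s dates.
#' @export
generate_visits <- function(env, effects = data.frame(variable = character(),
                                                      lag = integer(),
                                                      effect = numeric()),
                            baseline_rate = 54,
                            link = c("identity", "log"), seed = 1L) {
  stopifnot(inherits(env, "env_series"))
  link <- match.arg(link)
  if (link == "identity" && baseline_rate < 0)
    stop("'baseline_rate' must be >= 0 under the identity link")
  vars <- setdiff(colnames(env), "date")
  unknown <- setdiff(effects$variable, vars)
  if (length(unknown))
    stop("effect variable(s) not in the environmental series: ",
         paste(unknown, collapse = ", "))
  n <- nrow(env)
  eta <- rep(baseline_rate, n)
  for (i in seq_len(nrow(effects))) {
    k <- effects$lag[i]
    x <- env[[effects$variable[i]]]
    idx <- seq_len(n) - k
    contrib <- ifelse(idx >= 1, x[pmax(idx, 1)], 0)
    eta <- eta + effects$effect[i] * contrib
  }
  lambda <- if (link == "log") exp(eta) else pmax(eta, 1e-8)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "visits"))
  visit_series(env$date, stats::rpois(n, lambda))
}

#' Generate a synthetic patient-level cohort from daily counts
#'
#' Expands daily counts into one record per visit with a synthetic patient
#' id, sex drawn Bernoulli(`sex_split`) (probability of male), and age drawn
#' from a piecewise-linear quantile function matching the requested
#' quartiles, bounded to the pediatric range [0, 18).
#'
#' @param visits a [visit_series()].
#' @param sex_split probability a visit is by a male patient; default 0.6468.
#' @param age_quartiles numeric triple `(Q1, median, Q3)` in years; default
#'   `c(3, 5, 7)`.
#' @param seed integer seed.
#' @return a `data.frame` with columns `patient_id`, `visit_date`, `age`,
#'   `sex`; exactly `sum(visits$visits)` rows.
#' @export
generate_cohort <- function(visits, sex_split = 0.6468,
                            age_quartiles = c(3, 5, 7), seed = 1L) {
  stopifnot(inherits(visits, "visit_series"))
  if (length(sex_split) != 1 || is.na(sex_split) || sex_split < 0 ||
      sex_split > 1)
    stop("'sex_split' must lie in [0, 1]")
  if (length(age_quartiles) != 3 || any(diff(age_quartiles) < 0))
    stop("'age_quartiles' must be a non-decreasing triple (Q1, median, Q3)")
  total <- sum(visits$visits)
  dates <- rep(visits$date, visits$visits)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "cohort"))
  sex <- ifelse(stats::runif(total) < sex_split, "M", "F")
  u <- stats::runif(total)
  knots_p <- c(0, 0.25, 0.5, 0.75, 1)
  knots_q <- c(0, age_quartiles, 17.99)
  age <- stats::approx(knots_p, knots_q, xout = u)$y
  data.frame(patient_id = sprintf("P%07d", seq_len(total)),
             visit_date = dates, age = age, sex = sex,
             stringsAsFactors = FALSE)
}
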