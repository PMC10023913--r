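#' Fit lagged causal effects of environmental exposures on daily counts
#'
#' The package's central fitting function. For each lag `k` in `lags` it
#' pairs the daily counts on day `t` with the exposures on day `t - k`,
#' identifies the backdoor adjustment set implied by the causal DAG, fits
#' the adjusted Poisson outcome model, and collects per-unit effects,
#' Wald standard errors and p-values, and IQR-scaled (per-IQR) causal
#' effects -- the full lag sweep an air-pollution time-series analysis
#' reports per treatment. The fit is deterministic given its inputs.
#'
#' If the backdoor criterion fails on the supplied DAG (for example when
#' the unobserved confounder is allowed to cause the treatments), the
#' returned object is flagged `identified = FALSE`, contains no estimates,
#' and its methods refuse to fabricate numbers.
#'
#' @param env an [env_series()] of daily exposures.
#' @param visits a [visit_series()] of daily counts.
#' @param dag a [causal_dag()]; defaults to the joint 8-treatment model of
#'   [build_multiple_treatment_dag()].
#' @param lags integer vector of lags in days (default `0:6`).
#' @param link `"identity"` (additive counts per unit, the default) or
#'   `"log"`.
#' @param alpha significance level for per-coefficient Wald tests.
#' @return an object of class `lagcausal` with components `estimates` (a
#'   `data.frame` of effect rows), `fits` (one [estimate_effect()] state
#'   per lag), `dag`, `adjustment`, `iqr`, `link`, `alpha`, `call`.
#' @seealso [estimate_effect()], [refute_estimate()], [effect_table()]
#' @examples
#' cfg <- synth_config(n_days = 400)
#' env <- generate_environment(cfg, seed = 1)
#' vis <- generate_visits(env, cfg$true_effects, cfg$baseline_rate,
#'                        cfg$link, seed = 1)
#' fit <- lagcausal(env, vis, build_single_treatment_dag("SO2"), lags = 0:2)
#' coef(fit)
#' @export
lagcausal <- function(env, visits, dag = build_multiple_treatment_dag(),
                      lags = 0:6, link = c("identity", "log"),
                      alpha = 0.05) {
  link <- match.arg(link)
  stopifnot(inherits(env, "env_series"), inherits(visits, "visit_series"),
            inherits(dag, "causal_dag"))
  if (any(lags < 0) || any(lags != round(lags)))
    stop("'lags' must be non-negative integers")
  lags <- sort(unique(as.integer(lags)))

  treatments <- dag$nodes[dag$roles == "treatment"]
  missing <- setdiff(treatments, colnames(env))
  if (length(missing))
    stop("treatment(s) absent from the exposure series: ",
         paste(missing, collapse = ", "))

  fits <- lapply(lags, function(k)
    estimate_effect(env, visits, dag, lag = k, link = link, alpha = alpha))
  names(fits) <- paste0("lag", lags)

  identified <- fits[[1]]$identified
  estimates <- if (identified) {
    do.call(rbind, lapply(fits, .estimate_rows))
  } else {
    data.frame()
  }
  if (identified) rownames(estimates) <- NULL

  structure(list(
    estimates = estimates,
    fits = fits,
    dag = dag,
    identified = identified,
    adjustment = if (identified) fits[[1]]$adjustment,
    iqr = if (identified) fits[[1]]$iqr,
    treatments = treatments,
    lags = lags, link = link, alpha = alpha,
    model_kind = .infer_model_kind(dag),
    call = match.call()),
    class = "lagcausal")
}

.estimate_rows <- function(est) {
  rows <- data.frame(
    model_kind = est$model_kind,
    treatment = est$treatments,
    lag = est$lag,
    per_unit_effect = unname(est$per_unit),
    standard_error = unname(est$standard_error),
    p_value = unname(est$p_value),
    iqr = unname(est$iqr),
    causal_effect = unname(est$causal_effect),
    significant = unname(est$p_value < est$alpha))
  if (!is.null(est$pooled)) {
    rows <- rbind(rows, data.frame(
      model_kind = est$model_kind, treatment = "pooled", lag = est$lag,
      per_unit_effect = est$pooled, standard_error = NA_real_,
      p_value = NA_real_, iqr = NA_real_, causal_effect = NA_real_,
      significant = NA))
  }
  rows
}

.check_identified <- function(object) {
  if (!object$identified)
    stop("the causal effect is not identified on this DAG; ",
         "no estimates are available")
}

#' @export
print.lagcausal <- function(x, digits = 3, ...) {
  cat("Lagged causal Poisson model (", x$model_kind, ", ", x$link,
      " link)\n", sep = "")
  cat("  treatments: ", paste(x$treatments, collapse = ", "), "\n", sep = "")
  if (!x$identified) {
    cat("  NOT IDENTIFIED: the backdoor criterion fails on this DAG\n")
    return(invisible(x))
  }
  cat("  adjustment: ",
      if (length(x$adjustment)) paste(x$adjustment, collapse = ", ")
      else "(none required)", "\n", sep = "")
  cat("  lags: ", paste(x$lags, collapse = ", "), "; alpha = ", x$alpha,
      "\n", sep = "")
  cat("\nPer-IQR causal effects (columns = lag):\n")
  print(round(effect_table(x, "causal_effect"), digits))
  invisible(x)
}

#' @export
summary.lagcausal <- function(object, ...) {
  .check_identified(object)
  est <- object$estimates
  strongest <- do.call(rbind, lapply(split(est, est$treatment), function(d) {
    d <- d[!is.na(d$causal_effect), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.max(abs(d$causal_effect)), ]
  }))
  structure(list(fit = object, strongest = strongest),
            class = "summary.lagcausal")
}

#' @export
print.summary.lagcausal <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nStrongest per-IQR effect per treatment:\n")
  cols <- c("treatment", "lag", "per_unit_effect", "iqr", "causal_effect",
            "p_value", "significant")
  out <- x$strongest[, cols]
  rownames(out) <- NULL
  print(format(out, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Wide effect table of a lag sweep
#'
#' Reshapes the estimate rows into the conventional treatment-by-lag table
#' (one row per treatment, one column per lag).
#'
#' @param object a [lagcausal()] fit.
#' @param value which column to tabulate: per-IQR `"causal_effect"` (the
#'   default), `"per_unit_effect"`, `"p_value"`, or `"significant"`.
#' @return a numeric matrix, treatments (plus `pooled` when present) by
#'   lags.
#' @export
effect_table <- function(object,
                         value = c("causal_effect", "per_unit_effect",
                                   "p_value", "significant")) {
  .check_identified(object)
  value <- match.arg(value)
  est <- object$estimates
  trt <- unique(est$treatment)
  out <- matrix(NA_real_, length(trt), length(object$lags),
                dimnames = list(trt, paste0("lag", object$lags)))
  for (i in seq_len(nrow(est)))
    out[est$treatment[i], paste0("lag", est$lag[i])] <- est[[value]][i]
  out
}

#' @export
coef.lagcausal <- function(object, ...) {
  .check_identified(object)
  effect_table(object, "per_unit_effect")
}

#' @export
predict.lagcausal <- function(object, newdata = NULL, lag = NULL,
                              type = c("response", "link"), ...) {
  .check_identified(object)
  type <- match.arg(type)
  lag <- if (is.null(lag)) object$lags[1] else lag
  fit <- object$fits[[paste0("lag", lag)]]
  if (is.null(fit)) stop("lag ", lag, " was not fitted")
  if (is.null(newdata)) newdata <- fit$table
  stats::predict(fit$model, newdata = newdata, type = type)
}

#' @export
residuals.lagcausal <- function(object, lag = NULL,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  .check_identified(object)
  type <- match.arg(type)
  lag <- if (is.null(lag)) object$lags[1] else lag
  fit <- object$fits[[paste0("lag", lag)]]
  if (is.null(fit)) stop("lag ", lag, " was not fitted")
  stats::residuals(fit$model, type = type)
}

#' @export
simulate.lagcausal <- function(object, nsim = 1, seed = NULL, lag = NULL,
                               ...) {
  .check_identified(object)
  lag <- if (is.null(lag)) object$lags[1] else lag
  fit <- object$fits[[paste0("lag", lag)]]
  if (is.null(fit)) stop("lag ", lag, " was not fitted")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(fit$model)
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.lagcausal <- function(x, value = "causal_effect", ...) {
  .check_identified(x)
  tab <- effect_table(x, value)
  tab <- tab[rownames(tab) != "pooled", , drop = FALSE]
  graphics::matplot(x$lags, t(tab), type = "b", pch = 19, lty = 1,
                    xlab = "lag (days)",
                    ylab = if (value == "causal_effect")
                      "causal effect (visits per IQR)" else value, ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = rownames(tab),
                   col = seq_len(nrow(tab)), lty = 1, pch = 19, cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' Export a lag-sweep effect table as CSV
#'
#' Writes the treatment-by-lag per-IQR causal-effect table with the
#' variable's IQR and per-lag significance flags, the layout in which such
#' results are conventionally reported.
#'
#' @param object a [lagcausal()] fit.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(object, path) {
  .check_identified(object)
  ce <- effect_table(object, "causal_effect")
  sig <- effect_table(object, "significant")
  trt <- rownames(ce)
  iqr <- object$iqr[trt]
  out <- data.frame(treatment = trt, iqr = unname(iqr),
                    ce, check.names = FALSE)
  sig_df <- as.data.frame(sig == 1)
  names(sig_df) <- paste0("significant_", colnames(sig))
  out <- cbind(out, sig_df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lagcausal
#' @param ... arguments passed to [lagcausal()].
#' @export
run_lag_sweep <- function(...) lagcausal(...)
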