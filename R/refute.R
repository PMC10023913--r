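.refuted_refit <- function(est, table, extra_adjust = character()) {
  fit <- fit_outcome_model(table, est$treatments,
                           c(est$adjustment, extra_adjust), est$link)
  if (length(est$treatments) == 1) {
    w <- .wald_stats(fit, est$treatments)
    list(effect = marginal_effect(fit, est$treatments), se = unname(w["se"]))
  } else {
    list(effect = pooled_effect(fit, est$treatments), se = NA_real_)
  }
}

.refutation_report <- function(method, est, refuted, refuted_se, reps,
                               tolerance, passed, seed) {
  structure(list(method = method,
                 original_effect = est$focal,
                 refuted_effects = refuted,
                 refuted_se = refuted_se,
                 repetitions = reps,
                 tolerance = tolerance,
                 passed = passed,
                 seed = seed),
            class = "refutation_report")
}

.relative_pass <- function(original, refuted, tolerance) {
  # relative stability rule with an absolute fallback when the original
  # effect is (numerically) zero
  if (abs(original) < 1e-8) {
    mean(abs(refuted - original)) < tolerance
  } else {
    mean(abs(refuted - original)) / abs(original) < tolerance
  }
}

.check_reps <- function(reps) {
  if (length(reps) != 1 || is.na(reps) || reps < 1 || reps != round(reps))
    stop("'reps' must be a positive integer")
}

#' Refute an estimate by adding a random common cause
#'
#' Appends an independent standard-normal covariate to the adjustment set
#' and re-estimates, `reps` times. A well-specified estimate should not
#' move: the probe passes when the mean absolute deviation of the refuted
#' effects from the original, relative to the original's magnitude, stays
#' below `tolerance`.
#'
#' @param est a [estimate_effect()] state (identified).
#' @param reps number of repetitions (default 20).
#' @param seed integer seed.
#' @param tolerance relative tolerance (default 0.1).
#' @return a `refutation_report`.
#' @export
refute_random_common_cause <- function(est, reps = 20, seed = 1L,
                                       tolerance = 0.1) {
  stopifnot(inherits(est, "causal_estimate"))
  if (!est$identified) stop("cannot refute an unidentified estimate")
  .check_reps(reps)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "random_common_cause"))
  n <- nrow(est$table)
  refuted <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- est$table
    tab$random_common_cause <- stats::rnorm(n)
    refuted[r] <- .refuted_refit(est, tab, "random_common_cause")$effect
  }
  .refutation_report("random_common_cause", est, refuted, NULL, reps,
                     tolerance,
                     .relative_pass(est$focal, refuted, tolerance), seed)
}

#' Refute an estimate by a placebo treatment
#'
#' Replaces each treatment column with an independent normal draw matched
#' to the real treatment's mean and standard deviation, and re-estimates.
#' Because the placebo is independent of the outcome, the refuted effect
#' should vanish: the probe passes when the mean refuted effect is within
#' two of its standard errors of zero (for a single treatment; for a
#' pooled multi-treatment estimate an absolute `tolerance` on the mean is
#' used since a pooled Wald SE is not defined).
#'
#' @inheritParams refute_random_common_cause
#' @param tolerance absolute fallback tolerance for pooled estimates.
#' @return a `refutation_report`.
#' @export
refute_placebo <- function(est, reps = 20, seed = 1L, tolerance = 0.1) {
  stopifnot(inherits(est, "causal_estimate"))
  if (!est$identified) stop("cannot refute an unidentified estimate")
  .check_reps(reps)
  for (t in est$treatments) {
    if (stats::sd(est$table[[t]]) == 0)
      stop("degenerate treatment '", t, "': zero variance")
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "placebo_treatment"))
  n <- nrow(est$table)
  refuted <- numeric(reps)
  ses <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- est$table
    for (t in est$treatments) {
      tab[[t]] <- stats::rnorm(n, mean(est$table[[t]]),
                               stats::sd(est$table[[t]]))
    }
    rr <- .refuted_refit(est, tab)
    refuted[r] <- rr$effect
    ses[r] <- rr$se
  }
  passed <- if (length(est$treatments) == 1) {
    abs(mean(refuted)) < 2 * mean(ses)
  } else {
    abs(mean(refuted)) < tolerance
  }
  .refutation_report("placebo_treatment", est, refuted, ses, reps,
                     tolerance, passed, seed)
}

#' Refute an estimate on random data subsets
#'
#' Re-estimates on uniformly random row subsets of the stated fraction. A
#' root-n-consistent estimator should be stable: the probe passes under
#' the same relative rule as [refute_random_common_cause()]. With
#' `fraction = 1` every refuted effect equals the original exactly.
#'
#' @inheritParams refute_random_common_cause
#' @param fraction subset fraction in (0, 1] (default 0.8).
#' @return a `refutation_report`.
#' @export
refute_subset <- function(est, fraction = 0.8, reps = 20, seed = 1L,
                          tolerance = 0.1) {
  stopifnot(inherits(est, "causal_estimate"))
  if (!est$identified) stop("cannot refute an unidentified estimate")
  .check_reps(reps)
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 ||
      fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  n <- nrow(est$table)
  m <- floor(fraction * n)
  p <- length(est$treatments) + length(est$adjustment) + 1
  if (m <= p + 1)
    stop("subset of ", m, " rows is too small to fit ", p, " coefficients")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.substream(seed, "data_subset"))
  refuted <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    refuted[r] <- .refuted_refit(est, est$table[idx, , drop = FALSE])$effect
  }
  .refutation_report("data_subset", est, refuted, NULL, reps, tolerance,
                     .relative_pass(est$focal, refuted, tolerance), seed)
}

#' Run the full refutation suite
#'
#' Applies all three robustness probes -- random common cause, placebo
#' treatment, and data subsets -- to an estimate. The estimate is labelled
#' robust iff all three pass.
#'
#' @inheritParams refute_random_common_cause
#' @param fraction subset fraction for [refute_subset()].
#' @return a list of class `refutation_suite` with one report per method
#'   and a `robust` flag.
#' @export
refute_estimate <- function(est, reps = 20, fraction = 0.8, seed = 1L,
                            tolerance = 0.1) {
  reports <- list(
    random_common_cause = refute_random_common_cause(est, reps, seed,
                                                     tolerance),
    placebo_treatment = refute_placebo(est, reps, seed, tolerance),
    data_subset = refute_subset(est, fraction, reps, seed, tolerance))
  structure(list(reports = reports,
                 robust = all(vapply(reports, `[[`, logical(1), "passed"))),
            class = "refutation_suite")
}

#' @export
print.refutation_report <- function(x, digits = 4, ...) {
  cat("Refutation (", x$method, "): ", x$repetitions, " repetitions\n",
      sep = "")
  cat("  original effect: ", format(x$original_effect, digits = digits),
      "\n  mean refuted:    ", format(mean(x$refuted_effects),
                                      digits = digits),
      "\n  verdict:         ", if (x$passed) "PASS" else "FAIL", "\n",
      sep = "")
  invisible(x)
}

#' @export
print.refutation_suite <- function(x, ...) {
  for (r in x$reports) print(r, ...)
  cat("Estimate is", if (x$robust) "ROBUST" else "NOT robust",
      "(all three probes must pass)\n")
  invisible(x)
}

#' Export refutation results as CSV
#'
#' One row per method and repetition: `method`, `rep`, `refuted_effect`.
#'
#' @param suite a [refute_estimate()] result (or single report).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_refutation_csv <- function(suite, path) {
  reports <- if (inherits(suite, "refutation_suite")) suite$reports
             else list(suite)
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(method = r$method, rep = seq_len(r$repetitions),
               refuted_effect = r$refuted_effects)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
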