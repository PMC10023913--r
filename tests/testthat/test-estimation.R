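test_that("model fitting rejects degenerate inputs", {
  st <- tiny_study(n_days = 120)
  tab <- lag_align(st$env, st$vis, 0)

  expect_error(fit_outcome_model(tab[1, ], "SO2"), "underdetermined")
  expect_error(fit_outcome_model(tab, "SO2", "not_a_column"),
               "missing column")
  tab$flat <- 1
  expect_error(fit_outcome_model(tab, "SO2", "flat"), "constant column")
  tab2 <- tab
  tab2$visits <- tab2$visits + 0.5
  expect_error(fit_outcome_model(tab2, "SO2"), "integer counts")
  tab$SO2_copy <- tab$SO2
  expect_error(fit_outcome_model(tab, "SO2", "SO2_copy"), "collinear")
})

test_that("null-effect coefficients are centred on zero with Wald coverage", {
  covered <- 0
  for (seed in 1:20) {
    st <- tiny_study(n_days = 600, seed = seed, effects = no_effects,
                     baseline = 75)
    tab <- lag_align(st$env, st$vis, 1)
    fit <- fit_outcome_model(tab, "SO2",
                             c("humidity", "temperature", "wind_speed"))
    est <- marginal_effect(fit, "SO2")
    se <- summary(fit)$coefficients["SO2", "Std. Error"]
    if (abs(est) < 2 * se) covered <- covered + 1
  }
  expect_gte(covered, 16)  # nominal ~95% coverage, tested at 80%
})

test_that("identity-link fit recovers a known per-unit effect", {
  st <- tiny_study(n_days = 2922, seed = 9,
                   effects = data.frame(variable = "SO2", lag = 0,
                                        effect = 1.59))
  tab <- lag_align(st$env, st$vis, 0)
  fit <- fit_outcome_model(tab, "SO2", backdoor_set(
    build_single_treatment_dag("SO2")))
  est <- marginal_effect(fit, "SO2")
  se <- summary(fit)$coefficients["SO2", "Std. Error"]
  expect_lt(abs(est - 1.59), 2 * se)
})

test_that("marginal effects honour the link function", {
  st <- tiny_study(n_days = 800, seed = 10)
  tab <- lag_align(st$env, st$vis, 5)

  fit_id <- fit_outcome_model(tab, "SO2", "humidity", link = "identity")
  expect_identical(marginal_effect(fit_id, "SO2"),
                   unname(coef(fit_id)["SO2"]))

  fit_log <- fit_outcome_model(tab, "SO2", "humidity", link = "log")
  # row-wise finite-difference oracle on the count scale
  b <- coef(fit_log)
  eta <- b[1] + b["SO2"] * tab$SO2 + b["humidity"] * tab$humidity
  oracle <- mean(exp(eta + b["SO2"]) - exp(eta))
  expect_equal(marginal_effect(fit_log, "SO2"), oracle, tolerance = 1e-10)

  expect_error(marginal_effect(fit_id, "ozone"), "not in the model")
})

test_that("pooled effect is additive under identity, joint-shift under log", {
  st <- tiny_study(n_days = 800, seed = 12)
  tab <- lag_align(st$env, st$vis, 1)
  trts <- c("SO2", "NO2", "CO")

  fit_id <- fit_outcome_model(tab, trts, "humidity", link = "identity")
  expect_equal(pooled_effect(fit_id, trts),
               sum(coef(fit_id)[trts]), tolerance = 1e-12)

  fit_log <- fit_outcome_model(tab, trts, "humidity", link = "log")
  b <- coef(fit_log)
  eta <- b[1] + as.matrix(tab[, c(trts, "humidity")]) %*%
    b[c(trts, "humidity")]
  oracle <- mean(exp(eta + sum(b[trts])) - exp(eta))
  expect_equal(pooled_effect(fit_log, trts), oracle, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pooled_effect(fit_log, trts),
                                sum(b[trts]))))

  expect_error(pooled_effect(fit_id, character(0)), "nonempty")
})

test_that("published pooled row is consistent with coordinate additivity", {
  # the eight reported single-coefficient lag-1 effects and the reported
  # pooled lag-1 effect agree within print rounding under additivity
  lag1 <- c(0.04, 0.10, 0.02, -0.14, -0.05, 0.93, 0.11, 0.02)
  expect_equal(sum(lag1), 1.03, tolerance = 1e-12)
  expect_lt(abs(sum(lag1) - 1.02), 8 * 0.005 + 0.005)
})

test_that("IQR scaling is the exact product and preserves sign", {
  expect_identical(scale_by_iqr(1.59, 7), 11.13)
  expect_identical(scale_by_iqr(123.4, 0), 0)
  expect_lt(scale_by_iqr(-0.3, 4.6), 0)
  expect_error(scale_by_iqr(1, -1), ">= 0")
})

test_that("the lag sweep produces a complete, internally consistent table", {
  st <- tiny_study(n_days = 700, seed = 13)
  fit <- lagcausal(st$env, st$vis, build_multiple_treatment_dag(),
                   lags = 0:3)
  est <- fit$estimates
  expect_equal(nrow(est), (8 + 1) * 4)  # 8 treatments + pooled, 4 lags
  rows <- est[est$treatment != "pooled", ]
  expect_equal(rows$causal_effect, rows$per_unit_effect * rows$iqr,
               tolerance = 1e-12)
  expect_true(all(rows$p_value >= 0 & rows$p_value <= 1))

  one <- lagcausal(st$env, st$vis, build_single_treatment_dag("SO2"),
                   lags = 0)
  expect_equal(nrow(one$estimates), 1)

  # pooled equals the sum of the per-treatment rows at every lag (identity)
  for (k in 0:3) {
    at <- est[est$lag == k, ]
    expect_equal(at$per_unit_effect[at$treatment == "pooled"],
                 sum(at$per_unit_effect[at$treatment != "pooled"]),
                 tolerance = 1e-10)
  }
})

test_that("identification failure propagates without fabricated estimates", {
  st <- tiny_study(n_days = 300, seed = 14)
  fit <- lagcausal(st$env, st$vis,
                   build_single_treatment_dag("SO2", u_to_treatments = TRUE),
                   lags = 0:1)
  expect_false(fit$identified)
  expect_equal(nrow(fit$estimates), 0)
  expect_error(coef(fit), "not identified")
  expect_error(effect_table(fit), "not identified")
})

test_that("dropping indirect causes shifts a meteorology-routed estimate", {
  # route part of the SO2-visits association through humidity: the
  # without-indirect model omits humidity and inherits its (negative
  # coupling x positive effect) bias, so the SO2 estimate falls
  effects <- data.frame(variable = c("SO2", "humidity"),
                        lag = c(5, 0), effect = c(1.63, 0.4))
  st <- tiny_study(n_days = 2000, seed = 15, effects = effects, baseline = 30)
  with_ind <- lagcausal(st$env, st$vis,
                        build_single_treatment_dag("SO2", TRUE), lags = 5)
  without_ind <- lagcausal(st$env, st$vis,
                           build_single_treatment_dag("SO2", FALSE), lags = 5)
  expect_lt(coef(without_ind)["SO2", "lag5"], coef(with_ind)["SO2", "lag5"])
})

test_that("model methods expose predictions, residuals and simulations", {
  st <- tiny_study(n_days = 300, seed = 16)
  fit <- lagcausal(st$env, st$vis, build_single_treatment_dag("SO2"),
                   lags = c(0, 5))
  mu <- predict(fit, lag = 5)
  expect_length(mu, 300 - 5)
  expect_true(all(mu > 0))
  r <- residuals(fit, lag = 5, type = "response")
  tab <- fit$fits$lag5$table
  expect_equal(unname(mu + r), tab$visits)

  sims <- simulate(fit, nsim = 3, seed = 1, lag = 5)
  expect_equal(dim(sims), c(295, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1, lag = 5))

  expect_error(predict(fit, lag = 2), "not fitted")
})
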