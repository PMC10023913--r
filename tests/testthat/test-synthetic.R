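noise_free_config <- function(n_days = 10) {
  met <- default_met_params()
  met$sd <- 0
  pol <- default_pollutant_params()
  pol$sd <- 0
  pol$trend <- 0
  coup <- default_coupling()
  coup <- coup[0, ]
  synth_config(n_days = n_days, met = met, pollutants = pol, coupling = coup)
}

test_that("noise-free configuration yields the pure seasonal curves", {
  cfg <- noise_free_config()
  env <- generate_environment(cfg, seed = 1)
  met <- cfg$met
  doy1 <- as.integer(format(cfg$start_date, "%j"))
  for (i in seq_len(nrow(met))) {
    expected_day0 <- met$mean[i] + met$amplitude[i] *
      cos(2 * pi * (doy1 - met$peak_doy[i]) / 365.25)
    expect_equal(env[[met$variable[i]]][1], expected_day0,
                 info = met$variable[i])
  }
  # pollutants collapse to their constant intercepts
  expect_equal(env$SO2, rep(20.08, 10))
})

test_that("generated SO2 declines at the configured trend (OLS oracle)", {
  cfg <- synth_config()
  env <- generate_environment(cfg, seed = 2)
  t_idx <- seq_len(nrow(env)) - 1
  y <- env$SO2
  # closed-form simple-regression slope and its standard error
  sxx <- sum((t_idx - mean(t_idx))^2)
  b <- sum((t_idx - mean(t_idx)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - b * (t_idx - mean(t_idx))
  se <- sqrt(sum(resid^2) / (length(y) - 2) / sxx)
  true_slope <- cfg$pollutants$trend[cfg$pollutants$variable == "SO2"]
  expect_lt(b, 0)
  expect_lt(abs(b - true_slope), 3 * se)
})

test_that("generation is a pure, reproducible function of config and seed", {
  cfg <- synth_config(n_days = 120)
  a <- generate_environment(cfg, seed = 42)
  b <- generate_environment(cfg, seed = 42)
  c <- generate_environment(cfg, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$SO2, c$SO2)))

  va <- generate_visits(a, no_effects, 75, "identity", seed = 42)
  vb <- generate_visits(a, no_effects, 75, "identity", seed = 42)
  expect_identical(va, vb)

  # generators must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_environment(cfg, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("invalid configurations are rejected", {
  met <- default_met_params()
  met$ar[1] <- 1.0
  expect_error(synth_config(met = met), "inside \\(-1, 1\\)")

  coup <- default_coupling()
  coup$coef[1] <- Inf
  expect_error(synth_config(coupling = coup), "non-finite coupling")

  expect_error(synth_config(n_days = 0), "positive integer")
  expect_error(synth_config(baseline_rate = 0), "> 0")

  env <- tiny_env(30)
  expect_error(
    generate_visits(env, data.frame(variable = "XYZ", lag = 0, effect = 1),
                    75, "identity", 1),
    "XYZ")
})

test_that("null-effect counts behave like Poisson(baseline)", {
  n <- 10958  # 30 years, for the moment checks
  cfg <- synth_config(n_days = n)
  env <- generate_environment(cfg, seed = 3)
  vis <- generate_visits(env, no_effects, 75, "identity", seed = 3)
  expect_lt(abs(mean(vis$visits) - 75), 3 * sqrt(75 / n))
  expect_lt(abs(mean(vis$visits) / 75 - 1), 0.05)
  expect_lt(abs(var(vis$visits) / 75 - 1), 0.05)

  # log link: baseline on the log scale gives the same constant rate
  vlog <- generate_visits(env, no_effects, log(75), "log", seed = 3)
  expect_lt(abs(mean(vlog$visits) - 75), 3 * sqrt(75 / n))
})

test_that("a single lagged effect is recovered by a regression oracle", {
  cfg <- synth_config()
  env <- generate_environment(cfg, seed = 4)
  eff <- data.frame(variable = "SO2", lag = 5, effect = 1.6)
  vis <- generate_visits(env, eff, 54, "identity", seed = 4)
  n <- nrow(env)
  y <- vis$visits[6:n]
  x <- env$SO2[1:(n - 5)]
  fit <- lm(y ~ x)
  est <- coef(fit)["x"]
  se <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(est - 1.6), 3 * se)
})

test_that("coupling sign drives the induced correlation sign", {
  base <- noise_free_config(n_days = 2922)
  met <- base$met
  met$sd[met$variable == "wind_speed"] <- 2.8
  pol <- base$pollutants
  pol$sd[pol$variable == "SO2"] <- 1.6
  for (sgn in c(-1, 1)) {
    cfg <- synth_config(n_days = 2922, met = met, pollutants = pol,
                        coupling = data.frame(target = "SO2",
                                              driver = "wind_speed",
                                              coef = sgn * 0.3))
    env <- generate_environment(cfg, seed = 5)
    rs <- spearman_cor(env$wind_speed, env$SO2)$rs
    expect_equal(sign(rs), sgn)
  }
})

test_that("cohort generation conserves counts and matches margins", {
  vs <- visit_series(as.Date("2020-01-01") + 0:99, rep(1000L, 100))
  rec <- generate_cohort(vs, sex_split = 0.6468, seed = 6)
  expect_equal(nrow(rec), 100000)
  expect_lt(abs(mean(rec$sex == "M") - 0.6468), 0.01)
  expect_true(all(rec$age >= 0 & rec$age < 18))
  q <- unname(quantile(rec$age, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(3, 5, 7), tolerance = 0.05)

  small <- visit_series(as.Date("2020-01-01") + 0:9, rep(10L, 10))
  expect_equal(nrow(generate_cohort(small, seed = 1)), 100)
  all_male <- generate_cohort(small, sex_split = 1, seed = 1)
  expect_true(all(all_male$sex == "M"))
  expect_error(generate_cohort(small, sex_split = 1.2), "\\[0, 1\\]")
})
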