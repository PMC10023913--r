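test_that("spearman is a rank statistic: monotone invariance and extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x^3)$rs, 1)
  expect_equal(spearman_cor(x, rev(x))$rs, -1)
  expect_equal(spearman_cor(x, x^3)$p, 0)

  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(30)
    b <- rnorm(30)
    raw <- spearman_cor(a, b)
    expect_equal(spearman_cor(exp(a), b)$rs, raw$rs)        # increasing map
    expect_equal(spearman_cor(a, qlogis(plogis(b)))$rs, raw$rs)
    expect_equal(spearman_cor(a, a)$rs, 1)
  }

  expect_error(spearman_cor(rep(1, 5), x), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("exact permutation p-value matches the brute-force oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  s <- spearman_cor(x, y, method = "exact")
  expect_equal(s$rs, 0.6)
  expect_equal(s$p, oracle_spearman_p(x, y))

  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(spearman_cor(a, b, method = "exact")$p,
                 oracle_spearman_p(a, b))
  }
  expect_error(spearman_cor(rnorm(9), rnorm(9), method = "exact"),
               "n <= 8")
})

test_that("the screening grid is complete and lag-aware", {
  st <- tiny_study(n_days = 200)
  grid <- lag_screen(st$env, st$vis, max_lag = 6)
  vars <- setdiff(colnames(st$env), "date")
  expect_equal(nrow(grid), length(vars) * 7)
  expect_true(all(grid$rs >= -1 & grid$rs <= 1))
  expect_true(all(grid$p >= 0 & grid$p <= 1))
  expect_true(all(grid$n > 2))
  # each lag-k cell is computed on its shorter aligned sample
  expect_equal(unique(grid$n[grid$lag == 6]), unique(grid$n[grid$lag == 0]) - 6)

  grid0 <- lag_screen(st$env, st$vis, max_lag = 0)
  expect_equal(unique(grid0$lag), 0)

  expect_error(lag_screen(st$env, st$vis, max_lag = 500), "series length")
})

test_that("a lagged effect surfaces at its own lag in the screen", {
  hits <- 0
  for (seed in 1:20) {
    st <- tiny_study(n_days = 500, seed = seed,
                     effects = data.frame(variable = "SO2", lag = 5,
                                          effect = 1.6))
    grid <- lag_screen(st$env, st$vis, max_lag = 6)
    so2 <- grid[grid$variable == "SO2", ]
    if (abs(so2$rs[so2$lag == 5]) > abs(so2$rs[so2$lag == 0])) hits <- hits + 1
  }
  expect_gt(hits, 10)  # majority of seeds
})

test_that("selection rules have any-lag / all-lags semantics", {
  st <- tiny_study(n_days = 300, seed = 2)
  grid <- lag_screen(st$env, st$vis, max_lag = 3)

  # craft a deterministic grid to pin the rule semantics
  fake <- grid
  fake$significant <- FALSE
  fake$significant[fake$variable == "SO2"] <- TRUE                # all lags
  fake$significant[fake$variable == "NO2" & fake$lag == 3] <- TRUE # one lag
  expect_equal(select_treatments(fake, "all_lags"), "SO2")
  expect_setequal(select_treatments(fake, "any_lag"), c("SO2", "NO2"))

  none <- grid
  none$significant <- FALSE
  expect_length(select_treatments(none, "any_lag"), 0)
  expect_error(select_treatments(grid, "sometimes"), "should be one of")
})

test_that("selection returns exactly the variables passing every lag", {
  st <- tiny_study(n_days = 2922, seed = 3)
  grid <- lag_screen(st$env, st$vis, max_lag = 6)
  chosen <- select_treatments(grid, "all_lags")
  manual <- unique(grid$variable)[vapply(unique(grid$variable), function(v)
    all(grid$p[grid$variable == v] < 0.05), logical(1))]
  expect_identical(chosen, manual)
  expect_true("SO2" %in% chosen)  # the variable carrying the true effect
})
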