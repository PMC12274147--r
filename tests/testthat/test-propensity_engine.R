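test_that("the odds shift satisfies its defining identities", {
  pis <- c(0, 1e-6, 0.2, 0.37, 0.5, 0.9, 1 - 1e-6, 1)
  expect_identical(shift_propensity(pis, 1), pis)
  expect_equal(shift_propensity(0.2, 4), 0.5)
  for (d in 2^runif(20, -9, 9)) {
    expect_identical(shift_propensity(0, d), 0)
    expect_identical(shift_propensity(1, d), 1)
  }
  expect_error(shift_propensity(0.5, 0), "domain error")
  expect_error(shift_propensity(0.5, -2), "domain error")
  expect_error(shift_propensity(1.2, 2), "domain error")
})

test_that("shift is odds-multiplicative, monotone and inverted by implied_delta", {
  set.seed(42)
  pis <- runif(50, 0.01, 0.99)
  d1 <- 2^runif(50, -5, 5); d2 <- 2^runif(50, -5, 5)
  expect_equal(shift_propensity(shift_propensity(pis, d1[1]), d2[1]),
               shift_propensity(pis, d1[1] * d2[1]), tolerance = 1e-12)
  for (i in 1:20)
    expect_equal(implied_delta(shift_propensity(pis[i], d1[i]), pis[i]), d1[i],
                 tolerance = 1e-10)
  expect_equal(implied_delta(shift_propensity(0.37, 2^-3), 0.37), 2^-3, tolerance = 1e-12)
  expect_equal(implied_delta(0.5, 0.2), 4)
  expect_equal(implied_delta(0.42, 0.42), 1)
  # strictly increasing in delta for interior pi
  q <- vapply(2^seq(-9, 9), function(d) shift_propensity(0.3, d), 0)
  expect_true(all(diff(q) > 0))
  expect_error(implied_delta(0, 0.5), "domain error")
  expect_error(implied_delta(0.5, 1), "domain error")
})

test_that("the default grid is the 19-point binary-power grid", {
  g <- default_delta_grid()
  expect_length(g, 19L)
  expect_equal(g[1], 1 / 512)
  expect_equal(g[10], 1)
  expect_equal(g[19], 512)
  expect_equal(as.numeric(g) * rev(as.numeric(g)), rep(1, 19))
  expect_error(delta_grid(c(1, 1)), "increasing")
  expect_error(delta_grid(c(-1, 2)), "increasing|positive")
})

test_that("the null propensity model recovers the marginal rate", {
  cfg <- synthetic_config(n = 2000, T = 1, p_C = c(b = 0.5),
                          coef_X = list(intercept = log(0.6 / 0.4), C = 0, l = 0),
                          seed = 14)
  pan <- generate_panel(cfg)
  fit <- fit_propensity(pan, 1)
  expect_equal(fit$regularization, 0)
  # score-equation identity of the intercept: mean fitted = empirical rate
  expect_equal(mean(fit$fitted_pi), mean(pan$x_1), tolerance = 1e-8)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - log(0.6 / 0.4)), 3 * 0.06)
  others <- fit$coefficients[names(fit$coefficients) != "(Intercept)"]
  expect_true(all(abs(others) < 0.5))
})

test_that("perfect separation engages the ridge fallback and keeps pi interior", {
  set.seed(1)
  n <- 150
  df <- data.frame(id = seq_len(n), g = rbinom(n, 1, 0.5), l_1 = rnorm(n),
                   x_1 = rbinom(n, 1, 0.5))
  df$y_1 <- 1 + 0.3 * df$x_1 + rnorm(n)
  df$l_2 <- rnorm(n); df$x_2 <- df$x_1; df$y_2 <- 1 + rnorm(n)
  pan <- panel_dataset(df, panel_schema(id = "id", C = "g", T = 2))
  expect_message(fit <- fit_propensity(pan, 2), "ridge fallback")
  expect_equal(fit$regularization, 1e-4)
  expect_true(all(fit$fitted_pi > 0 & fit$fitted_pi < 1))
  df$x_2 <- 1
  pan2 <- panel_dataset(df, panel_schema(id = "id", C = "g", T = 2))
  expect_error(fit_propensity(pan2, 2), "degenerate-exposure")
})

test_that("the propensity model recovers the generating coefficients", {
  dc <- discrete_config(n = 20000, seed = 17)
  pan <- generate_panel(dc)
  fit <- suppressMessages(fit_propensity(pan, 1))
  cf <- fit$coefficients
  # truth: intercept -0.2, base 0.3, l 0.4, interactions 0 (n = 20000)
  expect_lt(abs(cf[["(Intercept)"]] + 0.2), 0.15)
  expect_lt(abs(cf[["base"]] - 0.3), 0.2)
  expect_lt(abs(cf[["l_1"]] - 0.4), 0.2)
})

test_that("shifted-propensity summaries match direct arithmetic", {
  pan <- generate_panel(small_cont_config(n = 10, seed = 2))
  pis <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  fits <- list(list(fitted_pi = pis))
  sm <- summarize_shifted(pan, fits, delta_grid(c(0.5, 1, 2)))
  row1 <- sm[sm$delta == 1, ]
  expect_equal(row1$mean_q, mean(pis))
  expect_equal(row1$q10, unname(quantile(pis, 0.1)))
  expect_equal(row1$q90, unname(quantile(pis, 0.9)))
  q2 <- 2 * pis / (1 + pis)
  row2 <- sm[sm$delta == 2, ]
  expect_equal(row2$mean_q, mean(q2))
  expect_equal(row2$frac_above_0.05, mean(q2 > 0.05))
  # mean shifted propensity nondecreasing in delta
  expect_true(all(diff(sm$mean_q) >= 0))
})

test_that("overlap diagnostics flag empty and non-overlapping strata", {
  pan <- generate_panel(small_cont_config(n = 500, seed = 21))
  fit <- suppressMessages(fit_propensity(pan, 2))
  od <- overlap_diagnostics(pan, fit, 2)
  expect_equal(sum(od$stratum_prop[!duplicated(od$stratum)]), 1)
  expect_true(all(od$q1 <= od$q3, na.rm = TRUE))
  # constant propensity: full overlap
  fake <- list(fitted_pi = rep(0.5, nrow(pan)))
  od2 <- overlap_diagnostics(pan, fake, 2)
  expect_true(all(od2$iqr_overlap[od2$n > 0]))
  expect_true(all(od2$median[od2$n > 0] == 0.5))
  # x_2 == x_1 leaves the discordant cells empty and flagged
  df <- as.data.frame(pan); df$x_2 <- df$x_1
  pan3 <- panel_dataset(df, attr(pan, "schema"))
  f3 <- suppressMessages(fit_propensity(pan3, 2))
  od3 <- overlap_diagnostics(pan3, f3, 2)
  empty <- od3[(od3$stratum == "X1=1" & od3$x_current == 0) |
               (od3$stratum == "X1=0" & od3$x_current == 1), ]
  expect_true(all(empty$n == 0))
  expect_true(all(!empty$iqr_overlap))
  expect_error(overlap_diagnostics(pan, fit, 1), "t >= 2")
})
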