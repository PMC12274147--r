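fit_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dc <- discrete_config(n = 5000, seed = 5)
      pan <- generate_panel(dc)
      psf <- suppressMessages(fit_propensity_all(pan))
      sfit <- suppressMessages(fit_outcome_system(pan, outcome_system_spec(pan)))
      cache <<- list(dc = dc, pan = pan, psf = psf, sfit = sfit)
    }
    cache
  }
})

test_that("the cumulative weight has the stated closed form", {
  # single individual, X = (1, 0), pi = (0.5, 0.5), delta = 2 -> w = 8/9
  df <- data.frame(id = 1, c0 = 1, l_1 = 0, x_1 = 1, y_1 = 0,
                   l_2 = 0, x_2 = 0, y_2 = 3)
  pan <- panel_dataset(df, panel_schema(id = "id", C = "c0", T = 2))
  fits <- list(list(fitted_pi = 0.5), list(fitted_pi = 0.5))
  ht <- estimate_ipw(pan, fits, 2, 2, normalization = "horvitz_thompson")
  expect_equal(ht$estimate, 8 / 9 * 3, tolerance = 1e-12)
  hj <- estimate_ipw(pan, fits, 2, 2)
  expect_equal(hj$estimate, 3)   # Hajek normalizes the single weight away
})

test_that("Hajek IPW at delta = 1 is exactly the sample mean", {
  w <- fit_world()
  for (s in 1:2)
    expect_identical(estimate_ipw(w$pan, w$psf, 1, s)$estimate,
                     mean(w$pan[[paste0("y_", s)]]))
  expect_error(estimate_ipw(w$pan, w$psf, -1, 1), "domain error")
})

test_that("IPW, g-formula and enumeration agree with the enumeration truth", {
  w <- fit_world()
  for (d in c(1 / 4, 1, 4)) {
    tru <- true_ipsice(w$dc, d, 2, "enumerate")
    ipw <- estimate_ipw(w$pan, w$psf, d, 2)
    expect_lt(abs(ipw$estimate - tru), 3 * ipw$se + 1e-9)
    gf <- estimate_gformula(w$pan, w$sfit, w$psf, d, 2, mc_size = 100, seed = 13)
    expect_lt(abs(gf$estimate - tru), 3 * sqrt(gf$se^2 + ipw$se^2))
    en <- estimate_enumeration(w$pan, w$sfit, w$psf, d, 2)
    expect_lt(abs(en$estimate - tru), 3 * ipw$se)
    # model-based routes agree with each other within MC error
    expect_lt(abs(gf$estimate - en$estimate), 4 * gf$se)
  }
})

test_that("enumeration equals the independent flat-grid oracle", {
  w <- fit_world()
  for (d in c(1 / 4, 4)) {
    e1 <- estimate_enumeration(w$pan, w$sfit, w$psf, d, 1)$estimate
    expect_equal(e1, oracle_fitted_sum(w$pan, w$sfit, w$psf, d, 1), tolerance = 1e-10)
    e2 <- estimate_enumeration(w$pan, w$sfit, w$psf, d, 2, gh_nodes = 64)$estimate
    expect_equal(e2, oracle_fitted_sum(w$pan, w$sfit, w$psf, d, 2), tolerance = 1e-10)
  }
})

test_that("g-formula obeys the delta = 1 identity and MC scaling", {
  w <- fit_world()
  gf <- estimate_gformula(w$pan, w$sfit, w$psf, 1, 2, mc_size = 200, seed = 3)
  y <- w$pan$y_2
  expect_lt(abs(gf$estimate - mean(y)),
            3 * sqrt(gf$se^2 + var(y) / length(y)))
  se1 <- estimate_gformula(w$pan, w$sfit, w$psf, 2, 2, mc_size = 50, seed = 7)$se
  se2 <- estimate_gformula(w$pan, w$sfit, w$psf, 2, 2, mc_size = 200, seed = 7)$se
  expect_lt(abs(se1 / se2 - 2), 0.35)
  expect_error(estimate_gformula(w$pan, w$sfit, w$psf, 2, 2, mc_size = 0), "config error")
})

test_that("enumeration refuses continuous covariates", {
  cfg <- small_cont_config(n = 300, seed = 8)
  pan <- generate_panel(cfg)
  psf <- suppressMessages(fit_propensity_all(pan))
  sfit <- suppressMessages(fit_outcome_system(pan, outcome_system_spec(pan)))
  expect_error(estimate_enumeration(pan, sfit, psf, 2, 2), "estimate_gformula")
})

test_that("naive estimation is biased away from truth under latent confounding", {
  dcU <- discrete_config(n = 8000, u_loading = 0.7, seed = 21)
  panU <- generate_panel(dcU)
  psfU <- suppressMessages(fit_propensity_all(panU))
  lo <- estimate_ipw(panU, psfU, 1 / 4, 2)
  hi <- estimate_ipw(panU, psfU, 4, 2)
  # positive loadings on both equations: overstated exposure effect, so the
  # curve is too steep: biased low at small delta, high at large delta
  expect_lt(lo$estimate + 3 * lo$se, true_ipsice(dcU, 1 / 4, 2, "enumerate"))
  expect_gt(hi$estimate - 3 * hi$se, true_ipsice(dcU, 4, 2, "enumerate"))
})

test_that("curves are reproducible, well-shaped and reference-anchored", {
  pan <- generate_panel(small_cont_config(n = 300, seed = 41))
  g <- delta_grid(c(0.25, 1, 4))
  c0 <- ipsice_curve(pan, g, outcome_times = 2, method = "ipw", B = 0, seed = 2)
  expect_equal(nrow(c0), 3L)
  expect_true(all(is.na(c0$ci_low)))
  c1 <- ipsice_curve(pan, g, outcome_times = 1:2, method = "ipw", B = 25, seed = 2)
  c2 <- ipsice_curve(pan, g, outcome_times = 1:2, method = "ipw", B = 25, seed = 2)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_equal(nrow(c1), 6L)
  expect_false(any(c1$flagged[c1$delta == 1]))
  expect_true(all(c1$ci_low <= c1$estimate + 1e-9 & c1$estimate <= c1$ci_high + 1e-9))
  ref <- attr(c1, "reference")
  expect_equal(ref$mean, c(mean(pan$y_1), mean(pan$y_2)))
  gf <- ipsice_curve(pan, g, outcome_times = 2, method = "gformula", B = 0,
                     seed = 2, mc_size = 50)
  expect_equal(nrow(gf), 3L)
})

test_that("the sensitivity sweep is coherent and bookkept", {
  pan <- generate_panel(discrete_config(n = 1200, seed = 31))
  g <- delta_grid(c(0.5, 1, 2))
  main <- ipsice_curve(pan, g, outcome_times = 2, method = "gformula", B = 0,
                       seed = 11, mc_size = 60)
  sw <- sensitivity_sweep(pan, rho_grid = c(0, 0.2), grid = g, outcome_times = 2,
                          B = 0, seed = 11, mc_size = 60)
  expect_equal(nrow(sw), 2L * 3L * 1L)
  expect_identical(sw$estimate[sw$rho == 0], main$estimate)
  expect_false(identical(sw$estimate[sw$rho == 0.2], main$estimate))
  expect_error(sensitivity_sweep(pan, rho_grid = c(0, 1.5)), "inside")
})
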