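test_that("spec term rules match the declared interaction scheme", {
  sch <- panel_schema(id = "id", C = "g", L = "l", X = "x", Y = "y", T = 2)
  spec <- outcome_system_spec(sch)
  eq_y2 <- spec$equations[["y_2"]]
  expect_setequal(eq_y2$mains, c("x_2", "g", "l_1", "x_1", "y_1", "l_2"))
  labs <- paste(eq_y2$pairs[, 1], eq_y2$pairs[, 2], sep = ":")
  # x_1 and x_2 each interact with everything in H_2 except themselves; the
  # x_1:x_2 product appears exactly once
  expect_true(all(c("g:x_1", "g:x_2", "x_1:y_1", "x_2:y_1", "l_2:x_2") %in% labs))
  expect_equal(sum(labs == "x_1:x_2"), 1L)
  eq_l2 <- spec$equations[["l_2"]]
  expect_setequal(eq_l2$mains, c("g", "l_1", "x_1", "y_1"))
  expect_equal(nrow(eq_l2$pairs), 0L)
})

test_that("fixed-correlation declarations are validated", {
  sch <- panel_schema(id = "id", C = "g", T = 2)
  expect_error(outcome_system_spec(sch, fixed_residual_correlations =
    data.frame(x_wave = 1, y_wave = 1, rho = 1.2)), "inside \\(-1, 1\\)")
  expect_error(outcome_system_spec(sch, fixed_residual_correlations =
    data.frame(x_wave = 2, y_wave = 1, rho = 0.3)), "downstream")
  # same-wave pairs are downstream under exposure-first but not outcome-first
  expect_silent(outcome_system_spec(sch, fixed_residual_correlations =
    data.frame(x_wave = 1, y_wave = 1, rho = 0.3)))
  expect_error(outcome_system_spec(sch, ordering = "outcome_first",
    fixed_residual_correlations = data.frame(x_wave = 1, y_wave = 1, rho = 0.3)),
    "downstream")
})

test_that("least squares recovers the generating coefficients at large n", {
  cfg <- small_cont_config(n = 20000, T = 2, seed = 33)
  pan <- generate_panel(cfg)
  fit <- suppressMessages(fit_outcome_system(pan, outcome_system_spec(pan)))
  cy1 <- fit$coefficients[["y_1"]]
  expect_lt(abs(cy1[["x_1"]] - 0.2), 0.1)
  expect_lt(abs(cy1[["l_1"]] - 0.2), 0.05)
  cl2 <- fit$coefficients[["l_2"]]
  expect_lt(abs(cl2[["l_1"]] - 0.3), 0.05)
  expect_lt(abs(cl2[["x_1"]] - 0.2), 0.1)
  expect_lt(abs(fit$residual_sds[["l_2"]] - 0.8), 0.05)
})

test_that("joint ML factorizes to per-equation LS when unconstrained", {
  pan <- generate_panel(discrete_config(n = 1500, seed = 7))
  spec <- outcome_system_spec(pan)
  ls <- fit_outcome_system(pan, spec, method = "per_equation_ls")
  jm <- fit_outcome_system(pan, spec, method = "joint_ml")
  expect_equal(jm$loglik, ls$loglik, tolerance = 1e-8)
  expect_equal(unlist(jm$coefficients), unlist(ls$coefficients), tolerance = 1e-6)
  expect_equal(unname(jm$residual_sds), unname(ls$residual_sds), tolerance = 1e-6)
  # residual correlation matrices are PSD
  for (f in list(ls, jm))
    expect_gte(min(eigen(f$residual_correlation, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
})

test_that("fixing rho = 0 reproduces the unconstrained coefficients", {
  pan <- generate_panel(discrete_config(n = 1500, seed = 7))
  ls <- fit_outcome_system(pan, outcome_system_spec(pan))
  spec0 <- outcome_system_spec(pan, fixed_residual_correlations =
    data.frame(x_wave = c(1, 1, 2), y_wave = c(1, 2, 2), rho = 0))
  f0 <- fit_outcome_system(pan, spec0)
  expect_equal(f0$method, "joint_ml")
  shared <- intersect(names(ls$coefficients), names(f0$coefficients))
  expect_equal(unlist(f0$coefficients[shared]), unlist(ls$coefficients[shared]),
               tolerance = 1e-6)
})

test_that("equality constraints pool a common exposure effect", {
  pan <- generate_panel(discrete_config(n = 4000, seed = 19))  # true effect 0.4 at both waves
  spec <- outcome_system_spec(pan,
    equality_constraints = list(xy = c("y_1:x_1", "y_2:x_2")))
  fit <- fit_outcome_system(pan, spec)
  expect_identical(fit$coefficients[["y_1"]][["x_1"]],
                   fit$coefficients[["y_2"]][["x_2"]])
  expect_lt(abs(fit$coefficients[["y_1"]][["x_1"]] - 0.4), 0.15)
  free <- fit_outcome_system(pan, outcome_system_spec(pan))
  expect_lte(fit$loglik, free$loglik + 1e-8)
  expect_error(fit_outcome_system(pan, outcome_system_spec(pan,
    equality_constraints = list(bad = c("y_9:x_1", "y_1:x_1")))), "unknown")
})

test_that("an infeasible fixed-correlation set is rejected as non-PSD", {
  pan <- generate_panel(discrete_config(n = 300, seed = 3))
  spec <- outcome_system_spec(pan, fixed_residual_correlations =
    data.frame(x_wave = c(1, 1), y_wave = c(1, 2), rho = 0.95))
  expect_error(fit_outcome_system(pan, spec), "non-positive-definite")
})

test_that("coefficient paths are continuous in rho", {
  pan <- generate_panel(discrete_config(n = 1200, seed = 23))
  rhos <- seq(0, 0.3, by = 0.05)
  path <- vapply(rhos, function(r) {
    spec <- outcome_system_spec(pan, fixed_residual_correlations =
      data.frame(x_wave = c(1, 1, 2), y_wave = c(1, 2, 2), rho = r))
    fit_outcome_system(pan, spec)$coefficients[["y_1"]][["x_1"]]
  }, 0)
  expect_true(all(abs(diff(path)) < 0.25))
  # direction: positive rho pulls the exposure coefficient down
  expect_lt(path[length(path)], path[1])
})

test_that("prediction can condition on the exposure-equation residual", {
  pan <- generate_panel(discrete_config(n = 1000, seed = 13))
  spec <- outcome_system_spec(pan, fixed_residual_correlations =
    data.frame(x_wave = 1, y_wave = 1, rho = 0.3))
  fit <- fit_outcome_system(pan, spec)
  row <- as.data.frame(pan)[5, , drop = FALSE]
  marg <- predict_outcome(fit, 1, row)
  cond <- predict_outcome(fit, 1, row, condition_on_exposure_residual = TRUE)
  expect_false(isTRUE(all.equal(marg, cond)))
  # the adjustment is the regression of the outcome residual on the exposure residual
  j_y <- match("y_1", names(fit$equations)); j_x <- match("x_1", names(fit$equations))
  ex <- row$x_1 - ipsice:::linear_predictor(fit, j_x, row)
  adj <- 0.3 * fit$residual_sds[j_y] / fit$residual_sds[j_x] * ex
  expect_equal(unname(cond - marg), unname(adj), tolerance = 1e-10)
})

test_that("predict_outcome is the linear predictor and honours toggling", {
  pan <- generate_panel(discrete_config(n = 800, seed = 29))
  fit <- fit_outcome_system(pan, outcome_system_spec(pan))
  row <- as.data.frame(pan)[3, , drop = FALSE]
  cf <- fit$coefficients[["y_2"]]
  eq <- fit$equations[["y_2"]]
  manual <- cf[["(Intercept)"]]
  for (nm in names(cf)[-1]) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    manual <- manual + cf[[nm]] * prod(vapply(parts, function(p) row[[p]], 0))
  }
  expect_equal(predict_outcome(fit, 2, row), manual, tolerance = 1e-12)
  # all-zero covariates give the intercept
  zero <- row; for (nm in setdiff(names(zero), "id")) zero[[nm]] <- 0
  expect_equal(predict_outcome(fit, 2, zero), cf[["(Intercept)"]])
  # toggling x_2 moves the prediction by its main effect plus active interactions
  r1 <- row; r1$x_2 <- 1
  r0 <- row; r0$x_2 <- 0
  labs <- names(cf)
  inter <- grep("(^x_2:)|(:x_2$)", labs, value = TRUE)
  delta_manual <- cf[["x_2"]] + sum(vapply(inter, function(nm) {
    other <- setdiff(strsplit(nm, ":", fixed = TRUE)[[1]], "x_2")
    cf[[nm]] * row[[other]]
  }, 0))
  expect_equal(predict_outcome(fit, 2, r1) - predict_outcome(fit, 2, r0),
               delta_manual, tolerance = 1e-10)
  expect_error(predict_outcome(fit, 2, row[, 1:3]), "missing term")
})
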