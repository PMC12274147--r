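# Shared synthetic worlds used across the suite. Parameters are part of the
# stated test world and are not tuned to outcomes.

# Small continuous cohort: one baseline binary, one Gaussian stress covariate,
# stationary mid-scale outcome.
small_cont_config <- function(n = 400, T = 2, seed = 4, x_effect = 0.2) {
  synthetic_config(
    n = n, T = T, p_C = c(base = 0.5),
    coef_L = list(intercept = 0, C = 0.2, l_prev = 0.3, x_prev = 0.2, y_prev = 0.05,
                  sigma = 0.8),
    coef_X = list(intercept = 0.2, C = 0.2, l = 0.4, x_prev = 0.8, y_prev = 0.1),
    coef_Y = list(intercept = 2, C = 0.1, l = 0.2, x = x_effect, x_prev = x_effect / 2,
                  y_prev = 0.2, xl = 0, sigma = 0.5),
    y_bounds = c(1, 5), seed = seed)
}

# Null world for flagging calibration: zero exposure effects on the outcome.
null_config <- function(n = 400, seed = 1) small_cont_config(n = n, T = 2, seed = seed,
                                                            x_effect = 0)

expect_panel_ok <- function(panel) {
  s <- attr(panel, "schema")
  expect_s3_class(panel, "ipsi_panel")
  for (xc in s$X) expect_true(all(panel[[xc]] %in% 0:1))
}
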