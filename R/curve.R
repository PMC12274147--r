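curve_estimates <- function(panel, ps_fits, system_fit, deltas, times,
                            method, mc_size, normalization) {
  smax <- max(times)
  out <- matrix(NA_real_, length(deltas), length(times))
  for (i in seq_along(deltas)) {
    if (method == "gformula") {
      res <- gformula_sim(panel, system_fit, ps_fits, deltas[i], smax, mc_size)
      out[i, ] <- res$mean[times]
    } else {
      for (j in seq_along(times))
        out[i, j] <- estimate_ipw(panel, ps_fits, deltas[i], times[j],
                                  normalization)$estimate
    }
  }
  out
}

resample_panel <- function(panel, idx) {
  s <- panel_schema_of(panel)
  out <- as.data.frame(panel)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, schema = s, class = c("ipsi_panel", "data.frame"))
}

#' IPSICE curves over a shift-parameter grid with bootstrap inference
#'
#' For each outcome time and each grid value of \eqn{\delta}: the point
#' estimate and, when \code{B > 0}, a percentile 95\% confidence interval from
#' a nonparametric bootstrap that resamples individuals with replacement and
#' refits the propensity and outcome models inside every replicate. The
#' \eqn{\delta = 1} observed mean and its bootstrap CI are the reference; a
#' grid value is flagged when its CI does not overlap the reference CI
#' (a descriptive rule, not a formal test).
#'
#' @param panel an \code{ipsi_panel}.
#' @param grid a \code{\link{delta_grid}}.
#' @param outcome_times outcome waves (default: all).
#' @param method \code{"gformula"} (default) or \code{"ipw"}.
#' @param B bootstrap replicates (0 = point estimates only).
#' @param seed master seed; replicate sub-seeds are drawn from it so the
#'   resampling plan is reproducible.
#' @param mc_size g-formula replicates per individual.
#' @param ordering within-wave temporal ordering.
#' @param system_spec optional \code{\link{outcome_system_spec}} override.
#' @param normalization IPW normalization.
#' @param level confidence level of the percentile intervals.
#' @return An object of class \code{ipsice_curve}: a data.frame with columns
#'   (outcome_time, delta, estimate, ci_low, ci_high, flagged, method) and a
#'   \code{reference} attribute holding the observed means and their CIs.
#' @export
ipsice_curve <- function(panel, grid = default_delta_grid(), outcome_times = NULL,
                         method = c("gformula", "ipw"), B = 500L, seed = 1L,
                         mc_size = 1000L, ordering = "exposure_first",
                         system_spec = NULL, normalization = "hajek",
                         level = 0.95) {
  method <- match.arg(method)
  if (B < 0) stop("B must be >= 0", call. = FALSE)
  s <- panel_schema_of(panel)
  if (is.null(outcome_times)) outcome_times <- seq_len(s$T)
  deltas <- as.numeric(grid)
  smax <- max(outcome_times)
  n <- nrow(panel)
  if (is.null(system_spec) && method == "gformula")
    system_spec <- outcome_system_spec(panel, ordering)

  fit_all <- function(pan) {
    psf <- fit_propensity_all(pan, ordering, waves = seq_len(smax))
    sysf <- if (method == "gformula")
      fit_outcome_system(pan, system_spec) else NULL
    list(psf = psf, sysf = sysf)
  }

  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, B + 1L))
  fits <- suppressMessages(fit_all(panel))
  est <- with_seed(sub[1], curve_estimates(panel, fits$psf, fits$sysf, deltas,
                                           outcome_times, method, mc_size,
                                           normalization))
  ref_mean <- vapply(outcome_times, function(t) mean(panel[[s$Y[t]]]), 0)

  ci_lo <- ci_hi <- matrix(NA_real_, length(deltas), length(outcome_times))
  ref_ci <- matrix(NA_real_, length(outcome_times), 2)
  flagged <- matrix(NA, length(deltas), length(outcome_times))
  failed <- 0L
  if (B > 0) {
    boot <- array(NA_real_, c(B, length(deltas), length(outcome_times)))
    boot_ref <- matrix(NA_real_, B, length(outcome_times))
    for (b in seq_len(B)) {
      ok <- try(with_seed(sub[b + 1L], {
        idx <- sample.int(n, replace = TRUE)
        pan_b <- resample_panel(panel, idx)
        f <- suppressMessages(fit_all(pan_b))
        boot[b, , ] <- curve_estimates(pan_b, f$psf, f$sysf, deltas,
                                       outcome_times, method, mc_size,
                                       normalization)
        boot_ref[b, ] <- vapply(outcome_times, function(t) mean(pan_b[[s$Y[t]]]), 0)
      }), silent = TRUE)
      if (inherits(ok, "try-error")) failed <- failed + 1L
    }
    if (failed) message(failed, " bootstrap replicate(s) failed and were skipped")
    al <- (1 - level) / 2
    for (j in seq_along(outcome_times)) {
      ref_ci[j, ] <- stats::quantile(boot_ref[, j], c(al, 1 - al), na.rm = TRUE)
      for (i in seq_along(deltas)) {
        ci <- stats::quantile(boot[, i, j], c(al, 1 - al), na.rm = TRUE)
        ci_lo[i, j] <- ci[1]; ci_hi[i, j] <- ci[2]
        flagged[i, j] <- ci[1] > ref_ci[j, 2] || ci[2] < ref_ci[j, 1]
      }
      flagged[deltas == 1, j] <- FALSE   # the reference never flags itself
    }
  }

  rows <- do.call(rbind, lapply(seq_along(outcome_times), function(j)
    data.frame(outcome_time = outcome_times[j], delta = deltas,
               estimate = est[, j], ci_low = ci_lo[, j], ci_high = ci_hi[, j],
               flagged = flagged[, j], method = method)))
  structure(rows,
            reference = data.frame(outcome_time = outcome_times, mean = ref_mean,
                                   ci_low = ref_ci[, 1], ci_high = ref_ci[, 2]),
            grid = deltas, B = B, seed = seed, level = level,
            failed_replicates = failed,
            class = c("ipsice_curve", "data.frame"))
}

#' @export
print.ipsice_curve <- function(x, ...) {
  cat(sprintf("<ipsice_curve> %d delta value(s) x %d outcome time(s), B = %d\n",
              length(attr(x, "grid")), nrow(attr(x, "reference")), attr(x, "B")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plot an IPSICE curve on a binary-log shift axis
#'
#' Point estimates with vertical CI lines per \eqn{\delta}; horizontal dashed
#' and dotted lines mark the observed mean and its CI; flagged values are
#' drawn in red.
#'
#' @param x an \code{ipsice_curve}.
#' @param outcome_time which outcome wave to draw (default: first).
#' @param ... passed to \code{plot}.
#' @export
plot.ipsice_curve <- function(x, outcome_time = NULL, ...) {
  ref <- attr(x, "reference")
  if (is.null(outcome_time)) outcome_time <- ref$outcome_time[1]
  d <- x[x$outcome_time == outcome_time, ]
  r <- ref[ref$outcome_time == outcome_time, ]
  lx <- log2(d$delta)
  ylim <- range(c(d$estimate, d$ci_low, d$ci_high, r$mean), na.rm = TRUE)
  plot(lx, d$estimate, pch = 21, bg = ifelse(d$flagged %in% TRUE, "red", "white"),
       xlab = expression(log[2](delta)), ylab = "average potential outcome",
       ylim = ylim, main = paste("IPSICE, outcome time", outcome_time), ...)
  if (!all(is.na(d$ci_low)))
    segments(lx, d$ci_low, lx, d$ci_high,
             col = ifelse(d$flagged %in% TRUE, "red", "black"))
  abline(h = r$mean, lty = 2)
  if (!is.na(r$ci_low)) abline(h = c(r$ci_low, r$ci_high), lty = 3)
  invisible(x)
}

#' Sensitivity sweep over fixed exposure-outcome residual correlations
#'
#' Refits the outcome system with every exposure-outcome residual correlation
#' held fixed at each value of \code{rho_grid} (mimicking unmeasured
#' confounding of that strength) and recomputes the g-formula IPSICE curve.
#' The \code{rho = 0} row is the main analysis itself, reproduced exactly
#' (same seed, and per-equation least squares, which the zero-correlation
#' likelihood factorizes to).
#'
#' @inheritParams ipsice_curve
#' @param rho_grid residual correlations in (-1, 1); the default spans no to
#'   strong residual confounding.
#' @param base_spec optional unconstrained \code{outcome_system_spec} to which
#'   the fixed correlations are added.
#' @return A data.frame (rho, outcome_time, delta, estimate, ci_low, ci_high,
#'   flagged, method) of class \code{ipsice_sensitivity}.
#' @export
sensitivity_sweep <- function(panel, rho_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                              grid = default_delta_grid(), outcome_times = NULL,
                              B = 0L, seed = 1L, mc_size = 1000L,
                              ordering = "exposure_first", base_spec = NULL) {
  if (any(abs(rho_grid) >= 1))
    stop("every rho must lie strictly inside (-1, 1)", call. = FALSE)
  s <- panel_schema_of(panel)
  if (is.null(outcome_times)) outcome_times <- seq_len(s$T)
  if (is.null(base_spec)) base_spec <- outcome_system_spec(panel, ordering)
  all_pairs <- do.call(rbind, lapply(seq_len(s$T), function(xs) {
    ys <- if (ordering == "exposure_first") xs:s$T
          else if (xs < s$T) (xs + 1L):s$T else integer(0)
    if (!length(ys)) return(NULL)
    data.frame(x_wave = xs, y_wave = ys)
  }))
  out <- list()
  for (rho in rho_grid) {
    spec_r <- if (rho == 0) base_spec else
      outcome_system_spec(panel, ordering,
                          interactions = base_spec$interactions,
                          equality_constraints = base_spec$equality_constraints,
                          fixed_residual_correlations = cbind(all_pairs, rho = rho))
    cr <- ipsice_curve(panel, grid = grid, outcome_times = outcome_times,
                       method = "gformula", B = B, seed = seed,
                       mc_size = mc_size, ordering = ordering,
                       system_spec = spec_r)
    out[[length(out) + 1L]] <- cbind(rho = rho, as.data.frame(cr))
  }
  structure(do.call(rbind, out), class = c("ipsice_sensitivity", "data.frame"))
}

#' Plot shifted-propensity summaries on a binary-log shift axis
#'
#' Mean shifted propensity (cross) with the symmetric 80-percentile interval
#' (vertical line) per wave and grid value.
#'
#' @param summary output of \code{\link{summarize_shifted}}.
#' @param t wave to draw (default: first available).
#' @param ... passed to \code{plot}.
#' @export
plot_shifted_summary <- function(summary, t = NULL, ...) {
  if (is.null(t)) t <- summary$t[1]
  d <- summary[summary$t == t, ]
  lx <- log2(d$delta)
  plot(lx, d$mean_q, pch = 4, ylim = c(0, 1),
       xlab = expression(log[2](delta)), ylab = expression(Q[t]^delta),
       main = paste("Shifted propensity, wave", t), ...)
  segments(lx, d$q10, lx, d$q90)
  invisible(summary)
}
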