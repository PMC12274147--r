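new_ipsice_estimate <- function(delta, outcome_time, estimate, se, method, mc_size = NA_integer_) {
  structure(list(delta = delta, outcome_time = outcome_time, estimate = estimate,
                 se = se, method = method, mc_size = mc_size),
            class = "ipsice_estimate")
}

#' @export
print.ipsice_estimate <- function(x, ...) {
  cat(sprintf("IPSICE (%s) at delta = %g, outcome time %d: %.4f (se %.4f)\n",
              x$method, x$delta, x$outcome_time, x$estimate,
              if (is.null(x$se) || is.na(x$se)) NA_real_ else x$se))
  invisible(x)
}

#' Inverse-probability-weighted IPSICE estimate
#'
#' Weights each individual by the cumulative ratio of the shifted to the
#' natural propensity of their observed exposures,
#' \eqn{w = \prod_{t \le s} [\delta X_t + (1 - X_t)] / [\delta \pi_t + (1 - \pi_t)]},
#' and averages the wave-\code{s} outcome. Hajek normalization (weighted mean,
#' the default) reproduces the sample mean exactly at \eqn{\delta = 1};
#' Horvitz-Thompson divides by \code{n} instead.
#'
#' @param panel an \code{ipsi_panel}.
#' @param ps_fits per-wave \code{propensity_fit} list covering waves
#'   1..\code{outcome_time}.
#' @param delta positive shift parameter.
#' @param outcome_time outcome wave s.
#' @param normalization \code{"hajek"} or \code{"horvitz_thompson"}.
#' @param weight_cap optional stabilizing cap on the cumulative weights
#'   (default none: the intervention needs no positivity).
#' @return An \code{ipsice_estimate} with an empirical sandwich-type se.
#' @export
estimate_ipw <- function(panel, ps_fits, delta, outcome_time,
                         normalization = c("hajek", "horvitz_thompson"),
                         weight_cap = Inf) {
  normalization <- match.arg(normalization)
  if (!is.numeric(delta) || delta <= 0) stop("domain error: delta must be positive", call. = FALSE)
  s <- panel_schema_of(panel)
  y <- panel[[s$Y[outcome_time]]]
  n <- length(y)
  w <- rep(1, n)
  if (delta != 1) {
    for (t in seq_len(outcome_time)) {
      x <- panel[[s$X[t]]]
      pi_t <- ps_fits[[t]]$fitted_pi
      w <- w * (delta * x + (1 - x)) / (delta * pi_t + (1 - pi_t))
    }
    w <- pmin(w, weight_cap)
  }
  if (normalization == "hajek") {
    est <- if (all(w == w[1])) mean(y) else sum(w * y) / sum(w)
    se <- sqrt(sum((w * (y - est))^2)) / sum(w)
  } else {
    est <- mean(w * y)
    se <- stats::sd(w * y) / sqrt(n)
  }
  new_ipsice_estimate(delta, outcome_time, est, se, "ipw")
}

clip01 <- function(p) pmin(pmax(p, 0), 1)

# Simulate the fitted system under the delta-shifted propensity, starting from
# the observed baseline covariates; returns per-wave means and MC variance
# components. Chunked so n * mc_size never materializes at once.
gformula_sim <- function(panel, system_fit, ps_fits, delta, max_time, mc_size,
                         chunk_rows = 2e5) {
  s <- panel_schema_of(panel)
  ordering <- system_fit$spec$ordering
  Cdat <- as.matrix(panel[, s$C, drop = FALSE])
  n <- nrow(Cdat)
  reps_per_chunk <- max(1L, floor(chunk_rows / n))
  sums <- sumsq <- numeric(max_time)
  Ntot <- 0
  done <- 0L
  while (done < mc_size) {
    m <- min(reps_per_chunk, mc_size - done)
    N <- n * m
    cols <- c(s$C, unlist(lapply(seq_len(max_time), function(t) c(s$L[[t]], s$X[t], s$Y[t]))))
    sim <- matrix(0, N, length(cols), dimnames = list(NULL, cols))
    if (length(s$C)) sim[, s$C] <- Cdat[rep(seq_len(n), m), , drop = FALSE]
    draw_l <- function(t) {
      for (lc in s$L[[t]]) {
        # several L columns per wave each have their own equation
        jj <- which(vapply(system_fit$equations, function(e)
          e$kind == "L" && e$response == lc, NA))
        mu <- linear_predictor(system_fit, jj, sim)
        sim[, lc] <<- if (system_fit$is_binary[jj]) stats::rbinom(N, 1L, clip01(mu))
          else mu + stats::rnorm(N, sd = system_fit$residual_sds[jj])
      }
    }
    draw_x <- function(t) {
      pi_t <- predict.propensity_fit(ps_fits[[t]], sim)
      q <- shift_propensity(pi_t, delta)
      sim[, s$X[t]] <<- stats::rbinom(N, 1L, q)
    }
    draw_y <- function(t) {
      jj <- eq_index(system_fit, "Y", t)
      mu <- linear_predictor(system_fit, jj, sim)
      sim[, s$Y[t]] <<- mu + stats::rnorm(N, sd = system_fit$residual_sds[jj])
    }
    for (t in seq_len(max_time)) {
      if (ordering == "exposure_first") { draw_l(t); draw_x(t); draw_y(t) }
      else { draw_l(t); draw_y(t); draw_x(t) }
    }
    for (t in seq_len(max_time)) {
      v <- sim[, s$Y[t]]
      sums[t] <- sums[t] + sum(v)
      sumsq[t] <- sumsq[t] + sum(v^2)
    }
    Ntot <- Ntot + N
    done <- done + m
  }
  mean_y <- sums / Ntot
  var_y <- pmax(sumsq / Ntot - mean_y^2, 0)
  list(mean = mean_y, se = sqrt(var_y / Ntot), n_sim = Ntot)
}

#' Parametric g-formula IPSICE estimate
#'
#' Plug-in Monte-Carlo evaluation of the identification formula: starting from
#' each observed individual's baseline covariates, sequentially simulates
#' every time-varying covariate from its fitted equation, draws each exposure
#' from the delta-shifted fitted propensity, and simulates each outcome from
#' its fitted equation; the estimate is the grand mean of the simulated
#' outcome at \code{outcome_time} with its Monte-Carlo standard error.
#'
#' @inheritParams estimate_ipw
#' @param system_fit an \code{outcome_system_fit} covering the L and Y
#'   equations through \code{outcome_time}.
#' @param mc_size simulation replicates per observed individual (>= 1).
#' @param seed integer seed; identical seeds give identical estimates.
#' @return An \code{ipsice_estimate} with the Monte-Carlo se.
#' @export
estimate_gformula <- function(panel, system_fit, ps_fits, delta, outcome_time,
                              mc_size = 1000, seed = 1L) {
  if (mc_size < 1) stop("config error: mc_size must be >= 1", call. = FALSE)
  if (delta <= 0) stop("domain error: delta must be positive", call. = FALSE)
  res <- with_seed(seed,
    gformula_sim(panel, system_fit, ps_fits, delta, outcome_time, mc_size))
  new_ipsice_estimate(delta, outcome_time, res$mean[outcome_time],
                      res$se[outcome_time], "gformula", as.integer(mc_size))
}

# probabilists' Gauss-Hermite nodes/weights (weights sum to 1) via
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite_prob <- function(m) {
  if (m == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, m, m)
  off <- sqrt(seq_len(m - 1L))
  J[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- off
  J[cbind(seq_len(m - 1L) + 1L, seq_len(m - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2)[ord])
}

#' Exact enumeration IPSICE estimate from the fitted models
#'
#' Evaluates the identification sum exactly over the empirical baseline
#' distribution, all binary time-varying covariate paths and all exposure
#' paths, substituting the fitted conditional means and probabilities. Waves
#' of the Gaussian outcome that feed later histories are integrated by
#' Gauss-Hermite quadrature (they enter the fitted logistic propensity
#' nonlinearly, so no finite sum exists); with enough nodes this is exact to
#' numerical precision. Requires every time-varying covariate in scope to be
#' binary and \code{outcome_time <= 3}; otherwise use
#' \code{\link{estimate_gformula}}.
#'
#' @inheritParams estimate_gformula
#' @param gh_nodes Gauss-Hermite node count for outcome-wave integration.
#' @return An \code{ipsice_estimate} (no Monte-Carlo error; \code{se} is NA).
#' @export
estimate_enumeration <- function(panel, system_fit, ps_fits, delta, outcome_time,
                                 gh_nodes = 21L) {
  if (delta <= 0) stop("domain error: delta must be positive", call. = FALSE)
  if (outcome_time > 3L) stop("enumeration supports outcome_time <= 3", call. = FALSE)
  s <- panel_schema_of(panel)
  ordering <- system_fit$spec$ordering
  for (t in seq_len(outcome_time)) for (lc in s$L[[t]]) {
    jj <- which(vapply(system_fit$equations, function(e)
      e$kind == "L" && e$response == lc, NA))
    if (!system_fit$is_binary[jj])
      stop("unsupported-method error: continuous time-varying covariate '", lc,
           "'; use estimate_gformula", call. = FALSE)
  }
  if (ordering != "exposure_first")
    stop("enumeration is implemented for the exposure-first ordering", call. = FALSE)
  gh <- gauss_hermite_prob(as.integer(gh_nodes))

  # collapse identical baseline rows
  Cdat <- as.data.frame(panel)[, s$C, drop = FALSE]
  key <- if (length(s$C)) do.call(paste, c(Cdat, sep = "\r")) else rep("", nrow(panel))
  firsts <- !duplicated(key)
  tab <- Cdat[firsts, , drop = FALSE]
  tab$w <- as.numeric(table(key)[key[firsts]]) / nrow(panel)
  rownames(tab) <- NULL

  branch <- function(tab, col, values, probs) {
    m <- length(values)
    out <- tab[rep(seq_len(nrow(tab)), each = m), , drop = FALSE]
    out[[col]] <- rep(values, nrow(tab))
    out$w <- out$w * as.vector(t(probs))
    rownames(out) <- NULL
    out
  }
  for (t in seq_len(outcome_time)) {
    for (lc in s$L[[t]]) {
      jj <- which(vapply(system_fit$equations, function(e)
        e$kind == "L" && e$response == lc, NA))
      p1 <- clip01(linear_predictor(system_fit, jj, tab))
      tab <- branch(tab, lc, 0:1, cbind(1 - p1, p1))
    }
    pi_t <- predict.propensity_fit(ps_fits[[t]], tab)
    q <- shift_propensity(pi_t, delta)
    tab <- branch(tab, s$X[t], 0:1, cbind(1 - q, q))
    jj <- eq_index(system_fit, "Y", t)
    mu <- linear_predictor(system_fit, jj, tab)
    if (t == outcome_time)
      return(new_ipsice_estimate(delta, outcome_time, sum(tab$w * mu) / sum(tab$w),
                                 NA_real_, "enumerate"))
    sig <- system_fit$residual_sds[jj]
    nr <- nrow(tab)
    tab <- branch(tab, s$Y[t], seq_along(gh$nodes),
                  matrix(gh$weights, nr, length(gh$nodes), byrow = TRUE))
    tab[[s$Y[t]]] <- rep(mu, each = length(gh$nodes)) + sig * gh$nodes[tab[[s$Y[t]]]]
  }
}
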