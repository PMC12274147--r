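# Independent brute-force oracles. These re-implement the identification sum
# with plain recursion / flat grids, deliberately not sharing code with the
# package's table-expansion enumerators.

`%0%` <- function(a, b) if (is.null(a)) b else a

# Exact IPSICE of a *discrete* synthetic config by depth-first recursion over
# all paths, carrying a +/-1 latent confounder. Phase 1 accumulates the
# natural-law components of pibar(h_t) = P(X_t = 1 | h_t); phase 2 walks the
# intervened law with the shifted draw probability.
oracle_true_ipsice <- function(config, delta, s) {
  stopifnot(config$discrete)
  kc <- length(config$p_C)
  u_vals <- if (any(config$u_strength != 0)) c(-1, 1) else 0
  u_prob <- rep(1 / length(u_vals), length(u_vals))
  aL <- config$coef_L; aX <- config$coef_X; aY <- config$coef_Y
  cdot <- function(cf, cvec) if (kc) sum(cf$C * cvec) else 0
  eps_vals <- if (aY$sigma > 0) c(-1, 1) * aY$sigma else 0
  eps_prob <- rep(1 / length(eps_vals), length(eps_vals))

  key_of <- function(cvec, l, x, y, t)
    paste(c(cvec, l[seq_len(t)], if (t > 1) x[seq_len(t - 1)],
            if (t > 1) y[seq_len(t - 1)]), collapse = "|")

  num <- new.env(); den <- new.env()
  lp_l <- function(cvec, l, x, y, t)
    aL$intercept + cdot(aL, cvec) +
      (if (t > 1) aL$l_prev * l[t - 1] + aL$x_prev * x[t - 1] + aL$y_prev * y[t - 1] else 0)
  lp_x <- function(u, cvec, lv, x, y, t)
    aX$intercept + cdot(aX, cvec) + aX$l * lv +
      (if (t > 1) aX$x_prev * x[t - 1] + aX$y_prev * y[t - 1] else 0) +
      config$u_strength[1] * u
  lp_y <- function(u, cvec, lv, xv, x, y, t)
    aY$intercept + cdot(aY, cvec) + aY$l * lv + aY$x * xv + aY$xl * xv * lv +
      (if (t > 1) aY$x_prev * x[t - 1] + aY$y_prev * y[t - 1] else 0) +
      config$u_strength[2] * u

  walk_nat <- function(u, cvec, l, x, y, t, prob) {
    pl1 <- lp_l(cvec, l, x, y, t)
    for (lv in 0:1) {
      p_here <- prob * (if (lv == 1) pl1 else 1 - pl1)
      l[t] <- lv
      k <- key_of(cvec, l, x, y, t)
      piu <- stats::plogis(lp_x(u, cvec, lv, x, y, t))
      num[[k]] <- (num[[k]] %0% 0) + p_here * piu
      den[[k]] <- (den[[k]] %0% 0) + p_here
      if (t < s) {
        for (xv in 0:1) {
          x[t] <- xv
          p_x <- p_here * (if (xv == 1) piu else 1 - piu)
          mu_y <- lp_y(u, cvec, lv, xv, x, y, t)
          for (ie in seq_along(eps_vals)) {
            y[t] <- mu_y + eps_vals[ie]
            walk_nat(u, cvec, l, x, y, t + 1, p_x * eps_prob[ie])
          }
        }
      }
    }
  }

  total <- 0
  walk_int <- function(u, cvec, l, x, y, t, prob) {
    pl1 <- lp_l(cvec, l, x, y, t)
    for (lv in 0:1) {
      p_here <- prob * (if (lv == 1) pl1 else 1 - pl1)
      l[t] <- lv
      k <- key_of(cvec, l, x, y, t)
      q <- ipsice::shift_propensity(num[[k]] / den[[k]], delta)
      for (xv in 0:1) {
        x[t] <- xv
        p_x <- p_here * (if (xv == 1) q else 1 - q)
        mu_y <- lp_y(u, cvec, lv, xv, x, y, t)
        if (t == s) {
          total <<- total + p_x * mu_y
        } else {
          for (ie in seq_along(eps_vals)) {
            y[t] <- mu_y + eps_vals[ie]
            walk_int(u, cvec, l, x, y, t + 1, p_x * eps_prob[ie])
          }
        }
      }
    }
  }

  cgrid <- if (kc) as.matrix(expand.grid(rep(list(0:1), kc))) else matrix(0, 1, 0)
  for (iu in seq_along(u_vals)) {
    for (ic in seq_len(nrow(cgrid))) {
      cvec <- cgrid[ic, ]
      pc <- if (kc) prod(ifelse(cvec == 1, config$p_C, 1 - config$p_C)) else 1
      z <- numeric(s)
      walk_nat(u_vals[iu], cvec, z, z, z, 1, u_prob[iu] * pc)
    }
  }
  for (iu in seq_along(u_vals)) {
    for (ic in seq_len(nrow(cgrid))) {
      cvec <- cgrid[ic, ]
      pc <- if (kc) prod(ifelse(cvec == 1, config$p_C, 1 - config$p_C)) else 1
      z <- numeric(s)
      walk_int(u_vals[iu], cvec, z, z, z, 1, u_prob[iu] * pc)
    }
  }
  total
}

# Independent evaluation of the plug-in identification sum over the FITTED
# models: one flat grid over every discrete branch, with composite-Simpson
# quadrature (not Gauss-Hermite) for Gaussian outcome waves feeding later
# histories. Supports outcome_time 1 or 2 with a single binary L per wave.
oracle_fitted_sum <- function(panel, system_fit, ps_fits, delta, outcome_time,
                              n_simpson = 8001, width = 10) {
  s <- attr(panel, "schema")
  stopifnot(outcome_time %in% 1:2, all(lengths(s$L[seq_len(outcome_time)]) == 1))
  Call <- as.data.frame(panel)[, s$C, drop = FALSE]
  ckey <- do.call(paste, c(Call, sep = "\r"))
  Cdat <- Call[!duplicated(ckey), , drop = FALSE]
  Cdat$.cw <- as.numeric(table(ckey)[ckey[!duplicated(ckey)]]) / nrow(Call)
  rownames(Cdat) <- NULL
  lp <- function(eqname, df) {
    j <- match(eqname, names(system_fit$equations))
    ipsice:::linear_predictor(system_fit, j, df)
  }
  clip01 <- function(p) pmin(pmax(p, 0), 1)

  if (outcome_time == 1L) {
    g <- merge(cbind(Cdat, .row = seq_len(nrow(Cdat))),
               expand.grid(l1 = 0:1, x1 = 0:1), by = NULL)
    g[[s$L[[1]]]] <- g$l1; g[[s$X[1]]] <- g$x1
    pl <- clip01(lp(s$L[[1]], g))
    pi1 <- predict(ps_fits[[1]], g)
    q1 <- ipsice::shift_propensity(pi1, delta)
    w <- g$.cw * ifelse(g$l1 == 1, pl, 1 - pl) * ifelse(g$x1 == 1, q1, 1 - q1)
    mu <- lp(s$Y[1], g)
    return(sum(w * mu))
  }

  h <- 2 * width / (n_simpson - 1)
  z <- seq(-width, width, length.out = n_simpson)
  simp <- c(1, rep(c(4, 2), length.out = n_simpson - 2), 1)
  simp[n_simpson] <- 1
  wz <- simp * h / 3 * stats::dnorm(z)
  wz <- wz / sum(wz)

  g <- merge(cbind(Cdat, .row = seq_len(nrow(Cdat))),
             expand.grid(l1 = 0:1, x1 = 0:1, iy = seq_len(n_simpson),
                         l2 = 0:1, x2 = 0:1), by = NULL)
  g[[s$L[[1]]]] <- g$l1; g[[s$X[1]]] <- g$x1
  pl1 <- clip01(lp(s$L[[1]], g))
  q1 <- ipsice::shift_propensity(predict(ps_fits[[1]], g), delta)
  mu1 <- lp(s$Y[1], g)
  j1 <- match(s$Y[1], names(system_fit$equations))
  g[[s$Y[1]]] <- mu1 + system_fit$residual_sds[j1] * z[g$iy]
  g[[s$L[[2]]]] <- g$l2
  pl2 <- clip01(lp(s$L[[2]], g))
  g[[s$X[2]]] <- g$x2
  q2 <- ipsice::shift_propensity(predict(ps_fits[[2]], g), delta)
  w <- g$.cw * ifelse(g$l1 == 1, pl1, 1 - pl1) * ifelse(g$x1 == 1, q1, 1 - q1) *
    wz[g$iy] *
    ifelse(g$l2 == 1, pl2, 1 - pl2) * ifelse(g$x2 == 1, q2, 1 - q2)
  mu2 <- lp(s$Y[2], g)
  sum(w * mu2)
}
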