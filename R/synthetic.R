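#' Configuration of the synthetic recurring-exposure cohort
#'
#' The generator draws, per individual, baseline binaries \code{C}, then
#' sequentially for each wave \code{t}: a time-varying confounder \code{L_t}
#' affected by past exposure, a binary exposure \code{X_t} assigned by a
#' logistic model on the observed history (through \code{C}, \code{L_t},
#' \code{X_{t-1}}, \code{Y_{t-1}}), and an outcome \code{Y_t} depending on the
#' exposure history. An optional shared latent confounder \code{U} loads on
#' the exposure and outcome equations; with \code{u_strength = 0} there is no
#' unmeasured confounding by construction.
#'
#' With \code{discrete = TRUE} the world is fully discrete so the intervention
#' mean can be computed by exact path enumeration: \code{L_t} becomes binary
#' with a *linear* success probability, the outcome noise becomes a symmetric
#' two-point variable (+/- \code{sigma}), and \code{U} (if any) is a +/-1 coin.
#' Coefficients must keep every reachable L-probability inside [0, 1]; this is
#' checked at generation time.
#'
#' @param n cohort size (>= 1).
#' @param T number of waves (>= 1).
#' @param p_C named vector of Bernoulli probabilities for the baseline
#'   binaries (may be empty).
#' @param coef_L list(intercept, C, l_prev, x_prev, y_prev, sigma): the
#'   linear equation of \code{L_t}; \code{sigma} is the Gaussian noise sd
#'   (ignored when \code{discrete}).
#' @param coef_X list(intercept, C, l, x_prev, y_prev): the logistic equation
#'   of \code{X_t}.
#' @param coef_Y list(intercept, C, l, x, x_prev, y_prev, xl, sigma): the
#'   linear equation of \code{Y_t}; \code{xl} is an optional current
#'   exposure-by-covariate interaction.
#' @param u_strength loadings of the latent confounder on (X, Y); a scalar is
#'   recycled to both. 0 means no unmeasured confounding.
#' @param discrete fully discrete variant for exact enumeration.
#' @param y_bounds clip range for the continuous outcome (the observed scale,
#'   e.g. a 1..5 depression score); \code{NULL} disables clipping. Ignored
#'   when \code{discrete}.
#' @param keep_counterfactuals also simulate, with shared noise, the potential
#'   outcomes under every fixed exposure path (debug flag; stored as an
#'   attribute of the generated panel).
#' @param seed integer seed used by \code{\link{generate_panel}}.
#' @return An object of class \code{ipsi_config}.
#' @export
synthetic_config <- function(n = 1000, T = 3,
                             p_C = c(cohort = 0.5, female = 0.5, black = 0.8, income = 0.55),
                             coef_L = list(intercept = 0, C = c(0, 0, 0.2, 0.1),
                                           l_prev = 0.4, x_prev = 0.25, y_prev = 0.05,
                                           sigma = 0.9),
                             coef_X = list(intercept = 0.6, C = c(-0.1, 0.1, 0.3, 0.2),
                                           l = 0.5, x_prev = 1.4, y_prev = 0.1),
                             coef_Y = list(intercept = 1.8, C = c(0.05, 0.1, 0.1, 0.1),
                                           l = 0.2, x = 0.2, x_prev = 0.1, y_prev = 0.2,
                                           xl = 0, sigma = 0.55),
                             u_strength = 0, discrete = FALSE,
                             y_bounds = c(1, 5), keep_counterfactuals = FALSE,
                             seed = 1L) {
  n <- as.integer(n); T <- as.integer(T)
  if (is.na(n) || n < 1L || is.na(T) || T < 1L)
    stop("config error: n and T must be positive integers", call. = FALSE)
  u_strength <- rep(as.numeric(u_strength), length.out = 2L)
  kc <- length(p_C)
  fill <- function(cf, defaults) {
    for (nm in names(defaults)) if (is.null(cf[[nm]])) cf[[nm]] <- defaults[[nm]]
    cf$C <- rep(as.numeric(cf$C %||% 0), length.out = kc)
    cf
  }
  coef_L <- fill(coef_L, list(intercept = 0, l_prev = 0, x_prev = 0, y_prev = 0, sigma = 1))
  coef_X <- fill(coef_X, list(intercept = 0, l = 0, x_prev = 0, y_prev = 0))
  coef_Y <- fill(coef_Y, list(intercept = 0, l = 0, x = 0, x_prev = 0, y_prev = 0,
                              xl = 0, sigma = 1))
  if (!discrete && (coef_L$sigma <= 0 || coef_Y$sigma <= 0))
    stop("config error: sigma_L and sigma_Y must be > 0 for the continuous variant", call. = FALSE)
  if (kc && (any(p_C < 0) || any(p_C > 1)))
    stop("config error: p_C entries must be probabilities", call. = FALSE)
  structure(list(n = n, T = T, p_C = p_C, coef_L = coef_L, coef_X = coef_X,
                 coef_Y = coef_Y, u_strength = u_strength, discrete = isTRUE(discrete),
                 y_bounds = y_bounds, keep_counterfactuals = isTRUE(keep_counterfactuals),
                 seed = as.integer(seed)),
            class = "ipsi_config")
}

#' A small fully discrete configuration for exact enumeration
#'
#' Two waves, one baseline binary, binary stress indicator with a linear
#' success probability, outcome with symmetric two-point noise. Used as the
#' enumeration test-bed; \code{u_loading} switches on a +/-1 latent
#' confounder with the given loading on both the exposure and the outcome.
#'
#' @param n cohort size.
#' @param T waves (enumeration supports up to 3).
#' @param u_loading latent confounder loading (0 = none).
#' @param seed integer seed.
#' @return An \code{ipsi_config} with \code{discrete = TRUE}.
#' @export
discrete_config <- function(n = 5000, T = 2, u_loading = 0, seed = 1L) {
  synthetic_config(
    n = n, T = T, p_C = c(base = 0.5),
    coef_L = list(intercept = 0.35, C = 0.2, l_prev = 0.1, x_prev = 0.15, y_prev = 0.02),
    coef_X = list(intercept = -0.2, C = 0.3, l = 0.4, x_prev = 0.8, y_prev = 0.1),
    coef_Y = list(intercept = 2, C = 0.2, l = 0.3, x = 0.4, x_prev = 0.2, y_prev = 0.1,
                  xl = 0, sigma = 0.5),
    u_strength = u_loading, discrete = TRUE, y_bounds = NULL, seed = seed)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sequential draw of one cohort. exposure_rule: NULL = natural logistic draw;
# a number delta = draw from the delta-shifted natural propensity (only valid
# without a latent confounder); a 0/1 vector of length T = fixed exposure path.
sim_cohort <- function(config, n, exposure_rule = NULL) {
  kc <- length(config$p_C)
  Cmat <- matrix(0, n, kc)
  if (kc) for (j in seq_len(kc)) Cmat[, j] <- stats::rbinom(n, 1L, config$p_C[j])
  colnames(Cmat) <- if (kc) (names(config$p_C) %||% paste0("c", seq_len(kc))) else NULL
  u <- numeric(n)
  if (any(config$u_strength != 0)) {
    u <- if (config$discrete) sign(stats::runif(n) - 0.5) else stats::rnorm(n)
    if (is.numeric(exposure_rule) && length(exposure_rule) == 1L)
      stop("intervened simulation is unavailable under a latent confounder; use enumeration",
           call. = FALSE)
  }
  cC <- function(cf) if (kc) drop(Cmat %*% cf$C) else 0
  L <- X <- Y <- PI <- matrix(0, n, config$T)
  l_prev <- x_prev <- y_prev <- numeric(n)
  for (t in seq_len(config$T)) {
    aL <- config$coef_L
    lp_L <- aL$intercept + cC(aL) +
      if (t > 1L) aL$l_prev * l_prev + aL$x_prev * x_prev + aL$y_prev * y_prev else 0
    # uniform-comparison draws keep the noise streams aligned across
    # counterfactual exposure paths (shared-noise potential outcomes)
    if (config$discrete) {
      if (any(lp_L < 0 | lp_L > 1))
        stop("config error: discrete L probability outside [0, 1] at wave ", t, call. = FALSE)
      L[, t] <- as.numeric(stats::runif(n) < lp_L)
    } else L[, t] <- lp_L + stats::rnorm(n, sd = aL$sigma)
    aX <- config$coef_X
    lp_X <- aX$intercept + cC(aX) + aX$l * L[, t] +
      (if (t > 1L) aX$x_prev * x_prev + aX$y_prev * y_prev else 0) +
      config$u_strength[1] * u
    PI[, t] <- stats::plogis(lp_X)
    pdraw <- PI[, t]
    if (is.numeric(exposure_rule) && length(exposure_rule) == 1L)
      pdraw <- shift_propensity(PI[, t], exposure_rule)
    ux <- stats::runif(n)
    X[, t] <- if (is.numeric(exposure_rule) && length(exposure_rule) == config$T)
      rep(exposure_rule[t], n) else as.numeric(ux < pdraw)
    aY <- config$coef_Y
    lp_Y <- aY$intercept + cC(aY) + aY$l * L[, t] + aY$x * X[, t] +
      aY$xl * X[, t] * L[, t] +
      (if (t > 1L) aY$x_prev * x_prev + aY$y_prev * y_prev else 0) +
      config$u_strength[2] * u
    if (config$discrete) {
      eps <- if (aY$sigma > 0) sign(stats::runif(n) - 0.5) * aY$sigma else 0
      Y[, t] <- lp_Y + eps
    } else {
      Y[, t] <- lp_Y + stats::rnorm(n, sd = aY$sigma)
      if (!is.null(config$y_bounds))
        Y[, t] <- pmin(pmax(Y[, t], config$y_bounds[1]), config$y_bounds[2])
    }
    l_prev <- L[, t]; x_prev <- X[, t]; y_prev <- Y[, t]
  }
  list(C = Cmat, L = L, X = X, Y = Y, PI = PI, U = u)
}

#' Generate a synthetic recurring-exposure panel
#'
#' @param config an \code{\link{synthetic_config}}.
#' @param seed optional override of \code{config$seed}; the same seed yields a
#'   bit-identical panel.
#' @return An \code{ipsi_panel} with columns \code{id}, the baseline block,
#'   and per wave \code{l_t}, \code{x_t}, \code{y_t}. The latent confounder
#'   (if any) is drawn but never returned. When
#'   \code{config$keep_counterfactuals} is set, the attribute
#'   \code{counterfactuals} holds, for every fixed exposure path, the
#'   shared-noise potential outcomes at each wave.
#' @export
generate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ipsi_config"))
  with_seed(seed, {
    sim <- sim_cohort(config, config$n)
    cf <- NULL
    if (config$keep_counterfactuals) {
      paths <- as.matrix(expand.grid(rep(list(0:1), config$T)))
      cf <- lapply(seq_len(nrow(paths)), function(i) {
        with_seed(seed, {   # identical noise stream => consistency by construction
          s2 <- sim_cohort(config, config$n, exposure_rule = paths[i, ])
          s2$Y
        })
      })
      names(cf) <- apply(paths, 1L, paste, collapse = "")
    }
    df <- data.frame(id = seq_len(config$n))
    if (ncol(sim$C)) df <- cbind(df, as.data.frame(sim$C))
    for (t in seq_len(config$T)) {
      df[[paste0("l_", t)]] <- sim$L[, t]
      df[[paste0("x_", t)]] <- sim$X[, t]
      df[[paste0("y_", t)]] <- sim$Y[, t]
    }
    schema <- panel_schema(id = "id", C = colnames(sim$C) %||% character(),
                           L = "l", X = "x", Y = "y", T = config$T)
    panel <- panel_dataset(df, schema)
    attr(panel, "counterfactuals") <- cf
    if (any(config$u_strength != 0)) attr(panel, "latent_u") <- sim$U  # debug only
    panel
  })
}

# Expand a path table: branch every row over `values` with row-wise
# probabilities `probs` (nrow x length(values)); multiplies both the natural
# and intervened cumulative probabilities unless `pint_probs` differs.
expand_paths <- function(tab, values, probs, pint_probs = probs) {
  m <- length(values)
  nr <- nrow(tab)
  idx <- rep(seq_len(nr), each = m)
  out <- tab[idx, , drop = FALSE]
  out$.val <- rep(values, nr)   # rows are repeated each = m, so values tile per block
  pv <- as.vector(t(probs))
  qv <- as.vector(t(pint_probs))
  out$pn <- out$pn * pv
  out$pint <- out$pint * qv
  rownames(out) <- NULL
  out
}

# Exact path enumeration of the IPSI mean for a discrete config, carrying a
# possible +/-1 latent confounder through the sum. The shifted draw
# probability at wave t is shift(pibar(h_t), delta) where pibar marginalizes
# the confounder over the *natural* law of (U, H_t).
enumerate_ipsice <- function(config, delta, outcome_time) {
  if (!config$discrete)
    stop("unsupported-method error: enumeration requires a discrete config", call. = FALSE)
  s <- outcome_time
  kc <- length(config$p_C)
  tab <- data.frame(pn = 1, pint = 1)
  if (any(config$u_strength != 0)) {
    tab <- expand_paths(tab, c(-1, 1), matrix(0.5, 1, 2)); names(tab)[names(tab) == ".val"] <- "u"
  } else tab$u <- 0
  for (j in seq_len(kc)) {
    tab <- expand_paths(tab, 0:1, cbind(1 - config$p_C[j], config$p_C[j])[rep(1, nrow(tab)), , drop = FALSE])
    names(tab)[names(tab) == ".val"] <- paste0(".c", j)
  }
  cC <- function(cf) {
    if (!kc) return(0)
    v <- 0
    for (j in seq_len(kc)) v <- v + cf$C[j] * tab[[paste0(".c", j)]]
    v
  }
  hist_cols <- function(t) {
    # observed history identifying h_t (everything except u and probabilities)
    cols <- c(if (kc) paste0(".c", seq_len(kc)),
              paste0("l", seq_len(t)),
              if (t > 1L) paste0("x", seq_len(t - 1L)),
              if (t > 1L) paste0("y", seq_len(t - 1L)))
    cols
  }
  for (t in seq_len(s)) {
    aL <- config$coef_L
    lp_L <- aL$intercept + cC(aL) +
      if (t > 1L) aL$l_prev * tab[[paste0("l", t - 1L)]] +
        aL$x_prev * tab[[paste0("x", t - 1L)]] +
        aL$y_prev * tab[[paste0("y", t - 1L)]] else 0
    lp_L <- rep(lp_L, length.out = nrow(tab))
    if (any(lp_L < 0 | lp_L > 1))
      stop("config error: discrete L probability outside [0, 1] at wave ", t, call. = FALSE)
    tab <- expand_paths(tab, 0:1, cbind(1 - lp_L, lp_L))
    names(tab)[names(tab) == ".val"] <- paste0("l", t)
    aX <- config$coef_X
    lp_X <- aX$intercept + cC(aX) + aX$l * tab[[paste0("l", t)]] +
      (if (t > 1L) aX$x_prev * tab[[paste0("x", t - 1L)]] +
         aX$y_prev * tab[[paste0("y", t - 1L)]] else 0) +
      config$u_strength[1] * tab$u
    pi_u <- stats::plogis(lp_X)
    key <- do.call(paste, c(tab[hist_cols(t)], sep = "\r"))
    num <- tapply(tab$pn * pi_u, key, sum)
    den <- tapply(tab$pn, key, sum)
    pibar <- (num / den)[key]
    q <- shift_propensity(as.numeric(pibar), delta)
    tab <- expand_paths(tab, 0:1, cbind(1 - pi_u, pi_u), cbind(1 - q, q))
    names(tab)[names(tab) == ".val"] <- paste0("x", t)
    aY <- config$coef_Y
    lp_Y <- aY$intercept + cC(aY) + aY$l * tab[[paste0("l", t)]] +
      aY$x * tab[[paste0("x", t)]] + aY$xl * tab[[paste0("x", t)]] * tab[[paste0("l", t)]] +
      (if (t > 1L) aY$x_prev * tab[[paste0("x", t - 1L)]] +
         aY$y_prev * tab[[paste0("y", t - 1L)]] else 0) +
      config$u_strength[2] * tab$u
    if (t == s) return(sum(tab$pint * lp_Y) / sum(tab$pint))
    if (aY$sigma > 0) {
      tab <- expand_paths(tab, c(-1, 1), matrix(0.5, nrow(tab), 2))
      tab[[paste0("y", t)]] <- lp_Y[rep(seq_along(lp_Y), each = 2)] + tab$.val * aY$sigma
      tab$.val <- NULL
    } else tab[[paste0("y", t)]] <- lp_Y
  }
}

#' Ground-truth IPSICE of a synthetic configuration
#'
#' The average potential outcome at \code{outcome_time} when every
#' individual's exposure odds are multiplied by \code{delta} at all waves.
#' \code{"enumerate"} evaluates the exact weighted path sum (discrete configs
#' only, carrying any latent confounder through the sum);
#' \code{"monte_carlo"} simulates a large cohort with exposures drawn from the
#' shifted propensity and reports the mean with its standard error (attribute
#' \code{"se"}); it requires \code{u_strength = 0}, since the natural
#' propensity marginal over a latent confounder is not available in closed
#' form.
#'
#' @param config an \code{ipsi_config}.
#' @param delta positive shift parameter.
#' @param outcome_time wave of the outcome.
#' @param method \code{"enumerate"} or \code{"monte_carlo"}.
#' @param mc_size Monte-Carlo cohort size (>= 1e5 recommended and enforced by
#'   default; lower with \code{relax = TRUE} for exploratory use).
#' @param seed seed for the Monte-Carlo draw.
#' @param relax allow mc_size below 1e5.
#' @return The true IPSICE (numeric scalar; Monte-Carlo carries an \code{se}
#'   attribute).
#' @export
true_ipsice <- function(config, delta, outcome_time,
                        method = c("enumerate", "monte_carlo"),
                        mc_size = 1e5, seed = config$seed, relax = FALSE) {
  stopifnot(inherits(config, "ipsi_config"))
  method <- match.arg(method)
  if (delta <= 0) stop("domain error: delta must be positive", call. = FALSE)
  if (outcome_time < 1L || outcome_time > config$T)
    stop("index error: outcome_time outside 1..T", call. = FALSE)
  if (method == "enumerate") {
    if (outcome_time > 3L) stop("enumerate supports outcome_time <= 3", call. = FALSE)
    return(enumerate_ipsice(config, delta, outcome_time))
  }
  if (mc_size < 1e5 && !relax)
    stop("monte_carlo requires mc_size >= 1e5 (or relax = TRUE)", call. = FALSE)
  with_seed(seed, {
    sim <- sim_cohort(config, as.integer(mc_size), exposure_rule = delta)
    y <- sim$Y[, outcome_time]
    structure(mean(y), se = stats::sd(y) / sqrt(length(y)))
  })
}
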