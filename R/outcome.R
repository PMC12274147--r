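#' Specification of the joint linear outcome system
#'
#' Declares one linear equation per time-varying covariate \code{L_t} and per
#' outcome \code{Y_t} (and, when needed, a linear-probability equation per
#' exposure \code{X_t}). The outcome equation at wave t has main effects for
#' the current exposure and the full history, plus two-way interactions
#' between every exposure instance \code{X_s, s <= t} and each history
#' variable excluding that exposure. The covariate equations have main
#' effects of everything preceding \code{L_t}. Cross-time equality
#' constraints and fixed exposure-outcome residual correlations (the
#' unmeasured-confounding sensitivity parameter rho) turn the fit into a
#' joint Gaussian maximum-likelihood problem; otherwise the recursive system
#' factorizes and per-equation least squares is exact ML.
#'
#' @param panel an \code{ipsi_panel} (or \code{ipsi_schema}).
#' @param ordering within-wave temporal ordering.
#' @param interactions include the exposure-by-history interaction products in
#'   the outcome equations (TRUE mirrors the applied analysis; FALSE gives
#'   main-effects-only outcome models).
#' @param equality_constraints named list of character vectors of
#'   \code{"response:term"} labels constrained equal across waves, e.g.
#'   \code{list(x_eff = c("y_1:x_1", "y_2:x_2", "y_3:x_3"))}.
#' @param fixed_residual_correlations data.frame with columns \code{x_wave},
#'   \code{y_wave}, \code{rho}: the residual correlation between exposure
#'   \code{X_s} and a causally downstream outcome \code{Y_t} (t >= s under
#'   exposure-first, t > s under outcome-first) held fixed at rho in (-1, 1).
#' @param include_exposure_equations add linear-probability equations for the
#'   exposures (forced on whenever fixed residual correlations are present).
#' @return An object of class \code{outcome_system_spec}.
#' @export
outcome_system_spec <- function(panel, ordering = "exposure_first",
                                interactions = TRUE,
                                equality_constraints = NULL,
                                fixed_residual_correlations = NULL,
                                include_exposure_equations = NULL) {
  s <- if (inherits(panel, "ipsi_schema")) panel else panel_schema_of(panel)
  ordering <- check_ordering(ordering)
  frc <- fixed_residual_correlations
  if (!is.null(frc)) {
    frc <- as.data.frame(frc)
    stopifnot(all(c("x_wave", "y_wave", "rho") %in% names(frc)))
    if (any(abs(frc$rho) >= 1))
      stop("every fixed residual correlation must lie strictly inside (-1, 1)", call. = FALSE)
    ok <- if (ordering == "exposure_first") frc$y_wave >= frc$x_wave else frc$y_wave > frc$x_wave
    if (!all(ok))
      stop("fixed residual correlations must pair an exposure with a causally downstream outcome",
           call. = FALSE)
    if (nrow(frc) == 0L) frc <- NULL
  }
  if (is.null(include_exposure_equations)) include_exposure_equations <- !is.null(frc)
  if (!is.null(frc) && !include_exposure_equations)
    stop("fixed residual correlations need the exposure equations in the system", call. = FALSE)

  blocks_before <- function(t) {   # all columns of waves < t, plus C
    cols <- s$C
    for (k in seq_len(t - 1L)) cols <- c(cols, s$L[[k]], s$X[k], s$Y[k])
    cols
  }
  eqs <- list()
  add_eq <- function(response, kind, wave, mains, pairs) {
    eqs[[length(eqs) + 1L]] <<- list(response = response, kind = kind, wave = wave,
                                     mains = mains, pairs = pairs)
  }
  for (t in seq_len(s$T)) {
    for (lc in s$L[[t]])   # one equation per covariate column in the wave block
      add_eq(lc, "L", t, blocks_before(t), matrix(character(), 0, 2))
    if (include_exposure_equations) {
      hx <- build_history(s, t, ordering)$columns
      add_eq(s$X[t], "X", t, hx, matrix(character(), 0, 2))
    }
    base <- c(blocks_before(t), s$L[[t]])
    xs <- if (ordering == "exposure_first") s$X[seq_len(t)] else s$X[seq_len(t - 1L)]
    mains <- unique(c(if (ordering == "exposure_first") s$X[t], base))
    pr <- matrix(character(), 0, 2)
    if (interactions && length(xs)) {
      pl <- list()
      for (xv in xs) {
        partners <- setdiff(union(base, xs), xv)
        for (p in partners) pl[[length(pl) + 1L]] <- sort(c(xv, p))
      }
      pr <- unique(do.call(rbind, pl))
    }
    add_eq(s$Y[t], "Y", t, mains, pr)
  }
  names(eqs) <- vapply(eqs, `[[`, "", "response")
  if (!is.null(equality_constraints)) {
    for (cs in equality_constraints) {
      eqn <- sub(":.*$", "", cs)
      if (!all(eqn %in% names(eqs)))
        stop("equality constraint references unknown equation(s): ",
             paste(setdiff(eqn, names(eqs)), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(schema = s, T = s$T, ordering = ordering,
                 interactions = isTRUE(interactions),
                 equations = eqs,
                 equality_constraints = equality_constraints,
                 fixed_residual_correlations = frc,
                 include_exposure_equations = include_exposure_equations),
            class = "outcome_system_spec")
}

# independent columns of a design (QR with pivoting), always keeping intercept
independent_columns <- function(D) {
  q <- qr(D)
  kept <- sort(q$pivot[seq_len(q$rank)])
  colnames(D)[kept]
}

eq_design <- function(panel, eq) {
  D <- build_design(panel, eq$mains, eq$pairs)
  kept <- drop_degenerate(D, quiet = TRUE)
  D <- D[, kept, drop = FALSE]
  ind <- independent_columns(D)
  if (length(ind) < ncol(D))
    message(sprintf("equation %s: dropped aliased column(s): %s", eq$response,
                    paste(setdiff(colnames(D), ind), collapse = ", ")))
  D[, ind, drop = FALSE]
}

#' Fit the outcome system
#'
#' Without equality constraints or fixed residual correlations the recursive
#' system factorizes equation-wise and per-equation least squares is the exact
#' Gaussian ML. With constraints or fixed correlations the joint conditional
#' Gaussian likelihood is maximized by alternating a generalized-least-squares
#' step for all coefficients (given the residual covariance) with a
#' residual-scale step (given the coefficients), which is monotone in the
#' likelihood. Exposure indicators enter the residual block as numeric
#' variables — a linear-probability approximation for binary exposures.
#'
#' @param panel an \code{ipsi_panel}.
#' @param spec an \code{\link{outcome_system_spec}}.
#' @param method \code{"auto"} (LS when exact, joint ML otherwise),
#'   \code{"per_equation_ls"} or \code{"joint_ml"}.
#' @param maxit,tol outer-iteration cap and relative log-likelihood tolerance
#'   of the joint fit.
#' @return An object of class \code{outcome_system_fit} with per-equation
#'   coefficients, residual sds (ML scale), the implied or fixed residual
#'   correlation matrix, the joint Gaussian log-likelihood, and per-column
#'   binary flags used by the g-formula simulator.
#' @export
fit_outcome_system <- function(panel, spec, method = c("auto", "per_equation_ls", "joint_ml"),
                               maxit = 500L, tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "outcome_system_spec"))
  n <- nrow(panel)
  eqs <- spec$equations
  k <- length(eqs)
  designs <- lapply(eqs, function(eq) eq_design(panel, eq))
  Ymat <- vapply(eqs, function(eq) as.numeric(panel[[eq$response]]), numeric(n))
  is_binary <- vapply(eqs, function(eq) all(panel[[eq$response]] %in% c(0, 1)), NA)

  ls_fit <- lapply(seq_len(k), function(j) {
    f <- stats::lm.fit(designs[[j]], Ymat[, j])
    sig <- sqrt(mean(f$residuals^2))
    list(coef = f$coefficients, resid = f$residuals, sigma = sig)
  })
  ls_ll <- sum(vapply(ls_fit, function(f)
    -n / 2 * (log(2 * pi * f$sigma^2) + 1), 0))

  needs_joint <- !is.null(spec$equality_constraints) ||
    !is.null(spec$fixed_residual_correlations)
  use_joint <- method == "joint_ml" || (method == "auto" && needs_joint)

  if (!use_joint) {
    E <- vapply(ls_fit, `[[`, numeric(n), "resid")
    R <- suppressWarnings(stats::cor(E))
    R[!is.finite(R)] <- 0; diag(R) <- 1
    return(structure(list(
      spec = spec, n = n,
      coefficients = stats::setNames(lapply(ls_fit, `[[`, "coef"), names(eqs)),
      residual_sds = stats::setNames(vapply(ls_fit, `[[`, 0, "sigma"), names(eqs)),
      residual_correlation = R, loglik = ls_ll,
      method = "per_equation_ls", converged = TRUE, iterations = 0L,
      is_binary = is_binary,
      equations = eqs), class = "outcome_system_fit"))
  }

  ## ---- joint Gaussian ML ---------------------------------------------------
  # fixed residual correlation structure
  R <- diag(k)
  if (!is.null(spec$fixed_residual_correlations)) {
    sc <- spec$schema
    for (i in seq_len(nrow(spec$fixed_residual_correlations))) {
      row <- spec$fixed_residual_correlations[i, ]
      a <- match(sc$X[row$x_wave], names(eqs))
      b <- match(sc$Y[row$y_wave], names(eqs))
      if (is.na(a) || is.na(b))
        stop("fixed correlation references a wave outside the system", call. = FALSE)
      R[a, b] <- R[b, a] <- row$rho
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      stop("constraint error: fixed residual correlations give a non-positive-definite residual block",
           call. = FALSE)
  }

  # parameter map with equality constraints: theta index per (equation, term)
  pmap <- vector("list", k)
  n_theta <- 0L
  labels <- character()
  for (j in seq_len(k)) {
    terms_j <- colnames(designs[[j]])
    pmap[[j]] <- integer(length(terms_j))
    for (m in seq_along(terms_j)) {
      n_theta <- n_theta + 1L
      pmap[[j]][m] <- n_theta
      labels[n_theta] <- paste0(names(eqs)[j], ":", terms_j[m])
    }
  }
  if (!is.null(spec$equality_constraints)) {
    for (cs in spec$equality_constraints) {
      ids <- match(cs, labels)
      if (anyNA(ids))
        stop("equality constraint references unknown coefficient(s): ",
             paste(cs[is.na(ids)], collapse = ", "), call. = FALSE)
      tgt <- ids[1]
      for (j in seq_len(k)) pmap[[j]][pmap[[j]] %in% ids[-1]] <- tgt
    }
    for (j in seq_len(k)) if (anyDuplicated(pmap[[j]]))
      stop("equality constraints joining two terms of the same equation are not supported",
           call. = FALSE)
    # compress indices
    used <- sort(unique(unlist(pmap)))
    relabel <- match(seq_len(n_theta), used)
    for (j in seq_len(k)) pmap[[j]] <- relabel[pmap[[j]]]
    labels <- labels[used]
    n_theta <- length(used)
  }

  # precomputed cross-products
  ZZ <- vector("list", k * k); dim(ZZ) <- c(k, k)
  Zy <- vector("list", k * k); dim(Zy) <- c(k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ZZ[[a, b]] <- crossprod(designs[[a]], designs[[b]])
    Zy[[a, b]] <- crossprod(designs[[a]], Ymat[, b])
  }

  theta <- numeric(n_theta); cnt <- numeric(n_theta)
  for (j in seq_len(k)) {
    theta[pmap[[j]]] <- theta[pmap[[j]]] + ls_fit[[j]]$coef
    cnt[pmap[[j]]] <- cnt[pmap[[j]]] + 1
  }
  theta <- theta / pmax(cnt, 1)
  sig <- vapply(ls_fit, `[[`, 0, "sigma")

  resid_mat <- function(theta) {
    E <- Ymat
    for (j in seq_len(k)) E[, j] <- E[, j] - drop(designs[[j]] %*% theta[pmap[[j]]])
    E
  }
  loglik_of <- function(E, sig) {
    Psi <- R * tcrossprod(sig)
    ch <- tryCatch(chol(Psi), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Pinv <- chol2inv(ch)
    -n * k / 2 * log(2 * pi) - n * sum(log(diag(ch))) - 0.5 * sum((E %*% Pinv) * E)
  }

  ll <- loglik_of(resid_mat(theta), sig)
  it <- 0L
  repeat {
    it <- it + 1L
    Psi <- R * tcrossprod(sig)
    W <- chol2inv(chol(Psi))
    A <- matrix(0, n_theta, n_theta)
    bvec <- numeric(n_theta)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (W[a, b] == 0) next
      ia <- pmap[[a]]; ib <- pmap[[b]]
      A[ia, ib] <- A[ia, ib] + W[a, b] * ZZ[[a, b]]
      bvec[ia] <- bvec[ia] + W[a, b] * Zy[[a, b]]
    }
    theta_new <- tryCatch(solve(A, bvec), error = function(e)
      stop("non-convergence: singular GLS system in joint ML", call. = FALSE))
    E <- resid_mat(theta_new)
    S <- crossprod(E) / n
    Rinv <- solve(R)
    # scale step: minimize sum(log sig) * n + n/2 * sum(Rinv * S / (sig sig'))
    obj_s <- function(ls) {
      s2 <- exp(ls)
      n * sum(ls) + n / 2 * sum(Rinv * (S / tcrossprod(s2)))
    }
    # gradient: d/dls_k [n ls_k + n/2 * sum_ab Rinv_ab S_ab exp(-ls_a - ls_b)]
    gr_s <- function(ls) {
      s2 <- exp(ls)
      M <- Rinv * (S / tcrossprod(s2))
      n - n * rowSums(M)
    }
    op <- stats::optim(log(sig), obj_s, gr_s, method = "BFGS",
                       control = list(maxit = 200, reltol = 1e-14))
    sig_new <- exp(op$par)
    ll_new <- loglik_of(E, sig_new)
    done <- is.finite(ll_new) && abs(ll_new - ll) < tol * (abs(ll) + 1)
    theta <- theta_new; sig <- sig_new; ll <- ll_new
    if (done || it >= maxit) break
  }
  if (!is.finite(ll) || it >= maxit)
    stop(sprintf("non-convergence of joint ML after %d iterations (loglik %.6g)", it, ll),
         call. = FALSE)

  coefs <- stats::setNames(lapply(seq_len(k), function(j) {
    cf <- theta[pmap[[j]]]
    names(cf) <- colnames(designs[[j]])
    cf
  }), names(eqs))
  structure(list(spec = spec, n = n, coefficients = coefs,
                 residual_sds = stats::setNames(sig, names(eqs)),
                 residual_correlation = R, loglik = ll,
                 method = "joint_ml", converged = TRUE, iterations = it,
                 is_binary = is_binary, equations = eqs,
                 theta_labels = labels),
            class = "outcome_system_fit")
}

#' @export
print.outcome_system_fit <- function(x, ...) {
  cat(sprintf("<outcome_system_fit> %d equations, n = %d, method = %s, loglik = %.3f\n",
              length(x$equations), x$n, x$method, x$loglik))
  invisible(x)
}

eq_index <- function(fit, kind, wave) {
  for (j in seq_along(fit$equations)) {
    eq <- fit$equations[[j]]
    if (eq$kind == kind && eq$wave == wave) return(j)
  }
  NA_integer_
}

linear_predictor <- function(fit, j, newdata) {
  eq <- fit$equations[[j]]
  cf <- fit$coefficients[[j]]
  D <- build_design(newdata, eq$mains, eq$pairs, keep = names(cf))
  drop(D %*% cf)
}

#' Model-based prediction of an outcome equation
#'
#' Evaluates the fitted linear predictor of the wave-\code{t} outcome
#' equation on new covariate rows. With
#' \code{condition_on_exposure_residual = TRUE} (and exposure equations in the
#' system) the prediction additionally conditions on the realized exposure
#' residuals through the fixed residual-covariance block; the default is the
#' marginal prediction.
#'
#' @param fit an \code{outcome_system_fit}.
#' @param t outcome wave.
#' @param newdata data.frame/matrix supplying every term of the equation.
#' @param condition_on_exposure_residual see description.
#' @return Numeric predictions.
#' @export
predict_outcome <- function(fit, t, newdata, condition_on_exposure_residual = FALSE) {
  j <- eq_index(fit, "Y", t)
  if (is.na(j)) stop("no outcome equation for wave ", t, call. = FALSE)
  mu <- linear_predictor(fit, j, newdata)
  if (!condition_on_exposure_residual) return(mu)
  xidx <- which(vapply(fit$equations, `[[`, "", "kind") == "X")
  xidx <- xidx[fit$residual_correlation[j, xidx] != 0]
  if (!length(xidx)) return(mu)
  ex <- vapply(xidx, function(jj)
    as.numeric(get_col(newdata, fit$equations[[jj]]$response)) -
      linear_predictor(fit, jj, newdata), numeric(length(mu)))
  Psi <- fit$residual_correlation * tcrossprod(fit$residual_sds)
  adj <- Psi[j, xidx, drop = FALSE] %*% solve(Psi[xidx, xidx, drop = FALSE], t(ex))
  mu + drop(adj)
}
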