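#' The incremental propensity score shift
#'
#' Maps a propensity \eqn{\pi} to the shifted propensity
#' \eqn{Q^\delta = \delta\pi / (1 + (\delta - 1)\pi)}, i.e. multiplies the
#' exposure odds by \eqn{\delta}. Vectorized; the boundaries 0 and 1 are
#' preserved for every \eqn{\delta}, which is why the intervention does not
#' require positivity.
#'
#' @param pi propensity value(s) in [0, 1].
#' @param delta positive odds multiplier.
#' @return Shifted propensity value(s).
#' @export
shift_propensity <- function(pi, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("domain error: delta must be a single positive number", call. = FALSE)
  if (any(pi < 0 | pi > 1, na.rm = TRUE))
    stop("domain error: pi must lie in [0, 1]", call. = FALSE)
  # delta*pi / (delta*pi + (1-pi)) == delta*pi / (1 + (delta-1)*pi),
  # written so the boundaries 0 and 1 are preserved exactly
  delta * pi / (delta * pi + (1 - pi))
}

#' Shift parameter implied by a pair of propensities
#'
#' The odds ratio \eqn{\delta = odds(q) / odds(\pi)}; the inverse of
#' \code{\link{shift_propensity}} in its second argument.
#'
#' @param q,pi propensities strictly inside (0, 1).
#' @return The implied positive shift parameter.
#' @export
implied_delta <- function(q, pi) {
  if (any(q <= 0 | q >= 1) || any(pi <= 0 | pi >= 1))
    stop("domain error: implied_delta needs propensities strictly inside (0, 1)", call. = FALSE)
  (q / (1 - q)) / (pi / (1 - pi))
}

#' Shift-parameter grids
#'
#' @param values strictly increasing positive values.
#' @return A numeric vector of class \code{delta_grid}.
#' @export
delta_grid <- function(values) {
  values <- as.numeric(values)
  if (any(values <= 0) || any(diff(values) <= 0))
    stop("delta grid must be strictly increasing and positive", call. = FALSE)
  structure(values, class = "delta_grid")
}

#' @rdname delta_grid
#' @details The default grid is \eqn{\{2^{-9}, 2^{-8}, \ldots, 2^9\}}: 19
#'   values, symmetric on the binary-log scale, containing 1.
#' @export
default_delta_grid <- function() delta_grid(2^(-9:9))

## ---- design machinery (shared by the propensity and outcome models) -------

get_col <- function(data, name) {
  if (is.data.frame(data)) {
    v <- data[[name]]
    if (is.null(v)) stop("design error: missing term '", name, "'", call. = FALSE)
    v
  } else {
    if (!name %in% colnames(data)) stop("design error: missing term '", name, "'", call. = FALSE)
    data[, name]
  }
}

# mains: character; pairs: 2-column character matrix of product terms.
# keep (optional): restrict construction to these already-known design columns
# (in construction order), avoiding work for dropped terms on the hot path.
build_design <- function(data, mains, pairs, keep = NULL) {
  if (!is.null(keep)) {
    mains <- mains[mains %in% keep]
    if (NROW(pairs)) {
      lab <- paste(pairs[, 1], pairs[, 2], sep = ":")
      pairs <- pairs[lab %in% keep, , drop = FALSE]
    }
  }
  is_df <- is.data.frame(data)
  n <- nrow(data)
  cn <- if (is_df) names(data) else colnames(data)
  need <- unique(c(mains, if (NROW(pairs)) as.vector(pairs)))
  idx <- match(need, cn)
  if (anyNA(idx))
    stop("design error: missing term(s): ", paste(need[is.na(idx)], collapse = ", "),
         call. = FALSE)
  cols <- vector("list", length(need))
  names(cols) <- need
  for (i in seq_along(need)) cols[[i]] <- if (is_df) data[[idx[i]]] else data[, idx[i]]
  k <- 1L + length(mains) + NROW(pairs)
  D <- matrix(1, n, k)
  nm <- character(k)
  nm[1] <- "(Intercept)"
  j <- 1L
  for (m in mains) { j <- j + 1L; D[, j] <- cols[[m]]; nm[j] <- m }
  if (NROW(pairs)) for (i in seq_len(nrow(pairs))) {
    j <- j + 1L
    D[, j] <- cols[[pairs[i, 1]]] * cols[[pairs[i, 2]]]
    nm[j] <- paste(pairs[i, 1], pairs[i, 2], sep = ":")
  }
  colnames(D) <- nm
  D
}

# All unordered pairs of the (sorted) history columns; the deterministic
# interaction rule of the propensity model.
pairwise_terms <- function(cols) {
  cols <- sort(cols)
  if (length(cols) < 2L) return(matrix(character(), 0, 2))
  t(utils::combn(cols, 2L))
}

# Drop exactly constant and exactly duplicated columns (keeping the earliest),
# returning kept column names. The intercept is always kept.
drop_degenerate <- function(D, quiet = FALSE) {
  keep <- rep(TRUE, ncol(D))
  const <- apply(D, 2L, function(v) all(v == v[1]))
  const[1] <- FALSE
  keep[const] <- FALSE
  idx <- which(keep)
  dup <- idx[duplicated(lapply(idx, function(j) D[, j]))]
  keep[dup] <- FALSE
  dropped <- colnames(D)[!keep]
  if (length(dropped) && !quiet)
    message("dropped degenerate design column(s): ", paste(dropped, collapse = ", "))
  colnames(D)[keep]
}

ridge_logistic <- function(D, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  # penalty on the standardized scale, intercept unpenalized
  sds <- apply(D, 2L, stats::sd)
  sds[1] <- 1
  sds[sds == 0] <- 1
  Ds <- sweep(D, 2L, sds, "/")
  p <- ncol(Ds)
  pen <- diag(rep(lambda, p)); pen[1, 1] <- 0
  beta <- rep(0, p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(maxit)) {
    eta <- drop(Ds %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- drop(crossprod(Ds, y - mu)) - 2 * pen %*% beta
    H <- crossprod(Ds * sqrt(w)) + 2 * pen
    step <- tryCatch(solve(H, g), error = function(e) solve(H + diag(1e-8, p), g))
    beta <- beta + drop(step)
    if (max(abs(g)) < tol) break
  }
  beta / sds
}

#' Fit the per-wave propensity model
#'
#' A maximum-likelihood logistic regression of \code{X_t} on main effects and
#' all pairwise interaction products of the history columns \code{H_t}
#' (deterministically: sorted columns, then all unordered pairs; constant or
#' duplicate columns are dropped with a log entry). On separation or
#' non-convergence the fit falls back to a small ridge penalty (1e-4 on the
#' standardized design) so that fitted propensities stay inside (0, 1) — the
#' intervention tolerates propensities near 0/1, so the fit must not fail
#' there.
#'
#' @param panel an \code{ipsi_panel}.
#' @param t wave index.
#' @param ordering within-wave temporal ordering.
#' @return An object of class \code{propensity_fit} with the coefficients,
#'   the ridge penalty actually used (0 if none), and per-individual fitted
#'   propensities \code{fitted_pi}.
#' @export
fit_propensity <- function(panel, t, ordering = "exposure_first") {
  s <- panel_schema_of(panel)
  h <- build_history(panel, t, ordering)
  y <- panel[[s$X[t]]]
  if (length(unique(y)) < 2L)
    stop(sprintf("degenerate-exposure error: X at wave %d is constant", t), call. = FALSE)
  mains <- sort(h$columns)
  pairs <- pairwise_terms(h$columns)
  D <- build_design(panel, mains, pairs)
  kept <- drop_degenerate(D)
  D <- D[, kept, drop = FALSE]
  sep <- FALSE
  fit <- withCallingHandlers(
    tryCatch(stats::glm.fit(D, y, family = stats::binomial()),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- if (!is.null(fit)) fit$coefficients else NA_real_
  need_ridge <- is.null(fit) || !fit$converged || anyNA(coefs) || sep ||
    max(abs(coefs), na.rm = TRUE) > 15
  regularization <- 0
  if (need_ridge) {
    regularization <- 1e-4
    message(sprintf("wave %d: separation or non-convergence detected; ridge fallback (lambda = %g)",
                    t, regularization))
    coefs <- ridge_logistic(D, y, lambda = regularization)
    names(coefs) <- colnames(D)
  }
  fitted_pi <- stats::plogis(drop(D %*% coefs))
  structure(list(t = t, ordering = h$ordering, h_columns = h$columns,
                 mains = mains, pairs = pairs, kept = kept,
                 coefficients = coefs, regularization = regularization,
                 fitted_pi = fitted_pi, separation = need_ridge),
            class = "propensity_fit")
}

#' Fit propensity models for every wave
#'
#' @inheritParams fit_propensity
#' @param waves wave indices (default all).
#' @return A list of \code{propensity_fit}, indexed by wave.
#' @export
fit_propensity_all <- function(panel, ordering = "exposure_first",
                               waves = seq_len(panel_schema_of(panel)$T)) {
  fits <- vector("list", max(waves))
  for (t in waves) fits[[t]] <- fit_propensity(panel, t, ordering)
  fits
}

#' Predict propensities for new (possibly simulated) rows
#'
#' @param object a \code{propensity_fit}.
#' @param newdata data.frame or named matrix holding every history column.
#' @param ... unused.
#' @return Fitted propensities in (0, 1).
#' @export
predict.propensity_fit <- function(object, newdata, ...) {
  D <- build_design(newdata, object$mains, object$pairs, keep = object$kept)
  stats::plogis(drop(D %*% object$coefficients))
}

#' Summaries of the shifted propensity distribution over a grid
#'
#' For each wave and each grid value of \eqn{\delta}: the mean shifted
#' propensity, the symmetric 80-percentile interval (10th and 90th
#' percentiles), and the fraction of individuals whose shifted propensity
#' exceeds 0.05 (extreme \eqn{\delta} can push nearly everyone to
#' (un)exposure; at very small \eqn{\delta} only a few percent may retain a
#' chance of exposure above 0.05).
#'
#' @param panel an \code{ipsi_panel}.
#' @param fits list of per-wave \code{propensity_fit} covering t = 1..T.
#' @param grid a \code{\link{delta_grid}}.
#' @return data.frame (t, delta, mean_q, q10, q90, frac_above_0.05).
#' @export
summarize_shifted <- function(panel, fits, grid = default_delta_grid()) {
  out <- list()
  for (t in seq_along(fits)) {
    if (is.null(fits[[t]])) next
    pi_t <- fits[[t]]$fitted_pi
    for (d in as.numeric(grid)) {
      q <- shift_propensity(pi_t, d)
      out[[length(out) + 1L]] <- data.frame(
        t = t, delta = d, mean_q = mean(q),
        q10 = unname(stats::quantile(q, 0.1)), q90 = unname(stats::quantile(q, 0.9)),
        frac_above_0.05 = mean(q > 0.05))
    }
  }
  do.call(rbind, out)
}

#' Propensity overlap diagnostics stratified by past exposure
#'
#' For each stratum of the exposure history \code{(X_1, ..., X_{t-1})} and
#' each current group \code{X_t = 0, 1}: the five-number summary of the
#' fitted propensities and the stratum's sample proportion, plus a flag when
#' the interquartile ranges of the two groups fail to overlap (or when a
#' group is empty — the pattern produced when past exposures perfectly
#' predict future exposure).
#'
#' @param panel an \code{ipsi_panel}.
#' @param fit the wave-\code{t} \code{propensity_fit}.
#' @param t wave index (>= 2).
#' @return data.frame with one row per (stratum, current-exposure group).
#' @export
overlap_diagnostics <- function(panel, fit, t) {
  if (t < 2L) stop("overlap diagnostics require t >= 2 (stratification by past exposure)", call. = FALSE)
  s <- panel_schema_of(panel)
  past <- panel[s$X[seq_len(t - 1L)]]
  stratum <- do.call(paste, c(lapply(seq_len(t - 1L), function(k)
    paste0("X", k, "=", past[[k]])), sep = ","))
  xt <- panel[[s$X[t]]]
  pi_t <- fit$fitted_pi
  out <- list()
  for (st in sort(unique(stratum))) {
    in_st <- stratum == st
    rows <- list()
    for (g in 0:1) {
      sel <- in_st & xt == g
      qs <- if (any(sel)) unname(stats::quantile(pi_t[sel], c(0, 0.25, 0.5, 0.75, 1)))
            else rep(NA_real_, 5)
      rows[[g + 1L]] <- data.frame(t = t, stratum = st, x_current = g,
                                   n = sum(sel), stratum_prop = mean(in_st),
                                   min = qs[1], q1 = qs[2], median = qs[3],
                                   q3 = qs[4], max = qs[5])
    }
    r0 <- rows[[1]]; r1 <- rows[[2]]
    overlap <- if (r0$n == 0 || r1$n == 0) FALSE else (r1$q1 <= r0$q3 && r0$q1 <= r1$q3)
    rows[[1]]$iqr_overlap <- rows[[2]]$iqr_overlap <- overlap
    out[[length(out) + 1L]] <- rbind(rows[[1]], rows[[2]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
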