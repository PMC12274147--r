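#' Within-wave temporal orderings
#'
#' Under \code{exposure_first} the exposure \code{X_t} causally precedes the
#' same-wave outcome \code{Y_t}, so the pre-exposure history at wave t is
#' \code{H_t = (C, L_1, X_1, Y_1, ..., L_{t-1}, X_{t-1}, Y_{t-1}, L_t)}.
#' Under \code{outcome_first} the same-wave outcome precedes the exposure and
#' \code{H_t = (C, L_1, Y_1, X_1, ..., L_t, Y_t)}.
#'
#' @name temporal_ordering
NULL

ORDERINGS <- c("exposure_first", "outcome_first")

check_ordering <- function(ordering) {
  match.arg(ordering, ORDERINGS)
}

#' History columns for a wave
#'
#' Returns the ordered column list constituting the pre-exposure history
#' \code{H_t} under the declared within-wave ordering (C block first, then
#' wave blocks in time order). No variable causally downstream of \code{X_t}
#' is ever included.
#'
#' @param panel an \code{ipsi_panel} (or an \code{ipsi_schema}).
#' @param t wave index, 1-based.
#' @param ordering \code{"exposure_first"} (default) or \code{"outcome_first"}.
#' @return An object of class \code{history_design}: a list with \code{t},
#'   \code{ordering} and the ordered \code{columns} of \code{H_t}.
#' @export
build_history <- function(panel, t, ordering = "exposure_first") {
  s <- if (inherits(panel, "ipsi_schema")) panel else panel_schema_of(panel)
  ordering <- check_ordering(ordering)
  t <- as.integer(t)
  if (is.na(t) || t < 1L || t > s$T)
    stop(sprintf("index error: wave t = %d outside 1..%d", t, s$T), call. = FALSE)
  cols <- s$C
  if (ordering == "exposure_first") {
    for (k in seq_len(t - 1L)) cols <- c(cols, s$L[[k]], s$X[k], s$Y[k])
    cols <- c(cols, s$L[[t]])
  } else {
    for (k in seq_len(t - 1L)) cols <- c(cols, s$L[[k]], s$Y[k], s$X[k])
    cols <- c(cols, s$L[[t]], s$Y[t])
  }
  structure(list(t = t, ordering = ordering, columns = cols),
            class = "history_design")
}

#' @export
print.history_design <- function(x, ...) {
  cat(sprintf("<history_design> H_%d (%s): %s\n", x$t, x$ordering,
              paste(x$columns, collapse = ", ")))
  invisible(x)
}
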