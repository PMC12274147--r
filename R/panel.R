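#' Declare the column roles of a recurring-exposure panel
#'
#' A panel holds, for each of \code{n} individuals, time-invariant covariates
#' \code{C} and, per wave \code{t = 1..T}, a time-varying covariate block
#' \code{L_t}, a binary exposure \code{X_t} and a numeric outcome \code{Y_t}.
#' Columns can be declared either by an explicit per-wave listing or by the
#' suffix convention \code{<base>_<t>} (e.g. \code{stress_1 .. stress_3}).
#'
#' @param id name of the individual identifier column, or \code{NULL}.
#' @param C character vector of time-invariant covariate columns.
#' @param L either a character vector of base names (suffix convention) or a
#'   list of length \code{T} with the per-wave covariate columns (explicit
#'   listing; the explicit form wins whenever a list is supplied).
#' @param X,Y either a single base name (suffix convention) or a length-
#'   \code{T} character vector of per-wave column names.
#' @param T number of waves (>= 1, 1-based and contiguous).
#' @return An object of class \code{ipsi_schema}.
#' @export
panel_schema <- function(id = "id", C = character(), L = "l", X = "x", Y = "y", T = 1L) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be a positive integer", call. = FALSE)
  expand <- function(v, what) {
    if (is.list(v)) {
      if (length(v) != T) stop(sprintf("explicit %s listing must have length T = %d", what, T), call. = FALSE)
      lapply(v, as.character)
    } else if (length(v) == T && T > 1L) {
      as.list(as.character(v))
    } else {
      lapply(seq_len(T), function(t) paste0(v, "_", t))
    }
  }
  Lc <- expand(L, "L")
  xy <- function(v, what) {
    if (length(v) == T && (T > 1L || grepl("_[0-9]+$", v[1]))) as.character(v)
    else if (length(v) == 1L) paste0(v, "_", seq_len(T))
    else stop(sprintf("%s must be a base name or a length-T vector", what), call. = FALSE)
  }
  out <- structure(list(id = id, C = as.character(C), L = Lc,
                        X = xy(X, "X"), Y = xy(Y, "Y"), T = T),
                   class = "ipsi_schema")
  all_cols <- unlist(c(out$C, out$L, out$X, out$Y))
  if (anyDuplicated(all_cols))
    stop("column names must be unique across the whole dataset: ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "), call. = FALSE)
  out
}

schema_columns <- function(schema) unlist(c(schema$C, schema$L, schema$X, schema$Y), use.names = FALSE)

#' Construct a validated panel dataset
#'
#' @param data a data.frame containing every column the schema declares.
#' @param schema an \code{\link{panel_schema}} object.
#' @param complete_cases drop rows with missing values among declared columns
#'   (the default and only missing-data policy; the dropped count is messaged).
#' @return A data.frame of class \code{ipsi_panel} carrying the schema as an
#'   attribute.
#' @export
panel_dataset <- function(data, schema, complete_cases = TRUE) {
  stopifnot(inherits(schema, "ipsi_schema"))
  data <- as.data.frame(data)
  declared <- schema_columns(schema)
  miss <- setdiff(c(if (!is.null(schema$id)) schema$id, declared), names(data))
  if (length(miss))
    stop("schema error: declared column(s) missing from data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (complete_cases) {
    keep <- stats::complete.cases(data[declared])
    if (any(!keep)) {
      message(sum(!keep), " row(s) with missing values among declared columns dropped (complete-case analysis)")
      data <- data[keep, , drop = FALSE]
      rownames(data) <- NULL
    }
  }
  for (xc in schema$X) {
    v <- data[[xc]]
    bad <- !(v %in% c(0, 1))
    if (any(bad))
      stop(sprintf("validation error: exposure column '%s' must be binary 0/1; offending value(s): %s",
                   xc, paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
  }
  for (cc in declared) {
    if (!is.numeric(data[[cc]]))
      stop(sprintf("type error: declared column '%s' is not numeric", cc), call. = FALSE)
  }
  structure(data, schema = schema, class = c("ipsi_panel", "data.frame"))
}

panel_schema_of <- function(panel) {
  s <- attr(panel, "schema")
  if (is.null(s)) stop("not an ipsi_panel: no schema attribute", call. = FALSE)
  s
}

#' @export
print.ipsi_panel <- function(x, ...) {
  s <- panel_schema_of(x)
  cat(sprintf("<ipsi_panel> n = %d individuals, T = %d waves\n", nrow(x), s$T))
  cat("  C:", if (length(s$C)) paste(s$C, collapse = ", ") else "(none)", "\n")
  cat("  waves:", paste(vapply(seq_len(s$T), function(t)
    sprintf("[%s | %s | %s]", paste(s$L[[t]], collapse = ","), s$X[t], s$Y[t]), ""),
    collapse = " "), "\n")
  invisible(x)
}

#' Read a delimited panel file
#'
#' Reads a CSV/TSV file with a header row, applies the schema and the
#' complete-case rule, and returns a validated \code{ipsi_panel}.
#'
#' @param path file path; the delimiter is taken from \code{sep}, defaulting
#'   to tab for \code{.tsv} files and comma otherwise.
#' @param schema a \code{\link{panel_schema}}, or a path to a JSON/YAML file
#'   declaring \code{id}, \code{C}, \code{L}, \code{X}, \code{Y}, \code{T}.
#' @param sep field separator override.
#' @return An \code{ipsi_panel}.
#' @export
load_panel <- function(path, schema, sep = NULL) {
  if (is.character(schema)) schema <- read_schema(schema)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  panel_dataset(raw, schema)
}

read_schema <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML schema files need the 'yaml' package; use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  L <- obj$L
  if (is.list(L)) L <- lapply(L, as.character)
  panel_schema(id = obj$id, C = obj$C %||% character(), L = L,
               X = obj$X, Y = obj$Y, T = obj$T)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a panel back to delimited text
#'
#' Numeric content round-trips exactly through \code{\link{load_panel}} for
#' clean input (full-precision printing).
#'
#' @param panel an \code{ipsi_panel}.
#' @param path output file path (.csv or .tsv).
#' @export
write_panel <- function(panel, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(panel)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean-center selected numeric columns
#'
#' Centering constants are retained in the \code{centers} attribute for
#' reporting; re-centering an already-centered column is a no-op up to
#' floating tolerance.
#'
#' @param panel an \code{ipsi_panel}.
#' @param columns character vector of numeric columns to center.
#' @return The panel with the named columns centered.
#' @export
center_covariates <- function(panel, columns) {
  s <- panel_schema_of(panel)
  centers <- attr(panel, "centers") %||% numeric()
  for (cc in columns) {
    if (is.null(panel[[cc]])) stop("unknown column: ", cc, call. = FALSE)
    if (!is.numeric(panel[[cc]])) stop("type error: column '", cc, "' is not numeric", call. = FALSE)
    m <- mean(panel[[cc]])
    panel[[cc]] <- panel[[cc]] - m
    prev <- if (cc %in% names(centers)) centers[[cc]] else 0
    centers[cc] <- prev + m
  }
  attr(panel, "centers") <- centers
  attr(panel, "schema") <- s
  class(panel) <- c("ipsi_panel", "data.frame")
  panel
}
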