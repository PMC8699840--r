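#' Read a censored series from a delimited file
#'
#' Expects a header with columns \code{y} and \code{delta}, optional covariate
#' columns \code{x1, x2, ...} and an optional nonparametric covariate column
#' \code{s} (defaulting to the row index scaled to \code{(0, 1]}). Rows are
#' sorted by \code{s}. Validation errors name the offending rows.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param column_map optional named list remapping the expected column names,
#'   e.g. \code{list(y = "response", delta = "status")}.
#' @return a \code{"censored_series"}.
#' @export
read_series <- function(path, sep = ",", column_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  nm <- function(key) {
    if (!is.null(column_map) && !is.null(column_map[[key]]))
      column_map[[key]] else key
  }
  for (key in c("y", "delta"))
    if (!nm(key) %in% names(df))
      stop(sprintf("missing required column '%s' in %s", nm(key), path))
  y <- df[[nm("y")]]
  if (!is.numeric(y)) stop("column 'y' is not numeric")
  if (any(is.na(y)))
    stop(sprintf("NaN/NA in 'y' at row(s) %s",
                 paste(which(is.na(y)), collapse = ", ")))
  delta <- df[[nm("delta")]]
  bad <- which(!(delta %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("'delta' must be 0/1; offending row(s): %s",
                 paste(bad, collapse = ", ")))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  X <- if (length(xcols)) as.matrix(df[xcols]) else NULL
  s <- if (nm("s") %in% names(df)) df[[nm("s")]] else seq_len(nrow(df)) / nrow(df)
  ord <- order(s)
  censored_series(Y = y[ord], delta = delta[ord],
                  X = if (is.null(X)) NULL else X[ord, , drop = FALSE],
                  s = s[ord])
}

#' Write a censored series to CSV
#'
#' Columns \code{t, y, delta, x1..xp, s}; the inverse of
#' \code{\link{read_series}} on the value columns.
#'
#' @param series a \code{"censored_series"}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "censored_series"))
  df <- data.frame(t = seq_len(series$n), y = series$Y, delta = series$delta)
  if (ncol(series$X) > 0) {
    Xd <- as.data.frame(series$X)
    names(Xd) <- paste0("x", seq_len(ncol(series$X)))
    df <- cbind(df, Xd)
  }
  df$s <- series$s
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build a lagged-covariate design from a response series
#'
#' Constructs the autoregressive partial-linear design in which lags of the
#' response serve as parametric covariates: \code{X} columns are
#' \code{y[t - l]} for each requested lag \code{l}, and the first
#' \code{max(lags)} rows are dropped consistently from the response,
#' indicators and nonparametric covariate.
#'
#' @param y response series.
#' @param lags positive integer lags.
#' @param delta,s optional indicator/covariate vectors trimmed alongside.
#' @return list with \code{X}, \code{y}, and trimmed \code{delta}, \code{s}.
#' @export
make_lagged_design <- function(y, lags, delta = NULL, s = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  lags <- as.integer(lags)
  if (any(lags <= 0)) stop("lags must be positive integers")
  L <- max(lags)
  if (L >= n) stop("largest lag must be smaller than the series length")
  keep <- (L + 1):n
  X <- vapply(lags, function(l) y[keep - l], numeric(length(keep)))
  X <- matrix(X, ncol = length(lags))
  colnames(X) <- paste0("lag", lags)
  out <- list(X = X, y = y[keep])
  if (!is.null(delta)) out$delta <- delta[keep]
  if (!is.null(s)) out$s <- s[keep]
  out
}
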