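#' Autoregressive error covariance for generalized least squares
#'
#' Estimates the AR coefficients of a residual series by Yule-Walker and
#' assembles the stationary error covariance \code{Sigma} and its inverse
#' \code{V}. For order 1, \code{Sigma = sigma_u^2 / (1 - rho^2) * R} with
#' \code{R[t, j] = rho^|t - j|}, and \code{V} is the exact tridiagonal inverse;
#' higher orders use the Yule-Walker autocovariances and a dense inverse.
#'
#' @param residuals numeric residual series.
#' @param n dimension of the covariance to build (defaults to the residual
#'   length).
#' @param order AR order (default 1).
#' @return An object of class \code{"ar_covariance"}: list with \code{rho},
#'   \code{sigma_u2}, \code{Sigma}, \code{V}, \code{order}, \code{degenerate}.
#' @export
estimate_ar_covariance <- function(residuals, n = length(residuals),
                                   order = 1L) {
  residuals <- as.numeric(residuals)
  order <- as.integer(order)
  if (length(residuals) < order + 2L)
    stop("need at least order + 2 residuals")
  if (stats::sd(residuals) == 0 || !is.finite(stats::sd(residuals))) {
    return(ar_covariance(rho = rep(0, order), sigma_u2 = 0, n = n,
                         degenerate = TRUE))
  }
  fit <- stats::ar.yw(residuals, aic = FALSE, order.max = order,
                      demean = TRUE)
  rho <- as.numeric(fit$ar)
  if (order == 1L) rho <- max(min(rho, 0.99), -0.99)
  sigma_u2 <- as.numeric(fit$var.pred)
  ar_covariance(rho = rho, sigma_u2 = sigma_u2, n = n)
}

#' Assemble an AR error covariance from known parameters
#'
#' @param rho AR coefficient vector (length = order); all zero gives
#'   \code{Sigma = sigma_u2 * I}.
#' @param sigma_u2 innovation variance.
#' @param n matrix dimension.
#' @param degenerate flag set when the residuals carried no information.
#' @return An \code{"ar_covariance"} object (see
#'   \code{\link{estimate_ar_covariance}}).
#' @export
ar_covariance <- function(rho, sigma_u2, n, degenerate = FALSE) {
  rho <- as.numeric(rho)
  order <- length(rho)
  s2 <- if (sigma_u2 > 0) sigma_u2 else 1  # degenerate: fall back to identity scale
  if (all(rho == 0)) {
    Sigma <- diag(s2, n)
    V <- diag(1 / s2, n)
  } else if (order == 1L) {
    r <- rho
    Sigma <- s2 / (1 - r^2) * stats::toeplitz(r^(0:(n - 1)))
    # exact tridiagonal inverse of the AR(1) Toeplitz covariance
    V <- diag(c(1, rep(1 + r^2, n - 2), 1), n)
    V[cbind(1:(n - 1), 2:n)] <- -r
    V[cbind(2:n, 1:(n - 1))] <- -r
    V <- V / s2
  } else {
    acf_th <- stats::ARMAacf(ar = rho, lag.max = n - 1)
    gamma0 <- s2 / (1 - sum(rho * acf_th[2:(order + 1)]))
    Sigma <- gamma0 * stats::toeplitz(as.numeric(acf_th))
    V <- chol2inv(chol(Sigma))
  }
  structure(list(rho = rho, sigma_u2 = sigma_u2, Sigma = Sigma, V = V,
                 order = order, n = n, degenerate = degenerate),
            class = "ar_covariance")
}

#' @export
print.ar_covariance <- function(x, ...) {
  cat(sprintf("AR(%d) error covariance: rho = %s, sigma_u^2 = %.4g%s\n",
              x$order, paste(sprintf("%.3f", x$rho), collapse = ", "),
              x$sigma_u2, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Naive autoregressive baseline fit
#'
#' Conditional least-squares AR(order) fit (regression of the series on its
#' own lags with an intercept), used as the naive comparator for the spline
#' estimators. One-step-ahead fitted values are returned for the full series;
#' the first \code{order} values, which have no complete lag history, are set
#' to the sample mean.
#'
#' @param Y response series (typically the synthetic responses).
#' @param order AR order.
#' @return list with \code{coefficients} (intercept first), \code{fitted},
#'   \code{residuals}, \code{order}.
#' @export
fit_ar_baseline <- function(Y, order = 1L) {
  Y <- as.numeric(Y)
  n <- length(Y)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be at least 1")
  if (order >= n - 1L) stop("'order' too large for the series length")
  lags <- sapply(seq_len(order), function(l) Y[(order + 1 - l):(n - l)])
  lags <- matrix(lags, ncol = order)
  yy <- Y[(order + 1):n]
  fit <- stats::lm.fit(cbind(1, lags), yy)
  fitted <- c(rep(mean(Y), order), fit$fitted.values)
  list(coefficients = as.numeric(fit$coefficients), fitted = fitted,
       residuals = Y - fitted, order = order)
}
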