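#' Mean absolute percentage error on the synthetic scale
#'
#' Mean of \code{|y - y_fit| / y} over the indices where the synthetic
#' response is nonzero; censored observations map to exactly zero under the
#' synthetic transform and are excluded (the only finite reading of the
#' percentage denominator). The number of observations used is attached as
#' attribute \code{"n_used"}.
#'
#' @param y_true synthetic responses.
#' @param y_fit fitted values.
#' @return numeric MAPE with attribute \code{"n_used"}.
#' @export
mape <- function(y_true, y_fit) {
  y_true <- as.numeric(y_true); y_fit <- as.numeric(y_fit)
  stopifnot(length(y_true) == length(y_fit))
  use <- y_true != 0
  if (!any(use)) stop("all denominators are zero: MAPE undefined")
  out <- mean(abs(y_true[use] - y_fit[use]) / abs(y_true[use]))
  attr(out, "n_used") <- sum(use)
  out
}

#' Median absolute error
#'
#' @param y_true,y_fit numeric vectors of equal length.
#' @return median of \code{|y_true - y_fit|}.
#' @export
medae <- function(y_true, y_fit) {
  y_true <- as.numeric(y_true); y_fit <- as.numeric(y_fit)
  stopifnot(length(y_true) == length(y_fit))
  if (length(y_true) == 0) stop("empty input")
  stats::median(abs(y_true - y_fit))
}

#' Generalized mean squared error
#'
#' Quadratic-form residual criterion \code{e' M e / n} with \code{e = y_true -
#' y_fit} and a symmetric positive semidefinite weight \code{M} standing in
#' for the second-moment matrix of the responses; \code{M = I} reduces it to
#' the ordinary mean squared residual. Normalization by \code{n} keeps values
#' comparable across sample sizes.
#'
#' @param y_true,y_fit numeric vectors of equal length.
#' @param weight \code{n x n} symmetric PSD matrix, or \code{NULL} for the
#'   identity.
#' @return numeric GMSE value.
#' @export
gmse <- function(y_true, y_fit, weight = NULL) {
  y_true <- as.numeric(y_true); y_fit <- as.numeric(y_fit)
  stopifnot(length(y_true) == length(y_fit))
  n <- length(y_true)
  e <- y_true - y_fit
  if (is.null(weight)) return(sum(e^2) / n)
  weight <- as.matrix(weight)
  stopifnot(nrow(weight) == n, ncol(weight) == n)
  if (max(abs(weight - t(weight))) > 1e-8 * max(1, max(abs(weight))))
    stop("'weight' must be symmetric")
  ev_min <- min(eigen(weight, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(weight))))
    stop("'weight' must be positive semidefinite")
  as.numeric(crossprod(e, weight %*% e)) / n
}

#' Second-moment plug-in weight for the generalized MSE
#'
#' Builds \code{Sigma-hat + mu-hat mu-hat'}, the fitted second-moment matrix
#' of the responses, from a semiparametric fit carrying an AR error
#' covariance; the default weight used when comparing whole-model fits.
#'
#' @param fit a \code{"semiparametric_fit"} with an \code{$ar} component.
#' @return \code{n x n} symmetric PSD matrix.
#' @export
gmse_weight <- function(fit) {
  stopifnot(inherits(fit, "semiparametric_fit"), !is.null(fit$ar))
  fit$ar$Sigma + tcrossprod(fit$mu_hat)
}

#' Ratio of generalized MSEs
#'
#' \code{gmse_as / gmse_bs}; values below one favor the adaptive-ridge spline.
#'
#' @param gmse_as,gmse_bs positive GMSE values.
#' @return numeric ratio.
#' @export
rgmse <- function(gmse_as, gmse_bs) {
  if (gmse_bs == 0) stop("zero denominator in RGMSE")
  gmse_as / gmse_bs
}

#' Root mean squared error of the smooth-component estimate
#'
#' @param f_true true smooth values on the observation grid.
#' @param f_hat estimated smooth values.
#' @return \code{sqrt(mean((f_true - f_hat)^2))}.
#' @export
rmse_f <- function(f_true, f_hat) {
  f_true <- as.numeric(f_true); f_hat <- as.numeric(f_hat)
  stopifnot(length(f_true) == length(f_hat))
  if (length(f_true) == 0) stop("empty input")
  sqrt(mean((f_true - f_hat)^2))
}

#' Closed-form bias and covariance diagnostics of a fit
#'
#' Evaluates the closed-form bias and variance-covariance expressions of the
#' parametric and spline coefficient estimators for a given fit, with the
#' model variance replaced by its estimate. The bias expressions are linear in
#' the true smooth component and require \code{f_true}; without it only the
#' covariance matrices are returned. The spline-coefficient reference is the
#' unpenalized basis least-squares projection of \code{f_true}.
#'
#' @param fit a \code{"semiparametric_fit"} carrying its basis, penalty and
#'   (optionally) \code{$ar}.
#' @param f_true optional true smooth values on the observation grid.
#' @return list with \code{cov_beta}, \code{cov_alpha}, \code{sigma2_hat} and,
#'   when \code{f_true} is given, \code{bias_beta} and \code{bias_alpha}.
#' @export
beta_diagnostics <- function(fit, f_true = NULL) {
  stopifnot(inherits(fit, "semiparametric_fit"))
  B <- fit$basis; D <- fit$D
  if (is.null(B) || is.null(D)) stop("fit is missing its design matrices")
  n <- fit$n
  V <- if (!is.null(fit$ar)) fit$ar$V else diag(1, n)
  X <- fit$X
  if (is.null(X) && fit$p > 0) stop("fit is missing the parametric design")
  W <- if (fit$method == "AS") diag(fit$weights, length(fit$weights))
       else diag(1, nrow(D))
  G <- crossprod(B, V %*% B) + fit$lambda * crossprod(D, W %*% D)
  Gi <- chol2inv(chol(G))
  BtV <- crossprod(B, V)
  M <- B %*% Gi %*% BtV
  s2 <- fit$sigma2_hat
  cov_alpha <- s2 * (1 / n) * Gi %*% crossprod(B, V %*% B) %*% Gi
  out <- list(sigma2_hat = s2, cov_alpha = cov_alpha)
  if (fit$p > 0) {
    A <- crossprod(X, V) %*% M          # X'V M  =  A of the closed forms
    XtVmA <- crossprod(X, V) - A        # X'V - A = X'V(I - M)
    Fm <- XtVmA %*% X
    Fi <- solve(Fm)
    out$cov_beta <- s2 * Fi %*% Fm %*% Fi
    if (!is.null(f_true)) {
      f_true <- as.numeric(f_true)
      out$bias_beta <- as.numeric(Fi %*% (XtVmA %*% f_true))
      Ef <- Gi %*% (BtV %*% (f_true - X %*% out$bias_beta))
      alpha_ref <- qr.coef(qr(B), f_true)
      out$bias_alpha <- as.numeric(Ef) - as.numeric(alpha_ref)
    }
  } else if (!is.null(f_true)) {
    f_true <- as.numeric(f_true)
    Ef <- Gi %*% (BtV %*% f_true)
    alpha_ref <- qr.coef(qr(B), f_true)
    out$bias_alpha <- as.numeric(Ef) - as.numeric(alpha_ref)
  }
  out
}
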