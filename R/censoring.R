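#' Construct a censored time-series object
#'
#' Bundles the observed response \code{Y = min(Z, C)}, the censoring indicator
#' \code{delta} (1 = uncensored), the parametric covariates \code{X} and the
#' nonparametric covariate \code{s} into a validated object. When the series
#' comes from the simulator, the latent response \code{Z}, censoring variable
#' \code{C}, true smooth \code{f} and true coefficients may be attached for
#' scoring; estimation never touches them.
#'
#' @param Y observed responses.
#' @param delta 0/1 censoring indicators (1 = uncensored).
#' @param X numeric matrix of parametric covariates (may have zero columns).
#' @param s nonparametric covariate, strictly increasing; defaults to the
#'   scaled time index \code{(1:n)/n}.
#' @param Z,C,f_true,beta_true optional simulation truth, stored but unused by
#'   the estimators.
#' @return An object of class \code{"censored_series"}.
#' @export
censored_series <- function(Y, delta, X = NULL, s = NULL,
                            Z = NULL, C = NULL, f_true = NULL,
                            beta_true = NULL) {
  Y <- as.numeric(Y)
  n <- length(Y)
  if (n < 1L) stop("empty series")
  if (any(!is.finite(Y))) stop("'Y' contains non-finite values")
  delta <- as.numeric(delta)
  if (length(delta) != n || !all(delta %in% c(0, 1)))
    stop("'delta' must be a 0/1 vector of the same length as 'Y'")
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("'X' must have one row per observation")
  storage.mode(X) <- "double"
  if (is.null(s)) s <- seq_len(n) / n
  s <- as.numeric(s)
  if (length(s) != n) stop("'s' must have the same length as 'Y'")
  if (n > 1L && any(diff(s) <= 0)) stop("'s' must be strictly increasing")
  if (!is.null(Z) && !is.null(C)) {
    if (any(abs(Y - pmin(Z, C)) > 1e-8))
      stop("inconsistent truth: Y != min(Z, C)")
    if (any(delta != as.numeric(Z <= C)))
      stop("inconsistent truth: delta != [Z <= C]")
  }
  structure(list(Y = Y, delta = delta, X = X, s = s, n = n,
                 Z = Z, C = C, f_true = f_true, beta_true = beta_true),
            class = "censored_series")
}

#' @export
print.censored_series <- function(x, ...) {
  cat(sprintf(
    "censored time series: n = %d, p = %d covariates, %.1f%% censored\n",
    x$n, ncol(x$X), 100 * mean(x$delta == 0)))
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimate of \code{1 - G(y)}, the survival function of the
#' censoring variable, computed with the roles of events and censorings
#' reversed: jumps occur only at censored observations. Sorted order statistics
#' contribute factors \code{(n - t) / (n - t + 1)} at censored ranks; at tied
#' response values, uncensored records are ranked before censored ones, which
#' makes the ranking unique.
#'
#' @param Y observed responses.
#' @param delta 0/1 censoring indicators (1 = uncensored).
#' @return An object of class \code{"km_censoring"} with the sorted support,
#'   the right-continuous survival values \code{1 - G} on the support, and the
#'   left-limit values \code{1 - G(y-)} used by the synthetic transform.
#' @export
km_censoring_survival <- function(Y, delta) {
  Y <- as.numeric(Y); delta <- as.numeric(delta)
  n <- length(Y)
  if (n < 1L) stop("empty input")
  if (length(delta) != n || !all(delta %in% c(0, 1)))
    stop("'delta' must be a 0/1 vector matching 'Y'")
  ord <- order(Y, -delta)           # uncensored before censored at ties
  Ys <- Y[ord]; ds <- delta[ord]
  t_idx <- seq_len(n)
  fac <- ifelse(ds == 0, (n - t_idx) / (n - t_idx + 1), 1)
  surv <- cumprod(fac)              # 1 - G at Y_(t), right-continuous
  # left limit at each sorted point: product over strictly smaller values
  first_at_value <- match(Ys, Ys)   # index of first occurrence of each value
  surv_left <- c(1, surv)[first_at_value]
  structure(list(support = Ys, delta_sorted = ds, survival = surv,
                 survival_left = surv_left, order = ord, n = n),
            class = "km_censoring")
}

#' @export
print.km_censoring <- function(x, ...) {
  cat(sprintf("Kaplan-Meier censoring-survival estimate: n = %d, %d jumps\n",
              x$n, sum(x$delta_sorted == 0)))
  invisible(x)
}

#' Evaluate the censoring survival estimate
#'
#' Step-function evaluation of \code{1 - G(y)} (right-continuous) or its left
#' limit \code{1 - G(y-)} at arbitrary points.
#'
#' @param km a \code{"km_censoring"} object.
#' @param y evaluation points.
#' @param left if \code{TRUE}, return the left limit.
#' @return numeric vector of survival values in \code{[0, 1]}.
#' @export
km_survival_at <- function(km, y, left = FALSE) {
  stopifnot(inherits(km, "km_censoring"))
  sup <- km$support
  if (left) {
    idx <- findInterval(y, sup, left.open = TRUE)  # count of support < y
  } else {
    idx <- findInterval(y, sup)                    # count of support <= y
  }
  c(1, km$survival)[idx + 1L]
}

#' Kaplan-Meier synthetic-data transformation
#'
#' Replaces the observed responses by \code{YG_t = delta_t * Y_t /
#' max(1 - G(Y_t-), floor)}, where \code{1 - G(.-)} is the left limit of the
#' censoring-survival estimate. Censored observations map to exactly zero;
#' uncensored ones are inflated so that the transformed series has (to KM
#' accuracy) the same conditional mean as the latent uncensored response.
#'
#' @param series a \code{"censored_series"}.
#' @param km optional precomputed \code{"km_censoring"} for the same data;
#'   computed if missing.
#' @param floor lower bound applied to the denominator, guarding uncensored
#'   ties at the sample maximum.
#' @return An object of class \code{"synthetic_series"}: list with \code{YG},
#'   \code{km}, \code{source}, and \code{floor_hits} (how often the floor was
#'   active).
#' @export
synthetic_transform <- function(series, km = NULL, floor = 1e-8) {
  stopifnot(inherits(series, "censored_series"))
  if (is.null(km)) km <- km_censoring_survival(series$Y, series$delta)
  stopifnot(inherits(km, "km_censoring"))
  denom <- km_survival_at(km, series$Y, left = TRUE)
  hits <- sum(series$delta == 1 & denom < floor)
  denom <- pmax(denom, floor)
  YG <- series$delta * series$Y / denom
  structure(list(YG = YG, km = km, source = series, floor_hits = hits),
            class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat(sprintf(
    "synthetic responses: n = %d, %d zeros at censored points, mean %.3f\n",
    length(x$YG), sum(x$source$delta == 0), mean(x$YG)))
  invisible(x)
}

#' Generate a right-censoring mechanism for a latent series
#'
#' Draws per-observation censoring statuses \code{delta ~ Bernoulli(1 - CL)}.
#' For observations marked censored, a detection limit \code{C_t} is drawn from
#' \code{Normal(mean(Z), sd(Z))} repeatedly until \code{C_t < Z_t} (rejection
#' sampling with a cap, after which \code{C_t = Z_t - |Normal(0, sd(Z))|}
#' guarantees termination); for uncensored observations \code{C_t = Z_t}. The
#' observed response is \code{Y_t = min(Z_t, C_t)}.
#'
#' @param Z latent uncensored responses.
#' @param CL target censoring level in \code{[0, 1)}.
#' @param seed optional integer seed; if \code{NULL} the current RNG state is
#'   used.
#' @param max_redraw rejection-sampling cap per observation.
#' @return list with components \code{Y}, \code{delta}, \code{C}.
#' @export
generate_censoring <- function(Z, CL, seed = NULL, max_redraw = 10000L) {
  Z <- as.numeric(Z)
  if (any(!is.finite(Z))) stop("'Z' must be finite")
  if (!is.numeric(CL) || CL < 0 || CL >= 1)
    stop("'CL' must lie in [0, 1); an all-censored series is unestimable")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(Z)
  delta <- stats::rbinom(n, 1L, 1 - CL)
  mu_z <- mean(Z); sd_z <- stats::sd(Z)
  if (!is.finite(sd_z) || sd_z == 0) sd_z <- max(abs(mu_z), 1) * 1e-8
  C <- Z
  for (t in which(delta == 0)) {
    ok <- FALSE
    for (i in seq_len(max_redraw)) {
      ct <- stats::rnorm(1L, mu_z, sd_z)
      if (ct < Z[t]) { C[t] <- ct; ok <- TRUE; break }
    }
    if (!ok) C[t] <- Z[t] - abs(stats::rnorm(1L, 0, sd_z))
  }
  Y <- pmin(Z, C)
  list(Y = Y, delta = delta, C = C)
}
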