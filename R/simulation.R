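#' Seasonal true smooth function of the simulation design
#'
#' Builds the smooth component used by the data generator: five identical
#' seasonal pieces, each \code{S(s) = s * sin(s)^2} evaluated on the
#' within-block grid \code{s_i = (i - 0.5) / (n / 5)}, \code{i = 1, ...,
#' n / 5}, concatenated over the blocks (the last block is truncated when
#' \code{n} is not a multiple of five).
#'
#' @param n series length (at least 5).
#' @return numeric vector of length \code{n}.
#' @export
true_function <- function(n) {
  n <- as.integer(n)
  if (n < 5L) stop("'n' must be at least 5")
  L <- ceiling(n / 5)
  si <- (seq_len(L) - 0.5) / L
  block <- si * sin(si)^2
  rep(block, times = 5L)[seq_len(n)]
}

#' Simulation configuration
#'
#' Collects the data-generating parameters of the censored seasonal design
#' (partial-linear model with three Gaussian covariates, seasonal smooth,
#' AR(1) errors, Bernoulli censoring statuses) together with the estimator
#' controls, and validates them.
#'
#' @param n series length.
#' @param CL censoring level in \code{[0, 1)}.
#' @param reps number of Monte-Carlo replications.
#' @param seed integer master seed; replication seeds are derived from it.
#' @param beta true parametric coefficients.
#' @param rho AR(1) coefficient of the errors.
#' @param x_mean,x_sd mean and sd of the covariate distribution.
#' @param u_sd innovation sd of the error process.
#' @param methods subset of \code{c("AS", "BS", "AR")} to fit.
#' @param ar_baseline_order order of the naive AR comparator.
#' @param q,d,k,lambda_grid,gamma,tol,max_iter,ar_order,outer_tol,outer_max
#'   estimator controls forwarded to \code{\link{fit_semiparametric}}.
#' @return list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n = 50L, CL = 0.20, reps = 1000L, seed = 1L,
                              beta = c(3, 0.5, -1), rho = 0.5,
                              x_mean = 5, x_sd = 1, u_sd = 1,
                              methods = c("AS", "BS", "AR"),
                              ar_baseline_order = 1L,
                              q = 3L, d = 2L, k = NULL, lambda_grid = NULL,
                              gamma = 1e-5, tol = 1e-4, max_iter = 100L,
                              ar_order = 1L, outer_tol = 1e-3,
                              outer_max = 10L) {
  stopifnot(n >= 10L, reps >= 1L, CL >= 0, CL < 1, abs(rho) < 1,
            all(methods %in% c("AS", "BS", "AR")), length(methods) >= 1)
  structure(list(n = as.integer(n), CL = CL, reps = as.integer(reps),
                 seed = as.integer(seed), beta = beta, rho = rho,
                 x_mean = x_mean, x_sd = x_sd, u_sd = u_sd,
                 methods = methods,
                 ar_baseline_order = as.integer(ar_baseline_order),
                 q = q, d = d, k = k, lambda_grid = lambda_grid,
                 gamma = gamma, tol = tol, max_iter = max_iter,
                 ar_order = ar_order, outer_tol = outer_tol,
                 outer_max = outer_max),
            class = "simulation_config")
}

#' Generate one censored dataset from the simulation design
#'
#' Draws the covariates \code{X ~ Normal(x_mean, x_sd^2)} (i.i.d., \code{n x
#' 3}), AR(1) errors started from their stationary distribution with a
#' 100-step burn-in, forms the latent response \code{Z = X beta + f + eps}
#' with the seasonal smooth of \code{\link{true_function}}, and censors it
#' with \code{\link{generate_censoring}}. The nonparametric covariate handed
#' to the estimators is the scaled time index \code{(1:n) / n}.
#'
#' @param config a \code{"simulation_config"}.
#' @param rep_seed integer seed for this replication.
#' @return a \code{"censored_series"} carrying the held-out truth
#'   (\code{Z}, \code{C}, \code{f_true}, \code{beta_true}).
#' @export
generate_dataset <- function(config, rep_seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(rep_seed))
  n <- config$n
  p <- length(config$beta)
  X <- matrix(stats::rnorm(n * p, config$x_mean, config$x_sd), n, p)
  burn <- 100L
  u <- stats::rnorm(n + burn, 0, config$u_sd)
  eps <- numeric(n + burn)
  eps[1] <- stats::rnorm(1, 0, config$u_sd / sqrt(1 - config$rho^2))
  for (t in 2:(n + burn)) eps[t] <- config$rho * eps[t - 1] + u[t]
  eps <- eps[(burn + 1):(burn + n)]
  f <- true_function(n)
  Z <- as.numeric(X %*% config$beta) + f + eps
  cens <- generate_censoring(Z, config$CL, seed = NULL)
  censored_series(Y = cens$Y, delta = cens$delta, X = X, s = seq_len(n) / n,
                  Z = Z, C = cens$C, f_true = f, beta_true = config$beta)
}

.fit_one_rep <- function(series, config) {
  out <- list()
  yg <- synthetic_transform(series)
  for (mth in intersect(config$methods, c("AS", "BS"))) {
    fit <- fit_semiparametric(series, method = mth, q = config$q,
                              d = config$d, k = config$k,
                              lambda_grid = config$lambda_grid,
                              gamma = config$gamma, tol = config$tol,
                              max_iter = config$max_iter,
                              ar_order = config$ar_order,
                              outer_tol = config$outer_tol,
                              outer_max = config$outer_max,
                              return_hat = FALSE)
    out[[mth]] <- list(
      beta = fit$beta_hat, alpha = fit$alpha_hat,
      rmse_f = rmse_f(series$f_true, fit$f_hat),
      mape = as.numeric(mape(fit$yg$YG, fit$mu_hat)),
      medae = medae(fit$yg$YG, fit$mu_hat),
      gmse = gmse(fit$yg$YG, fit$mu_hat,
                  fit$ar$Sigma + tcrossprod(fit$mu_hat)),
      lambda = fit$lambda, iterations = fit$iterations,
      converged = fit$converged,
      n_selected = length(fit$selected_knots),
      rho_hat = fit$ar$rho[1])
  }
  if ("AR" %in% config$methods) {
    arf <- fit_ar_baseline(yg$YG, order = config$ar_baseline_order)
    s2 <- stats::var(arf$residuals)
    out$AR <- list(
      mape = as.numeric(mape(yg$YG, arf$fitted)),
      medae = medae(yg$YG, arf$fitted),
      gmse = gmse(yg$YG, arf$fitted,
                  diag(s2, series$n) + tcrossprod(arf$fitted)))
  }
  out
}

#' Run the Monte-Carlo comparison of the spline estimators
#'
#' For each replication: generate a dataset, apply the synthetic transform,
#' fit the adaptive-ridge and penalized B-spline estimators (smoothing
#' parameter re-selected by AICc per replication) and the naive AR baseline,
#' and accumulate coefficient, smooth-component and whole-model statistics
#' with Monte-Carlo standard errors. Failed replications are recorded and
#' skipped; the run aborts if more than 5 percent fail.
#'
#' @param config a \code{"simulation_config"}.
#' @param progress print a dot every 50 replications.
#' @return An object of class \code{"mc_summary"}; see
#'   \code{\link{summary_to_tables}} for tabular views.
#' @export
run_monte_carlo <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$reps)
  spl <- intersect(config$methods, c("AS", "BS"))
  acc <- list()
  failures <- list()
  for (r in seq_len(config$reps)) {
    series <- generate_dataset(config, rep_seeds[r])
    res <- tryCatch(.fit_one_rep(series, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(rep = r, message = conditionMessage(res))
    } else {
      res$f_true <- series$f_true
      acc[[length(acc) + 1L]] <- res
    }
    if (progress && r %% 50L == 0L) cat(".")
    if (length(failures) > ceiling(0.05 * config$reps))
      stop(sprintf("more than 5%% of replications failed; first error: %s",
                   failures[[1]]$message))
  }
  if (progress) cat("\n")
  nrep <- length(acc)
  beta_true <- config$beta
  p <- length(beta_true)
  # reference spline coefficients: unpenalized projection of the true smooth
  kk <- if (is.null(config$k)) max(1L, min(floor(config$n / 4), 40L)) else config$k
  s <- seq_len(config$n) / config$n
  Bref <- bspline_basis(s, build_knots(s, k = kk, q = config$q))
  alpha_ref <- qr.coef(qr(Bref), true_function(config$n))

  se_mean <- function(x) stats::sd(x) / sqrt(length(x))
  beta_tab <- do.call(rbind, lapply(spl, function(mth) {
    bh <- t(vapply(acc, function(a) a[[mth]]$beta, numeric(p)))
    do.call(rbind, lapply(seq_len(p), function(j) {
      dev <- bh[, j] - beta_true[j]
      data.frame(method = mth, coef = j, true = beta_true[j],
                 bias_abs = mean(abs(dev)), bias_abs_se = se_mean(abs(dev)),
                 bias_signed = mean(dev), bias_signed_se = se_mean(dev),
                 variance = stats::var(bh[, j]),
                 variance_se = se_mean((dev - mean(dev))^2))
    }))
  }))
  alpha_tab <- do.call(rbind, lapply(spl, function(mth) {
    ah <- t(vapply(acc, function(a) a[[mth]]$alpha, numeric(length(alpha_ref))))
    dev <- sweep(ah, 2, alpha_ref)
    data.frame(method = mth,
               bias_abs = mean(rowMeans(abs(dev))),
               bias_abs_se = se_mean(rowMeans(abs(dev))),
               variance = mean(apply(ah, 2, stats::var)))
  }))
  f_tab <- do.call(rbind, lapply(spl, function(mth) {
    v <- vapply(acc, function(a) a[[mth]]$rmse_f, numeric(1))
    data.frame(method = mth, rmse_f = mean(v), rmse_f_se = se_mean(v))
  }))
  model_methods <- config$methods
  model_tab <- do.call(rbind, lapply(model_methods, function(mth) {
    g <- function(fld) vapply(acc, function(a) a[[mth]][[fld]], numeric(1))
    data.frame(method = mth,
               mape = mean(g("mape")), mape_se = se_mean(g("mape")),
               medae = mean(g("medae")), medae_se = se_mean(g("medae")),
               gmse = mean(g("gmse")), gmse_se = se_mean(g("gmse")))
  }))
  rgmse_val <- if (all(c("AS", "BS") %in% model_methods)) {
    rgmse(model_tab$gmse[model_tab$method == "AS"],
          model_tab$gmse[model_tab$method == "BS"])
  } else NA_real_
  iters <- if ("AS" %in% spl)
    vapply(acc, function(a) a$AS$iterations, numeric(1)) else numeric(0)
  structure(list(config = config, reps_used = nrep,
                 failures = failures,
                 beta = beta_tab, alpha = alpha_tab, f = f_tab,
                 model = model_tab, rgmse = rgmse_val,
                 as_iterations_mean = if (length(iters)) mean(iters) else NA_real_,
                 as_iterations = iters,
                 rep_results = acc),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary: n = %d, CL = %.0f%%, %d/%d replications\n",
              x$config$n, 100 * x$config$CL, x$reps_used, x$config$reps))
  print(x$beta[, c("method", "coef", "bias_abs", "variance")],
        row.names = FALSE)
  print(x$f, row.names = FALSE)
  invisible(x)
}

#' Render a Monte-Carlo summary as report tables
#'
#' Reshapes an \code{"mc_summary"} into the three standard comparison tables:
#' coefficient bias/variance, smooth-component bias/variance/RMSE, and
#' whole-model MAPE/MedAE/GMSE (plus the GMSE ratio). Optionally writes them
#' as CSV files.
#'
#' @param summary an \code{"mc_summary"}.
#' @param dir optional directory; when given, writes
#'   \code{table_beta.csv}, \code{table_f.csv}, \code{table_model.csv} there.
#' @return named list of data frames \code{beta}, \code{f}, \code{model}.
#' @export
summary_to_tables <- function(summary, dir = NULL) {
  stopifnot(inherits(summary, "mc_summary"))
  if (nrow(summary$model) == 0) stop("summary contains no fitted methods")
  cfg <- summary$config
  tag <- function(df) cbind(n = cfg$n, CL = cfg$CL, df)
  tabs <- list(beta = tag(summary$beta),
               f = tag(merge(summary$alpha, summary$f, by = "method")),
               model = tag(cbind(summary$model, rgmse = summary$rgmse)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]], file.path(dir, paste0("table_", nm, ".csv")),
                       row.names = FALSE)
  }
  tabs
}
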