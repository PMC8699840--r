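test_that("MAPE excludes zeroed censored points and is scale invariant", {
  expect_equal(as.numeric(mape(c(2, 0, 4), c(1, 0, 2))), 0.5)
  expect_equal(attr(mape(c(2, 0, 4), c(1, 0, 2)), "n_used"), 2)
  expect_equal(as.numeric(mape(c(1, 2), c(1, 2))), 0)
  y <- c(3, 0, 7, 2); f <- c(2.5, 1, 8, 2.2)
  expect_equal(as.numeric(mape(10 * y, 10 * f)), as.numeric(mape(y, f)))
  expect_error(mape(c(0, 0), c(1, 1)), "zero")
})

test_that("MedAE is the median residual and resists corruption", {
  expect_equal(medae(c(1, 2), c(1, 2)), 0)
  expect_equal(medae(c(1, 100), c(0, 0)), 50.5)
  r <- c(1, 2, 3, 4, 101)
  expect_equal(medae(r, rep(0, 5)), 3)
  r2 <- r; r2[5] <- 101 * 1000
  expect_equal(medae(r2, rep(0, 5)), 3)
})

test_that("GMSE is the stated quadratic form", {
  expect_equal(gmse(c(1, 2), c(1, 2), diag(2)), 0)
  set.seed(3)
  e <- rnorm(6); y <- rnorm(6)
  expect_equal(gmse(y, y - e), mean(e^2))
  A <- matrix(rnorm(36), 6); M <- crossprod(A)    # random PSD weight
  brute <- 0
  for (i in 1:6) for (j in 1:6) brute <- brute + e[i] * M[i, j] * e[j]
  expect_equal(gmse(y, y - e, M), brute / 6)
  expect_error(gmse(y, y - e, -diag(6)), "positive semidefinite")
})

test_that("RGMSE is a reciprocal ratio", {
  expect_equal(rgmse(2, 2), 1)
  expect_equal(rgmse(2, 4), 0.5)
  expect_equal(rgmse(3, 7) * rgmse(7, 3), 1)
  expect_error(rgmse(1, 0), "denominator")
})

test_that("RMSE of the smooth follows the root-mean-square formula", {
  expect_equal(rmse_f(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse_f(c(0, 0), c(3, 4)), sqrt(25 / 2))
  f <- rnorm(10)
  expect_equal(rmse_f(f, f + 2), 2)
})

test_that("closed-form diagnostics match a dense-matrix oracle", {
  inst <- make_instance(17, n = 25, k = 3, q = 2, d = 2, p = 2)
  lambda <- 3
  fit <- fit_bs(inst$y, inst$X, inst$B, inst$D, inst$V, lambda)
  fit$ar <- ar_covariance(0.4, 1, inst$n)
  V <- fit$ar$V
  f_true <- sin(2 * pi * inst$s)
  dg <- beta_diagnostics(fit, f_true = f_true)
  # dense evaluation of the printed formulas, term by term
  G <- crossprod(inst$B, V %*% inst$B) + lambda * crossprod(inst$D)
  M <- inst$B %*% solve(G, crossprod(inst$B, V))
  A <- crossprod(inst$X, V) %*% M
  XtVmA <- crossprod(inst$X, V) - A
  Fm <- XtVmA %*% inst$X
  bias_beta <- solve(Fm, XtVmA %*% f_true)
  cov_beta <- fit$sigma2_hat * solve(Fm) %*% Fm %*% solve(Fm)
  expect_equal(dg$bias_beta, as.numeric(bias_beta), tolerance = 1e-8)
  expect_equal(dg$cov_beta, cov_beta, tolerance = 1e-8)
  cov_alpha <- fit$sigma2_hat / inst$n *
    solve(G) %*% crossprod(inst$B, V %*% inst$B) %*% solve(G)
  expect_equal(dg$cov_alpha, cov_alpha, tolerance = 1e-8)
  # covariance matrices are symmetric PSD
  expect_lt(max(abs(dg$cov_beta - t(dg$cov_beta))), 1e-10)
  expect_gte(min(eigen(dg$cov_alpha, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  # a vanishing smooth cannot bias the parametric part
  dg0 <- beta_diagnostics(fit, f_true = rep(0, inst$n))
  expect_equal(dg0$bias_beta, rep(0, 2), tolerance = 1e-12)
})
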