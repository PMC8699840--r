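test_that("censoring-survival estimate matches hand-computed product", {
  # n = 4, censored ranks 2 and 4: 1-G = 1 on [0,2), 2/3 on [2,4), 0 beyond
  km <- km_censoring_survival(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_survival_at(km, c(0.5, 1.9, 2, 3.9, 4, 9)),
               c(1, 1, 2/3, 2/3, 0, 0))
  # no censoring: empty product
  km1 <- km_censoring_survival(1:5, rep(1, 5))
  expect_true(all(km_survival_at(km1, seq(0, 6, by = 0.5)) == 1))
  # single censored point
  km2 <- km_censoring_survival(5, 0)
  expect_equal(km_survival_at(km2, c(4.9, 5, 6)), c(1, 0, 0))
  expect_error(km_censoring_survival(numeric(0), numeric(0)), "empty")
  expect_error(km_censoring_survival(1:3, c(1, 2, 0)), "0/1")
})

test_that("censoring-survival is a step function agreeing with survfit", {
  skip_if_not_installed("survival")
  for (seed in 1:4) {
    set.seed(seed)
    n <- 40
    Y <- rexp(n, 0.2)        # continuous, ties almost surely absent
    delta <- rbinom(n, 1, 0.7)
    if (all(delta == 1)) delta[1] <- 0
    km <- km_censoring_survival(Y, delta)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    sf <- survival::survfit(survival::Surv(Y, 1 - delta) ~ 1)
    at <- sort(Y)
    expect_equal(km_survival_at(km, at),
                 summary(sf, times = at)$surv, tolerance = 1e-10)
  }
})

test_that("synthetic transform zeroes censored points and inflates the rest", {
  ser <- censored_series(Y = c(1, 2, 3, 4), delta = c(1, 0, 1, 0))
  yg <- synthetic_transform(ser)
  expect_equal(yg$YG, c(1, 0, 4.5, 0))   # 3 / (2/3) = 4.5 via the left limit
  # uncensored-only series: identity
  ser2 <- censored_series(Y = c(2, 5, 1), delta = c(1, 1, 1), s = 1:3)
  expect_equal(synthetic_transform(ser2)$YG, c(2, 5, 1))
  # censored rows are zero, uncensored at least their observed value
  set.seed(2)
  Z <- rnorm(100, 10, 2)
  cens <- generate_censoring(Z, 0.3)
  ser3 <- censored_series(cens$Y, cens$delta)
  yg3 <- synthetic_transform(ser3)
  expect_true(all(yg3$YG[cens$delta == 0] == 0))
  expect_true(all(yg3$YG[cens$delta == 1] >= cens$Y[cens$delta == 1] - 1e-12))
  expect_true(all(is.finite(yg3$YG)))
})

test_that("transform with the true censoring survival preserves the mean", {
  # with known (not KM-estimated) censoring distribution and genuinely
  # independent censoring, the synthetic responses are unbiased for Z
  set.seed(5)
  reps <- 300; n <- 150
  d <- replicate(reps, {
    Z <- rnorm(n, 10, 2)
    C <- rnorm(n, 12, 2)
    delta <- as.numeric(Z <= C)
    Y <- pmin(Z, C)
    YG <- delta * Y / (1 - pnorm(Y, 12, 2))
    c(mean(YG), mean(Z))
  })
  diffs <- d[1, ] - d[2, ]
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(reps))
})

test_that("censoring generator honors the mechanism's guarantees", {
  set.seed(7)
  Z <- rnorm(1000, 10, 3)
  out <- generate_censoring(Z, 0.20, seed = 99)
  # censored fraction within 3 binomial SE of the target
  expect_lt(abs(mean(out$delta == 0) - 0.20),
            3 * sqrt(0.2 * 0.8 / 1000))
  # delta = 0 implies C < Z and Y = C; delta = 1 implies Y = Z
  cidx <- out$delta == 0
  expect_true(all(out$C[cidx] < Z[cidx]))
  expect_equal(out$Y[cidx], out$C[cidx])
  expect_equal(out$Y[!cidx], Z[!cidx])
  # determinism under a fixed seed
  out2 <- generate_censoring(Z, 0.20, seed = 99)
  expect_identical(out, out2)
  # no-censoring limit
  out0 <- generate_censoring(Z, 0, seed = 1)
  expect_equal(out0$Y, Z)
  expect_true(all(out0$delta == 1))
  expect_error(generate_censoring(Z, 1), "\\[0, 1\\)")
})
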