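# censpline

Semiparametric spline estimation for right-censored time series.

## The problem

Time series are often censored from the right — a measuring device has a
detection limit, or a study ends before every duration is resolved. For a
series `Y_t = min(Z_t, C_t)` with censoring indicator `delta_t = [Z_t <= C_t]`,
ordinary regression of `Y` on covariates estimates the wrong conditional
mean. `censpline` is for analysts who want to fit the partial-linear model

    Z_t = x_t' beta + f(s_t) + eps_t,     eps_t = rho * eps_{t-1} + u_t,

to such data: a parametric part `x_t' beta`, an unspecified smooth `f` of an
ordered covariate (usually scaled time, capturing seasonality or trend), and
AR(1) errors handled by generalized least squares.

Censoring is removed in mean by the Kaplan–Meier synthetic-data
transformation `YG_t = delta_t * Y_t / (1 - Ghat(Y_t^-))`, where `1 - Ghat`
is the product-limit estimate of the censoring-survival function: censored
points become zero, uncensored points are inflated. The smooth `f` is then
estimated in two ways:

* **BS** — a penalized B-spline (P-spline): difference penalty
  `lambda * ||D alpha||^2` on the basis coefficients;
* **AS** — an adaptive-ridge spline: iteratively reweighted penalty
  `lambda * sum_i w_i (D alpha)_i^2` with `w_i = ((D alpha)_i^2 + gamma^2)^-1`,
  which approximates an L0 count of active differences and thereby *selects
  knots*; it is the estimator of interest, with BS as the benchmark.

The smoothing parameter is chosen by corrected AIC,
`AICc = log(sigma2) + 1 + 2(tr(H)+1)/(n - tr(H) - 2)`, and the AR error
covariance is re-estimated from residuals in an outer loop. Model quality is
reported via MAPE, MedAE, GMSE and the GMSE ratio between the two
estimators, and RMSE between `f` and its estimate when the truth is known.

## A worked example

```r
library(censpline)

# a censored seasonal dataset from the built-in generator:
# n = 100, three N(5,1) covariates with beta = (3, 0.5, -1),
# AR(1) errors (rho = 0.5), ~20% censoring
cfg    <- simulation_config(n = 100, CL = 0.20, reps = 1, seed = 42)
series <- generate_dataset(cfg, 42)
print(series)
#> censored time series: n = 100, p = 3 covariates, 21.0% censored

fit <- fit_semiparametric(series, method = "AS")
print(fit)
#> semiparametric AS fit: n = 100, p = 3, m = 29 basis functions
#>   beta-hat: 4.7405, -1.0185, -1.1160
#>   lambda = 1e+06, df = 3.00, sigma2-hat = 44.16, AICc = 4.8721
#>   3 weight iterations (converged), 0 selected knots

rmse_f(series$f_true, fit$f_hat)   # 0.2902 — error in the seasonal smooth
mape(fit$yg$YG, fit$mu_hat)        # 0.2095 — whole-model MAPE on the
                                   #          synthetic (nonzero) responses
```

Reading the output: `lambda` is the AICc-selected smoothing parameter and
`df = tr(H)` the effective model dimension — here the adaptive penalty
collapsed the smooth to its unpenalized (linear) null space plus the three
covariates, selecting no interior knots, because at 20% censoring the
synthetic-response noise (`sigma2-hat = 44`) dwarfs the seasonal signal.
`beta-hat` shows the distortion that censoring inflicts on the parametric
part under this censoring mechanism (the true values are 3, 0.5, -1; see
the vignette for why the mechanism, not the estimator, produces it). The
RMSE of the smooth is small because the true seasonal component has
amplitude below one.

Real data come in through `read_series("file.csv")` (columns `y, delta,
x1..xp, s`), with `make_lagged_design()` to use lags of the response as
covariates. A thin command-line wrapper with `transform`, `fit` and
`simulate` commands is installed at `inst/cli/censpline.R`.

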