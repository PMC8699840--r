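# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Cox-de Boor recursion written directly from the two-term recurrence, with
# the zero-denominator convention; right-closed last interval.
oracle_bspline <- function(aug, q, s) {
  nb <- length(aug) - q - 1L
  smax <- max(aug)
  B0 <- function(i, x) {
    if (aug[i] <= x && x < aug[i + 1]) return(1)
    # close the rightmost nondegenerate interval
    if (x == smax && aug[i] < aug[i + 1] && aug[i + 1] == smax) return(1)
    0
  }
  Brec <- function(i, deg, x) {
    if (deg == 0) return(B0(i, x))
    t1 <- 0
    den1 <- aug[i + deg] - aug[i]
    if (den1 > 0) t1 <- (x - aug[i]) / den1 * Brec(i, deg - 1L, x)
    t2 <- 0
    den2 <- aug[i + deg + 1] - aug[i + 1]
    if (den2 > 0) t2 <- (aug[i + deg + 1] - x) / den2 * Brec(i + 1L, deg - 1L, x)
    t1 + t2
  }
  t(vapply(s, function(x) vapply(seq_len(nb), function(i) Brec(i, q, x),
                                 numeric(1)), numeric(nb)))
}

# Dense block solve of the penalized normal equations (the stacked system
# with blocks X'VX, X'VB, B'VX, B'VB + lambda * P), P a ready penalty matrix.
oracle_block_solve <- function(y, X, B, P, V, lambda) {
  XtV <- crossprod(X, V)
  BtV <- crossprod(B, V)
  lhs <- rbind(cbind(XtV %*% X, XtV %*% B),
               cbind(BtV %*% X, BtV %*% B + lambda * P))
  rhs <- c(XtV %*% y, BtV %*% y)
  sol <- solve(lhs, rhs)
  list(beta = sol[seq_len(ncol(X))], alpha = sol[-seq_len(ncol(X))])
}

# Generic numerical minimizer of the penalized GLS criterion.
oracle_minimize_pss <- function(y, X, B, P, V, lambda) {
  p <- ncol(X); m <- ncol(B)
  fn <- function(theta) {
    beta <- theta[seq_len(p)]
    alpha <- theta[p + seq_len(m)]
    r <- y - if (p > 0) X %*% beta + B %*% alpha else B %*% alpha
    as.numeric(crossprod(r, V %*% r)) + lambda * as.numeric(
      crossprod(alpha, P %*% alpha))
  }
  start <- rep(0, p + m)
  opt <- stats::optim(start, fn, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  list(beta = opt$par[seq_len(p)], alpha = opt$par[p + seq_len(m)],
       value = opt$value)
}

# Small random fitting instance on a fixed seed.
make_instance <- function(seed, n = 25, k = 3, q = 2, d = 1, p = 2,
                          rho = 0.4) {
  set.seed(seed)
  s <- sort(runif(n))
  s[1] <- 0; s[n] <- 1
  kn <- build_knots(s, k = k, q = q)
  B <- bspline_basis(s, kn)
  m <- ncol(B)
  D <- difference_matrix(m, d)
  X <- matrix(rnorm(n * p, 1, 1), n, p)
  V <- ar_covariance(rho, 1, n)$V
  y <- rnorm(n, 2, 1)
  list(y = y, X = X, B = B, D = D, V = V, n = n, m = m, s = s, knots = kn)
}
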