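// Core penalized GLS solver for the semiparametric spline estimators.
//
// Solves, for fixed weights W (identity for the plain P-spline; iteratively
// reweighted for the adaptive-ridge spline),
//   min_{beta, alpha} (y - X beta - B alpha)' V (y - X beta - B alpha)
//                     + lambda * alpha' D' W D alpha,
// via the profiled block solution: with G = B'VB + lambda D'WD and
// M = B G^{-1} B'V, beta solves [X'V(I-M)X] beta = X'V(I-M) y and
// alpha = G^{-1} B'V (y - X beta).  The hat matrix is
// H = M + (I-M) X F^{-1} X'V(I-M), F = X'V(I-M)X, so mu = H y exactly.
//
// tr(H) and tr(H'H) (needed for AICc and the residual-variance denominator
// tr[(I-H)'(I-H)]) are accumulated from m x m and p x p pieces only; the full
// n x n hat matrix is formed only on request.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat chol_solve(const mat& G, const mat& rhs) {
  // Jacobi equilibration: penalty weights can span ~16 orders of magnitude
  // across rows, which makes a raw Cholesky solve lose all precision
  vec s = 1.0 / sqrt(G.diag());
  mat Gs = G.each_col() % s;
  Gs.each_row() %= s.t();
  mat R;
  if (!chol(R, Gs)) {
    Gs.diag() += 1e-10;                     // jitter retry before failing
    if (!chol(R, Gs))
      Rcpp::stop("singular penalized system (even after diagonal jitter)");
  }
  mat rhs_s = rhs.each_col() % s;
  mat x = solve(trimatu(R), solve(trimatl(R.t()), rhs_s));
  return x.each_col() % s;
}

// Cross-products shared by every lambda of a sweep.
struct Precomp {
  mat BtV, BtVB, XtV, XtVX, XtVB, E, Q;
  vec BtVY, XtVY;
  uword n, m, p;
};

static Precomp precompute(const vec& yg, const mat& X, const mat& B,
                          const mat& V) {
  Precomp pc;
  pc.n = B.n_rows; pc.m = B.n_cols; pc.p = X.n_cols;
  pc.BtV = B.t() * V;
  pc.BtVB = pc.BtV * B;
  pc.BtVY = pc.BtV * yg;
  pc.E = B.t() * B;
  pc.Q = pc.BtV * pc.BtV.t();       // B'V V B (V symmetric)
  if (pc.p > 0) {
    pc.XtV = X.t() * V;
    pc.XtVX = pc.XtV * X;
    pc.XtVB = pc.XtV * B;
    pc.XtVY = pc.XtV * yg;
  }
  return pc;
}

struct FitResult {
  vec beta, alpha, fitted, w, knot_stat;
  int iterations; bool converged; bool valid;
  double delta, trH, trHtH, rss, sigma2;
  mat G;
};

static FitResult penfit_core(const Precomp& pc, const vec& yg, const mat& X,
                             const mat& B, const mat& D, double lambda,
                             double gamma, double tol, int max_iter,
                             bool adaptive) {
  const uword m = pc.m, p = pc.p, n = pc.n;
  const uword md = D.n_rows;
  FitResult fr;
  vec w(md, fill::ones), ws(md, fill::ones);
  vec beta(p, fill::zeros), alpha(m, fill::zeros), fitted(n, fill::zeros);
  mat G;
  double delta_old = datum::inf, delta_new = datum::inf;
  bool converged = !adaptive;
  fr.valid = true;
  int iters = 0;
  const int n_iter = adaptive ? max_iter : 1;

  for (int it = 1; it <= n_iter; ++it) {
    iters = it;
    G = pc.BtVB + lambda * (D.t() * diagmat(ws) * D);
    if (p > 0) {
      mat GiBtVX = chol_solve(G, pc.XtVB.t());       // m x p
      vec GiBtVY = chol_solve(G, pc.BtVY);
      mat F   = pc.XtVX - pc.XtVB * GiBtVX;          // p x p
      vec rhs = pc.XtVY - pc.XtVB * GiBtVY;
      vec betav;
      // reject ill-conditioned profiled systems instead of approximating:
      // such lambdas are dropped from the AICc search
      if (rcond(F) < 1e-13 ||
          !solve(betav, F, rhs, solve_opts::no_approx)) {
        fr.valid = false;
        break;
      }
      beta = betav;
      alpha = GiBtVY - GiBtVX * beta;
      fitted = X * beta + B * alpha;
    } else {
      alpha = chol_solve(G, pc.BtVY).col(0);
      fitted = B * alpha;
    }
    delta_new = mean(abs(yg - fitted));
    if (adaptive) {
      vec dalpha = D * alpha;
      w = 1.0 / (square(dalpha) + gamma * gamma);
      if (it > 1 && std::abs(delta_new - delta_old) < tol) {
        converged = true;
        break;
      }
      delta_old = delta_new;
      // raw reciprocal-square weights: near-zero differences receive weights
      // up to gamma^-2, which is what drives the penalty toward the L0 count
      ws = w;
    }
  }

  if (!fr.valid) {
    fr.beta = beta; fr.alpha = alpha; fr.fitted = fitted; fr.w = w;
    fr.knot_stat = vec(md, fill::zeros);
    fr.iterations = iters; fr.converged = false; fr.delta = delta_new;
    fr.trH = datum::nan; fr.trHtH = datum::nan;
    fr.rss = datum::nan; fr.sigma2 = datum::nan;
    fr.G = G;
    return fr;
  }

  // knot-relevance statistic (Dalpha)^2 / ((Dalpha)^2 + gamma^2) in (0, 1)
  vec dalpha = D * alpha;
  fr.knot_stat = square(dalpha) / (square(dalpha) + gamma * gamma);

  // traces of H and H'H from small-matrix identities
  double trM  = trace(chol_solve(G, pc.BtVB));
  double trMM = trace(chol_solve(G, pc.E) * chol_solve(G, pc.Q));
  double trH = trM, trHtH = trMM;
  if (p > 0) {
    mat GiBtV  = chol_solve(G, pc.BtV);       // m x n
    mat GiBtVX = chol_solve(G, pc.XtVB.t());  // m x p
    mat U  = pc.XtV - pc.XtVB * GiBtV;        // p x n  = X'V(I-M)
    mat W1 = X - B * GiBtVX;                  // n x p  = (I-M)X
    mat F = pc.XtVX - pc.XtVB * GiBtVX;
    mat Fi;
    if (rcond(F) < 1e-13 || !inv(Fi, F)) {
      fr.valid = false;
      fr.beta = beta; fr.alpha = alpha; fr.fitted = fitted; fr.w = w;
      fr.iterations = iters; fr.converged = converged; fr.delta = delta_new;
      fr.trH = datum::nan; fr.trHtH = datum::nan;
      fr.rss = datum::nan; fr.sigma2 = datum::nan;
      fr.G = G;
      return fr;
    }
    double trT = trace(Fi * (U * W1));
    double trTtT = trace(Fi.t() * (W1.t() * W1) * Fi * (U * U.t()));
    mat BtW1 = B.t() * W1;                    // m x p
    mat UVB = U * pc.BtV.t();                 // p x m  (U V B, V symmetric)
    double trMT = trace(chol_solve(G, BtW1) * (Fi * UVB));
    trH  += trT;
    trHtH += 2.0 * trMT + trTtT;
  }

  fr.beta = beta; fr.alpha = alpha; fr.fitted = fitted; fr.w = w;
  fr.iterations = iters; fr.converged = converged; fr.delta = delta_new;
  fr.trH = trH; fr.trHtH = trHtH;
  fr.rss = accu(square(yg - fitted));
  fr.sigma2 = fr.rss / ((double)n - 2.0 * trH + trHtH);
  fr.G = G;
  return fr;
}

// [[Rcpp::export]]
Rcpp::List cpp_penfit(const arma::vec& yg, const arma::mat& X,
                      const arma::mat& B, const arma::mat& D,
                      const arma::mat& V, double lambda,
                      double gamma, double tol, int max_iter,
                      bool adaptive, bool return_hat) {
  Precomp pc = precompute(yg, X, B, V);
  FitResult fr = penfit_core(pc, yg, X, B, D, lambda, gamma, tol,
                             max_iter, adaptive);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("beta") = fr.beta, Rcpp::Named("alpha") = fr.alpha,
    Rcpp::Named("fitted") = fr.fitted, Rcpp::Named("w") = fr.w,
    Rcpp::Named("knot_stat") = fr.knot_stat,
    Rcpp::Named("iterations") = fr.iterations,
    Rcpp::Named("converged") = fr.converged,
    Rcpp::Named("delta") = fr.delta,
    Rcpp::Named("trH") = fr.trH, Rcpp::Named("trHtH") = fr.trHtH,
    Rcpp::Named("rss") = fr.rss, Rcpp::Named("sigma2") = fr.sigma2,
    Rcpp::Named("valid") = fr.valid);
  if (return_hat) {
    mat M = B * chol_solve(fr.G, pc.BtV);
    mat H = M;
    if (pc.p > 0) {
      mat GiBtVX = chol_solve(fr.G, pc.XtVB.t());
      mat U  = pc.XtV - pc.XtVB * chol_solve(fr.G, pc.BtV);
      mat W1 = X - B * GiBtVX;
      mat F = pc.XtVX - pc.XtVB * GiBtVX;
      H += W1 * (inv(F) * U);
    }
    out["H"] = H;
  }
  return out;
}

// Evaluate a whole lambda grid with shared cross-products; returns per-lambda
// scalars only (enough for AICc selection).
// [[Rcpp::export]]
Rcpp::List cpp_pensweep(const arma::vec& yg, const arma::mat& X,
                        const arma::mat& B, const arma::mat& D,
                        const arma::mat& V, const arma::vec& lambdas,
                        double gamma, double tol, int max_iter,
                        bool adaptive) {
  Precomp pc = precompute(yg, X, B, V);
  const uword L = lambdas.n_elem;
  vec trH(L), trHtH(L), rss(L), sigma2(L), iters(L), conv(L);
  for (uword l = 0; l < L; ++l) {
    FitResult fr = penfit_core(pc, yg, X, B, D, lambdas(l), gamma, tol,
                               max_iter, adaptive);
    trH(l) = fr.trH; trHtH(l) = fr.trHtH; rss(l) = fr.rss;
    sigma2(l) = fr.sigma2; iters(l) = fr.iterations;
    conv(l) = fr.converged ? 1.0 : 0.0;
  }
  return Rcpp::List::create(
    Rcpp::Named("lambda") = lambdas, Rcpp::Named("trH") = trH,
    Rcpp::Named("trHtH") = trHtH, Rcpp::Named("rss") = rss,
    Rcpp::Named("sigma2") = sigma2, Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = conv);
}
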