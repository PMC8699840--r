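#' Build an equally spaced, clamped knot vector
#'
#' Places \code{k} equally spaced interior knots strictly inside the range of
#' \code{s} and clamps the boundary by repeating each boundary knot \code{q+1}
#' times, so that a degree-\code{q} B-spline basis on the augmented sequence
#' spans all polynomials of degree \code{q} on \code{[min(s), max(s)]} and has
#' \code{m = q + k + 1} basis functions.
#'
#' @param s numeric vector of covariate values (at least two distinct values).
#' @param k number of interior knots (positive integer).
#' @param q spline degree (non-negative integer; 3 = cubic).
#' @return An object of class \code{"knot_vector"}: a list with elements
#'   \code{interior}, \code{boundary}, \code{augmented}, \code{k}, \code{q}.
#' @examples
#' build_knots(c(0, 1), k = 1, q = 1)$interior  # 0.5
#' @export
build_knots <- function(s, k, q = 3L) {
  s <- as.numeric(s)
  if (length(s) < 2L || !any(is.finite(s)))
    stop("'s' must contain at least two finite values")
  a <- min(s); b <- max(s)
  if (a == b) stop("degenerate domain: all values of 's' are identical")
  k <- as.integer(k); q <- as.integer(q)
  if (k < 1L) stop("'k' must be a positive integer")
  if (q < 0L) stop("'q' must be a non-negative integer")
  interior <- a + (b - a) * seq_len(k) / (k + 1)
  if (any(diff(c(a, interior, b)) <= 0))
    stop("invalid knots: adjacent knots coincide (k too large for this range)")
  augmented <- c(rep(a, q + 1L), interior, rep(b, q + 1L))
  structure(list(interior = interior, boundary = c(a, b),
                 augmented = augmented, k = k, q = q),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat(sprintf("knot vector: degree q = %d, %d interior knots on [%g, %g]\n",
              x$q, x$k, x$boundary[1], x$boundary[2]))
  invisible(x)
}

#' Evaluate the B-spline basis matrix
#'
#' Evaluates all \code{m = q + k + 1} B-spline basis functions of the knot
#' vector at the points \code{s}, via the Cox--de Boor recursion (degree-0
#' indicator functions combined with the usual two-term recursion; zero
#' denominators contribute zero). Intervals are half-open on the right except
#' the last, which is closed, so the basis is a partition of unity on the whole
#' closed domain including \code{s = b}.
#'
#' @param s numeric vector of evaluation points inside the knot domain.
#' @param knots a \code{"knot_vector"} from \code{\link{build_knots}}.
#' @return An \code{n x m} matrix with attributes \code{"s"} and \code{"knots"};
#'   rows sum to one and each row has at most \code{q + 1} nonzero entries.
#' @export
bspline_basis <- function(s, knots) {
  stopifnot(inherits(knots, "knot_vector"))
  s <- as.numeric(s)
  a <- knots$boundary[1]; b <- knots$boundary[2]
  if (any(!is.finite(s)) || any(s < a) || any(s > b))
    stop(sprintf("evaluation points must lie within [%g, %g]", a, b))
  B <- splines::splineDesign(knots$augmented, s, ord = knots$q + 1L,
                             outer.ok = FALSE)
  dimnames(B) <- NULL
  attr(B, "s") <- s
  attr(B, "knots") <- knots
  B
}

#' Difference-penalty matrix
#'
#' Returns the \code{(m - d) x m} banded matrix \code{D} whose rows apply the
#' \code{d}-th order forward difference to a coefficient vector, i.e.
#' \code{(D a)[i]} is the \code{d}-th difference of \code{a} ending at index
#' \code{i + d}. \code{t(D) \%*\% D} is the usual P-spline penalty.
#'
#' @param m number of basis coefficients.
#' @param d difference (penalty) order, \code{1 <= d < m}.
#' @return Integer-valued matrix of dimension \code{(m - d) x m}.
#' @examples
#' difference_matrix(4, 2)  # rows (1, -2, 1, 0) and (0, 1, -2, 1)
#' @export
difference_matrix <- function(m, d = 2L) {
  m <- as.integer(m); d <- as.integer(d)
  if (d < 1L) stop("'d' must be at least 1")
  if (d >= m) stop("invalid difference order: 'd' must be smaller than 'm'")
  D <- diff(diag(m), differences = d)
  dimnames(D) <- NULL
  D
}
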