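# Polynomials in the transform variable s are plain numeric coefficient
# vectors in ascending order: c(a0, a1, ...) <-> a0 + a1*s + ...

poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p))
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  c(p, numeric(n - length(p))) + c(q, numeric(n - length(q)))
}

poly_pow <- function(p, n) {
  out <- 1
  for (i in seq_len(n)) out <- poly_mult(out, p)
  out
}

#' Laplace-transform rule for the n-fold proportional derivative
#'
#' Under the usual (classical) Laplace transform, the n-fold proportional
#' derivative of a sufficiently smooth function \eqn{\phi} transforms as
#' \deqn{\mathcal{L}\{D^{(n)\alpha}_P \phi\}
#'   = (\alpha s + 1 - \alpha)^n \Phi(s)
#'   - \sum_{k=0}^{n-1} b_k(s)\, \phi^{(k)}(0),}
#' where the boundary-value coefficient for \eqn{\phi^{(k)}(0)} is
#' \deqn{b_k(s) = \alpha^{k+1} \sum_{r=0}^{n-1-k} \binom{n}{r}
#'   (\alpha s)^{n-1-k-r} (1-\alpha)^r.}
#' At \eqn{\alpha = 1} this reduces to the classical rule
#' \eqn{s^n \Phi(s) - \sum_k s^{n-1-k} \phi^{(k)}(0)}.
#'
#' @param n Fold count, \code{>= 1}.
#' @param alpha Order, \code{0 < alpha <= 1}.
#' @return An object of class \code{"prop_lt_rule"}: list with \code{n},
#'   \code{alpha}, \code{multiplier} (degree-\code{n} polynomial in \code{s},
#'   ascending coefficients) and \code{boundary_coeffs} (list of \code{n}
#'   polynomials; element \code{k+1} multiplies \eqn{\phi^{(k)}(0)}).
#' @seealso [lt_compose_first_order()] for the iterated first-order route,
#'   [expand_nth_prop_derivative()] for the time-domain expansion.
#' @export
lt_nth_order_rule <- function(n, alpha) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be an integer >= 1", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  n <- as.integer(n)
  first <- c(1 - alpha, alpha)                     # alpha*s + (1 - alpha)
  multiplier <- poly_pow(first, n)
  boundary <- vector("list", n)
  for (k in 0:(n - 1L)) {
    b <- numeric(1)                                # zero polynomial
    for (r in 0:(n - 1L - k)) {
      deg <- n - 1L - k - r
      term <- numeric(deg + 1L)
      term[deg + 1L] <- choose(n, r) * alpha^deg * (1 - alpha)^r
      b <- poly_add(b, term)
    }
    boundary[[k + 1L]] <- alpha^(k + 1L) * b
  }
  structure(list(n = n, alpha = alpha, multiplier = multiplier,
                 boundary_coeffs = boundary),
            class = "prop_lt_rule")
}

#' @export
print.prop_lt_rule <- function(x, ...) {
  cat("<prop_lt_rule> n =", x$n, " alpha =", format(x$alpha), "\n")
  cat("  multiplier coefficients (ascending in s):",
      paste(format(x$multiplier), collapse = ", "), "\n")
  for (k in seq_along(x$boundary_coeffs))
    cat(sprintf("  coeff of phi^(%d)(0): %s\n", k - 1L,
                paste(format(x$boundary_coeffs[[k]]), collapse = ", ")))
  invisible(x)
}

#' Iterate the first-order transform rule
#'
#' Applies the first-order relation
#' \eqn{\mathcal{L}\{D^\alpha_P \psi\} = (\alpha s + 1 - \alpha)
#' \mathcal{L}\{\psi\} - \alpha \psi(0)} once more to an existing rule,
#' using the time-domain expansion of [expand_nth_prop_derivative()] for
#' the boundary value \eqn{(D^{(m)\alpha}_P \phi)(0)}. Iterating from
#' \code{n = 1} must reproduce [lt_nth_order_rule()] exactly; this function
#' exists so that the identity can be checked by an independent route.
#'
#' @param rule A \code{"prop_lt_rule"} of fold count \code{m}.
#' @return The \code{"prop_lt_rule"} of fold count \code{m + 1}.
#' @export
lt_compose_first_order <- function(rule) {
  stopifnot(inherits(rule, "prop_lt_rule"))
  alpha <- rule$alpha
  m <- rule$n
  first <- c(1 - alpha, alpha)
  multiplier <- poly_mult(first, rule$multiplier)
  # (D^{(m)a} phi)(0) = sum_r C(m,r) a^(m-r) (1-a)^r phi^((m-r))(0)
  w <- expand_nth_prop_derivative(m, alpha)$weights
  boundary <- vector("list", m + 1L)
  for (k in 0:m) {
    prev <- if (k < m) poly_mult(first, rule$boundary_coeffs[[k + 1L]])
            else numeric(1)
    # weight index r = m - k multiplies phi^((k))(0)
    extra <- alpha * w[m - k + 1L]
    boundary[[k + 1L]] <- poly_add(prev, extra)
  }
  structure(list(n = m + 1L, alpha = alpha, multiplier = multiplier,
                 boundary_coeffs = boundary),
            class = "prop_lt_rule")
}

#' Time-domain expansion of the n-fold proportional derivative
#'
#' The n-fold proportional derivative (linear kappa) expands over classical
#' derivatives with binomial weights:
#' \deqn{D^{(n)\alpha}_P \phi = \sum_{r=0}^{n} \binom{n}{r}
#'   \alpha^{n-r} (1-\alpha)^r \, \phi^{(n-r)}.}
#' The weights sum to 1 for every \code{n} and \code{alpha}.
#'
#' @inheritParams lt_nth_order_rule
#' @return An object of class \code{"operator_expansion"}: list with
#'   \code{n}, \code{alpha} and \code{weights} (length \code{n + 1};
#'   element \code{r + 1} multiplies \eqn{\phi^{(n-r)}}).
#' @export
expand_nth_prop_derivative <- function(n, alpha) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be an integer >= 1", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  n <- as.integer(n)
  r <- 0:n
  structure(list(n = n, alpha = alpha,
                 weights = choose(n, r) * alpha^(n - r) * (1 - alpha)^r),
            class = "operator_expansion")
}

#' @export
print.operator_expansion <- function(x, ...) {
  cat("<operator_expansion> n =", x$n, " alpha =", format(x$alpha), "\n")
  cat("  weights on (phi^(n), ..., phi):",
      paste(format(x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Solve one breath phase of the proportional model by Laplace transform
#'
#' Solves \eqn{R\, D^\alpha_P V + V/C = K} (constant right-hand side
#' \eqn{K}) via the proportional Laplace-transform rule: the transform is a
#' single-pole rational function in \eqn{s}, inverted by partial fractions
#' to the exponential
#' \deqn{V(t) = V_\infty + (V_0 - V_\infty) e^{-\lambda (t - t_0)},
#'   \qquad V_\infty = \frac{C K}{1 + CR - \alpha CR}, \quad
#'   \lambda = \frac{1 + CR - \alpha CR}{\alpha C R}.}
#' Anchors at times other than 0 are handled by the shift invariance of the
#' constant-coefficient equation.
#'
#' @param coefficient_R Resistance multiplying the derivative, \code{> 0}.
#' @param coefficient_invC Elastance \code{1/C}, \code{> 0}.
#' @param rhs_constant Constant driving term \eqn{K} (pressure).
#' @param anchor Length-2 numeric \code{c(t0, V0)}: the solution passes
#'   through volume \code{V0} at time \code{t0}.
#' @param alpha Proportional order, \code{0 < alpha <= 1}.
#' @return A [phase_solution] for the proportional family.
#' @export
solve_linear_phase_ltp <- function(coefficient_R, coefficient_invC,
                                   rhs_constant, anchor, alpha) {
  stopifnot(coefficient_R > 0, coefficient_invC > 0,
            is.numeric(anchor), length(anchor) == 2L,
            alpha > 0, alpha <= 1)
  R <- coefficient_R
  C <- 1 / coefficient_invC
  D <- 1 + C * R - alpha * C * R
  if (abs(D) < 1e-14)
    stop("singular configuration: 1 + CR - alpha*CR = 0", call. = FALSE)
  phase_solution(
    family = "proportional", alpha = alpha, beta = NA_real_,
    phase = NA_character_,
    V_inf = C * rhs_constant / D,
    V0 = anchor[2L], t0 = anchor[1L],
    rate = D / (alpha * C * R),
    warp_kind = "identity", warp_origin = anchor[1L]
  )
}
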