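#' Evaluate a local derivative of a differentiable function
#'
#' Evaluates the chosen local derivative at time \code{t} using the
#' equivalence form valid for differentiable \code{f}:
#' \deqn{D^\alpha_P f = (1-\alpha) f(t) + \alpha f'(t) \quad
#'       D^\alpha_C f = t^{1-\alpha} f'(t) \quad
#'       D^{\alpha,\beta}_M f = t^{1-\alpha} f'(t) / \Gamma(\beta+1)}
#' The limit-quotient definitions are numerically fragile and are used only
#' as a test oracle, never as the evaluation path.
#'
#' @param f Scalar function of time.
#' @param spec A [derivative_spec()].
#' @param t Evaluation time(s). Must satisfy \code{t > origin} for the
#'   conformable and truncated-M families.
#' @param fprime Optional analytic first derivative of \code{f}. When
#'   omitted, a central finite difference with Richardson extrapolation is
#'   used.
#' @param origin Base point of the conformable/truncated-M dilation
#'   (default 0). The breath-anchored expiration solutions use the phase
#'   anchor as origin, so their derivative acts on the shifted time
#'   \code{t - origin}; the weight is then \code{|t - origin|^(1-alpha)}.
#'
#' @return Numeric vector of derivative values, one per element of \code{t}.
#' @export
#' @examples
#' sp <- derivative_spec("conformable", alpha = 0.5)
#' eval_local_derivative(function(t) t^2, sp, t = 1, fprime = function(t) 2 * t)
eval_local_derivative <- function(f, spec, t, fprime = NULL, origin = 0) {
  stopifnot(is_derivative_spec(spec), is.numeric(t))
  if (spec$family %in% c("conformable", "truncated_M")) {
    if (origin == 0 && any(t <= 0))
      stop("conformable/truncated_M derivatives require t > 0",
           call. = FALSE)
    if (any(t == origin))
      stop("conformable/truncated_M derivative is singular at its origin",
           call. = FALSE)
  }
  if (is.null(fprime)) fprime <- function(tt) num_deriv(f, tt)
  deriv_f_weight(spec, t) * vapply(t, f, numeric(1)) +
    deriv_weight(spec, t, origin) * vapply(t, fprime, numeric(1))
}

# Central difference with 3-level Richardson extrapolation; adequate for the
# smooth trajectories handled here (closed-form solutions supply analytic
# derivatives wherever accuracy matters).
num_deriv <- function(f, t, h = 1e-4) {
  cd <- function(h) (f(t + h) - f(t - h)) / (2 * h)
  d1 <- cd(h); d2 <- cd(h / 2); d3 <- cd(h / 4)
  r1 <- (4 * d2 - d1) / 3
  r2 <- (4 * d3 - d2) / 3
  (16 * r2 - r1) / 15
}

#' Proportional exponential function
#'
#' The eigenfunction of the proportional derivative,
#' \deqn{e_\Theta(t, r) = \exp\left(-\int_r^t
#'   \frac{\kappa_1(\alpha,\tau) - \Theta(\tau)}{\kappa_0(\alpha,\tau)}
#'   \, d\tau\right),}
#' satisfying \eqn{D^\alpha_P e_\Theta(t,r) = \Theta(t) e_\Theta(t,r)}.
#' With the linear pair \eqn{\kappa_1 = 1-\alpha}, \eqn{\kappa_0 = \alpha}
#' and constant \eqn{\Theta} this is
#' \eqn{\exp(-((1-\alpha) - \Theta)(t - r)/\alpha)}, evaluated in closed
#' form; otherwise the integral is computed by adaptive quadrature.
#'
#' @param theta Eigenvalue function \eqn{\Theta(t)}, or a single constant.
#' @param alpha Order, \code{0 < alpha <= 1}.
#' @param t Evaluation time.
#' @param r Anchor time (\code{e_theta(r, r) = 1}).
#' @param kappa0,kappa1 Optional \eqn{\kappa(\alpha, t)} functions of
#'   \code{(alpha, t)}; default is the linear pair. \code{kappa0} must not
#'   vanish on \code{[r, t]}.
#' @return \eqn{e_\Theta(t, r)} as a numeric scalar (vectorised over
#'   \code{t}).
#' @export
prop_exponential <- function(theta, alpha, t, r = 0,
                             kappa0 = NULL, kappa1 = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  linear_kappa <- is.null(kappa0) && is.null(kappa1)
  if (is.null(kappa0)) kappa0 <- function(a, tt) rep(a, length(tt))
  if (is.null(kappa1)) kappa1 <- function(a, tt) rep(1 - a, length(tt))
  if (is.numeric(theta) && length(theta) == 1L) {
    th_const <- theta
    theta <- function(tt) rep(th_const, length(tt))
    if (linear_kappa)
      return(exp(-((1 - alpha) - th_const) * (t - r) / alpha))
  }
  vapply(t, function(tt) {
    k0 <- kappa0(alpha, seq(min(r, tt), max(r, tt), length.out = 31))
    if (any(abs(k0) < 1e-14))
      stop("kappa0 vanishes on the integration interval", call. = FALSE)
    val <- adapt_quad(function(tau)
      (kappa1(alpha, tau) - theta(tau)) / kappa0(alpha, tau), r, tt)
    exp(-val)
  }, numeric(1))
}

#' Proportional integral
#'
#' The inverse operation of the proportional derivative (linear kappa):
#' \deqn{I^\alpha f(t) = \int_a^t
#'   e^{\frac{\alpha - 1}{\alpha}(t - \tau)} f(\tau) \frac{d\tau}{\alpha},}
#' computed by adaptive quadrature. Applying the proportional derivative to
#' \code{t -> prop_integral(f, alpha, a, t)} recovers \code{f(t)}.
#'
#' @param f Continuous integrand.
#' @param alpha Order, \code{0 < alpha <= 1}. \code{alpha = 1} gives the
#'   ordinary integral.
#' @param a Lower limit.
#' @param t Upper limit(s).
#' @return Numeric vector of integral values.
#' @export
prop_integral <- function(f, alpha, a, t) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  vapply(t, function(tt)
    adapt_quad(function(tau)
      exp((alpha - 1) / alpha * (tt - tau)) * vapply(tau, f, numeric(1)) /
        alpha,
      a, tt),
    numeric(1))
}

#' Truncated Mittag-Leffler function
#'
#' Partial sum \eqn{\sum_{k=0}^{n} z^k / \Gamma(\beta k + 1)}. Summation
#' stops early once a term falls below \code{1e-16} in magnitude.
#'
#' @param beta Parameter, \code{> 0}.
#' @param z Argument (vectorised).
#' @param n_terms Truncation index (default 40).
#' @return Numeric vector of partial sums.
#' @export
#' @examples
#' truncated_mittag_leffler(1, 1, 60) # ~ exp(1)
truncated_mittag_leffler <- function(beta, z, n_terms = 40L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0,
            n_terms >= 0, is.numeric(z))
  vapply(z, function(zz) {
    total <- 0
    for (k in 0:n_terms) {
      term <- zz^k / gamma(beta * k + 1)
      total <- total + term
      if (k > 0 && abs(term) < 1e-16) break
    }
    total
  }, numeric(1))
}

# Adaptive quadrature wrapper: abs/rel tolerance 1e-10, zero-width intervals
# short-circuited, direction handled by sign flip.
adapt_quad <- function(fun, lower, upper, tol = 1e-10) {
  if (lower == upper) return(0)
  sgn <- 1
  if (lower > upper) { tmp <- lower; lower <- upper; upper <- tmp; sgn <- -1 }
  res <- tryCatch(
    stats::integrate(function(x) vapply(x, function(xx) fun(xx)[1],
                                        numeric(1)),
                     lower, upper, rel.tol = tol, abs.tol = tol,
                     subdivisions = 400L),
    error = function(e)
      stop("quadrature failed on [", lower, ", ", upper, "]: ",
           conditionMessage(e), call. = FALSE)
  )
  sgn * res$value
}
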