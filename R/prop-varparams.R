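#' Damped mass-spring parameters under the proportional derivative
#'
#' The forced oscillator
#' \eqn{m\,D^\alpha_P D^\alpha_P y + 2b\,D^\alpha_P y + k y = g(t)}
#' (note the damping constant is \eqn{2b}). The auxiliary equation
#' \eqn{m\lambda^2 + 2b\lambda + k = 0} classifies the homogeneous
#' behaviour by the sign of \eqn{mk - b^2}: overdamped (\eqn{mk < b^2}),
#' critically damped (\eqn{mk = b^2}) or underdamped (\eqn{mk > b^2}).
#'
#' @param m Mass, \code{> 0}.
#' @param b Half the damping constant, \code{> 0}.
#' @param k Spring constant, \code{> 0}.
#' @param alpha Proportional order, \code{0 < alpha <= 1}.
#' @return An object of class \code{"mass_spring_params"}.
#' @export
mass_spring_params <- function(m, b, k, alpha = 1) {
  stopifnot(m > 0, b > 0, k > 0, alpha > 0, alpha <= 1)
  case <- if (m * k < b^2) "overdamped"
          else if (m * k == b^2) "critical" else "underdamped"
  structure(list(m = m, b = b, k = k, alpha = alpha, case = case),
            class = "mass_spring_params")
}

#' @export
print.mass_spring_params <- function(x, ...) {
  cat("<mass_spring_params> m =", x$m, " 2b =", 2 * x$b, " k =", x$k,
      " alpha =", format(x$alpha), " (", x$case, ")\n")
  invisible(x)
}

#' Homogeneous basis of the proportional mass-spring equation
#'
#' Returns the case-appropriate fundamental pair \eqn{\{y_1, y_2\}} of
#' \eqn{m\,D^\alpha_P D^\alpha_P y + 2b\,D^\alpha_P y + k y = 0}. Each
#' root \eqn{\lambda} of the auxiliary equation yields the proportional
#' exponential \eqn{e_\lambda(t, 0) = \exp((\lambda - (1-\alpha))t/\alpha)}
#' (an eigenfunction with eigenvalue \eqn{\lambda}); the underdamped pair is
#' \deqn{e^{\mu t}\cos(\omega_\alpha t), \quad e^{\mu t}\sin(\omega_\alpha t),
#'   \qquad \mu = \frac{-b - (1-\alpha)m}{m\alpha}, \quad
#'   \omega_\alpha = \frac{\sqrt{mk - b^2}}{m\alpha}}
#' (both the decay and the frequency carry the \eqn{1/\alpha} scaling of
#' the proportional exponential; this is the form whose p-Wronskian has the
#' closed form \eqn{(\sqrt{mk-b^2}/m)\,e^{2(-b-m+\alpha m)t/(m\alpha)}}).
#'
#' @param params A [mass_spring_params()].
#' @return An object of class \code{"homogeneous_basis"}: list with
#'   \code{case}, the functions \code{y1, y2}, their classical derivatives
#'   \code{y1p, y2p, y1pp, y2pp}, and their proportional derivatives
#'   \code{dy1, dy2}.
#' @export
homogeneous_basis <- function(params) {
  stopifnot(inherits(params, "mass_spring_params"))
  m <- params$m; b <- params$b; k <- params$k; alpha <- params$alpha
  prop_d <- function(y, yp) function(t) (1 - alpha) * y(t) + alpha * yp(t)
  if (params$case == "overdamped") {
    lam <- c((-b + sqrt(b^2 - m * k)) / m, (-b - sqrt(b^2 - m * k)) / m)
    th <- (lam - (1 - alpha)) / alpha
    y1 <- function(t) exp(th[1L] * t); y2 <- function(t) exp(th[2L] * t)
    y1p <- function(t) th[1L] * y1(t); y2p <- function(t) th[2L] * y2(t)
    y1pp <- function(t) th[1L]^2 * y1(t)
    y2pp <- function(t) th[2L]^2 * y2(t)
  } else if (params$case == "critical") {
    th0 <- (-b / m - (1 - alpha)) / alpha
    y1 <- function(t) exp(th0 * t)
    y2 <- function(t) (t / alpha) * exp(th0 * t)
    y1p <- function(t) th0 * y1(t)
    y2p <- function(t) y1(t) / alpha + th0 * y2(t)
    y1pp <- function(t) th0^2 * y1(t)
    y2pp <- function(t) 2 * th0 * y1(t) / alpha + th0^2 * y2(t)
  } else {
    mu <- (-b - (1 - alpha) * m) / (m * alpha)
    om <- sqrt(m * k - b^2) / (m * alpha)
    y1 <- function(t) exp(mu * t) * cos(om * t)
    y2 <- function(t) exp(mu * t) * sin(om * t)
    y1p <- function(t) mu * y1(t) - om * y2(t)
    y2p <- function(t) mu * y2(t) + om * y1(t)
    y1pp <- function(t) mu * y1p(t) - om * y2p(t)
    y2pp <- function(t) mu * y2p(t) + om * y1p(t)
  }
  structure(list(case = params$case, alpha = alpha, params = params,
                 y1 = y1, y2 = y2, y1p = y1p, y2p = y2p,
                 y1pp = y1pp, y2pp = y2pp,
                 dy1 = prop_d(y1, y1p), dy2 = prop_d(y2, y2p)),
            class = "homogeneous_basis")
}

#' Proportional Wronskian
#'
#' \eqn{W_p(y_1, y_2)(t) = y_1 D^\alpha_P y_2 - y_2 D^\alpha_P y_1}. With
#' the linear kappa pair the \eqn{(1-\alpha)} terms cancel, so
#' \eqn{W_p = \alpha (y_1 y_2' - y_2 y_1')}, i.e. alpha times the classical
#' Wronskian.
#'
#' @param y1,y2 Differentiable functions of time.
#' @param alpha Proportional order.
#' @param t Evaluation time(s).
#' @param dy1,dy2 Optional analytic classical derivatives of
#'   \code{y1, y2}; finite differences are used when omitted.
#' @return Numeric vector of p-Wronskian values.
#' @export
p_wronskian <- function(y1, y2, alpha, t, dy1 = NULL, dy2 = NULL) {
  if (is.null(dy1)) dy1 <- function(tt) num_deriv(y1, tt)
  if (is.null(dy2)) dy2 <- function(tt) num_deriv(y2, tt)
  v <- function(f, tt) vapply(tt, f, numeric(1))
  alpha * (v(y1, t) * v(dy2, t) - v(y2, t) * v(dy1, t))
}

classical_wronskian <- function(basis, t)
  basis$y1(t) * basis$y2p(t) - basis$y2(t) * basis$y1p(t)

#' Particular solution by proportional variation of parameters
#'
#' Seeks \eqn{y_p = \gamma_1 y_1 + \gamma_2 y_2} with
#' \deqn{\gamma_1' = \frac{-y_2\, g}{\alpha^2 W}, \qquad
#'       \gamma_2' = \frac{y_1\, g}{\alpha^2 W},}
#' where \eqn{W} is the classical Wronskian of the basis (linear kappa
#' choice). The coefficients are integrated from \code{t0} by adaptive
#' quadrature, so \eqn{y_p(t_0) = 0} and \eqn{D^\alpha_P y_p(t_0) = 0}.
#'
#' @param basis A [homogeneous_basis()].
#' @param g Forcing function of time.
#' @param alpha Proportional order (must match the basis).
#' @param t0 Lower integration limit.
#' @param t Evaluation time(s) for the returned samples.
#' @return An object of class \code{"particular_solution"}: functions
#'   \code{gamma1, gamma2, y_p} plus the samples \code{y_p(t)} in
#'   \code{values}.
#' @export
variation_of_parameters_particular <- function(basis, g, alpha, t0, t) {
  stopifnot(inherits(basis, "homogeneous_basis"))
  if (abs(alpha - basis$alpha) > 1e-12)
    stop("'alpha' must match the basis", call. = FALSE)
  Wfun <- function(tt) classical_wronskian(basis, tt)
  chk <- Wfun(seq(min(t0, t), max(t0, t), length.out = 41))
  if (any(abs(chk) < 1e-14))
    stop("Wronskian vanishes on the interval: basis is degenerate there",
         call. = FALSE)
  g1p <- function(tt) -basis$y2(tt) * g(tt) / (alpha^2 * Wfun(tt))
  g2p <- function(tt) basis$y1(tt) * g(tt) / (alpha^2 * Wfun(tt))
  gamma1 <- function(tt) vapply(tt, function(x) adapt_quad(g1p, t0, x),
                                numeric(1))
  gamma2 <- function(tt) vapply(tt, function(x) adapt_quad(g2p, t0, x),
                                numeric(1))
  y_p <- function(tt) gamma1(tt) * basis$y1(tt) + gamma2(tt) * basis$y2(tt)
  structure(list(gamma1 = gamma1, gamma2 = gamma2,
                 gamma1_prime = g1p, gamma2_prime = g2p,
                 y_p = y_p, values = y_p(t), t = t,
                 basis = basis, g = g, alpha = alpha, t0 = t0),
            class = "particular_solution")
}

#' Solve the forced proportional mass-spring equation
#'
#' General solution \eqn{y = c_1 y_1 + c_2 y_2 + y_p} with \eqn{(c_1, c_2)}
#' fixed by the initial displacement \code{y0} and the initial
#' proportional-derivative value \code{Dy0} at \code{t_grid[1]} (using the
#' proportional derivative for the initial slope makes \eqn{\alpha = 1}
#' reduce to the standard classical IVP). The variation-of-parameters
#' coefficients are integrated along the grid as an ODE system
#' (deSolve, tolerance 1e-10).
#'
#' @param params A [mass_spring_params()].
#' @param g Forcing function of time.
#' @param y0 Displacement at \code{t_grid[1]}.
#' @param Dy0 Proportional-derivative value \eqn{D^\alpha_P y} at
#'   \code{t_grid[1]}.
#' @param t_grid Increasing time grid.
#' @return An object of class \code{"mass_spring_solution"}: \code{t},
#'   \code{y}, constants \code{c1, c2}, the per-grid-point
#'   \code{gamma1, gamma2}, and the inputs.
#' @export
solve_mass_spring <- function(params, g, y0, Dy0, t_grid) {
  stopifnot(inherits(params, "mass_spring_params"),
            is.numeric(t_grid), length(t_grid) >= 1L,
            !is.unsorted(t_grid, strictly = TRUE))
  basis <- homogeneous_basis(params)
  alpha <- params$alpha
  t0 <- t_grid[1L]
  A <- matrix(c(basis$y1(t0), basis$dy1(t0),
                basis$y2(t0), basis$dy2(t0)), 2L, 2L)
  if (abs(det(A)) < 1e-12)
    stop("degenerate basis: singular initial-condition system",
         call. = FALSE)
  cc <- solve(A, c(y0, Dy0))
  Wfun <- function(tt) classical_wronskian(basis, tt)
  if (any(abs(Wfun(t_grid)) < 1e-14))
    stop("Wronskian vanishes on the grid", call. = FALSE)
  if (length(t_grid) > 1L) {
    out <- deSolve::ode(
      y = c(g1 = 0, g2 = 0), times = t_grid,
      func = function(t, y, p)
        list(c(-basis$y2(t) * g(t) / (alpha^2 * Wfun(t)),
               basis$y1(t) * g(t) / (alpha^2 * Wfun(t)))),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
    gamma1 <- unname(out[, "g1"]); gamma2 <- unname(out[, "g2"])
  } else {
    gamma1 <- gamma2 <- 0
  }
  y <- cc[1L] * basis$y1(t_grid) + cc[2L] * basis$y2(t_grid) +
    gamma1 * basis$y1(t_grid) + gamma2 * basis$y2(t_grid)
  structure(list(t = t_grid, y = y, c1 = cc[1L], c2 = cc[2L],
                 gamma1 = gamma1, gamma2 = gamma2, basis = basis,
                 params = params, g = g, y0 = y0, Dy0 = Dy0),
            class = "mass_spring_solution")
}

#' @export
print.mass_spring_solution <- function(x, ...) {
  cat("<mass_spring_solution>", x$params$case, " alpha =",
      format(x$params$alpha), "\n  ", length(x$t), "samples on [",
      format(min(x$t)), ",", format(max(x$t)), "]   c1 =",
      format(x$c1), " c2 =", format(x$c2), "\n")
  invisible(x)
}

#' Governing-equation residual of a mass-spring solution
#'
#' Evaluates \eqn{m\,D^{(2)\alpha}_P y + 2b\,D^\alpha_P y + k y - g(t)} on
#' the solution's grid, expanding the iterated proportional derivative as
#' \eqn{\alpha^2 y'' + 2\alpha(1-\alpha) y' + (1-\alpha)^2 y} and using the
#' analytic basis derivatives together with the stored
#' variation-of-parameters coefficients.
#'
#' @param solution A [solve_mass_spring()] result.
#' @return Numeric vector of residuals on \code{solution$t}.
#' @export
mass_spring_residual <- function(solution) {
  stopifnot(inherits(solution, "mass_spring_solution"))
  b <- solution$basis; p <- solution$params; alpha <- p$alpha
  t <- solution$t
  a1 <- solution$c1 + solution$gamma1
  a2 <- solution$c2 + solution$gamma2
  Wfun <- classical_wronskian(b, t)
  g1p <- -b$y2(t) * solution$g(t) / (alpha^2 * Wfun)
  g2p <- b$y1(t) * solution$g(t) / (alpha^2 * Wfun)
  y <- a1 * b$y1(t) + a2 * b$y2(t)
  yp <- a1 * b$y1p(t) + a2 * b$y2p(t)    # gamma' y terms vanish by Eq-style constraint
  ypp <- a1 * b$y1pp(t) + a2 * b$y2pp(t) + g1p * b$y1p(t) + g2p * b$y2p(t)
  D1 <- (1 - alpha) * y + alpha * yp
  D2 <- alpha^2 * ypp + 2 * alpha * (1 - alpha) * yp + (1 - alpha)^2 * y
  p$m * D2 + 2 * p$b * D1 + p$k * y - solution$g(t)
}
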