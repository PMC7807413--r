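#' Reformulate a local-derivative phase equation as a classical ODE
#'
#' Substituting the differentiable-function equivalence form of each local
#' derivative into the phase equation
#' \eqn{R\,D^\alpha V + V/C + P_m = P_{aw}} turns it into a first-order
#' classical ODE in \eqn{V(t)}:
#' \itemize{
#'   \item proportional: \eqn{V' = (K - V/C - R(1-\alpha)V)/(\alpha R)};
#'   \item conformable: \eqn{V' = (K - V/C)\,|t - o|^{\alpha-1}/R};
#'   \item truncated-M: \eqn{V' = \Gamma(\beta+1)(K - V/C)\,
#'     |t - o|^{\alpha-1}/R;}
#' }
#' with \eqn{K = P_d - P_m} (inspiration) or \eqn{-P_m} (expiration) and
#' \eqn{o} the derivative base point (0 for zero-anchored inspiration,
#' the phase anchor for the shifted expiration forms). The conformable/M
#' right-hand side is singular at \eqn{t = o} although the closed-form
#' solutions stay finite there; [integrate_oracle()] therefore integrates
#' those families in the warped time \eqn{u = \mathrm{sgn}(t-o)
#' |t-o|^\alpha/\alpha}, in which the equation is regular.
#'
#' @param params A [vent_params()].
#' @param Pm Residual pressure, cm H2O.
#' @param spec A [derivative_spec()].
#' @param phase \code{"inspiration"} or \code{"expiration"}.
#' @param origin Derivative base point for conformable/M (default 0 for
#'   inspiration, \code{tb} for expiration).
#' @return An object of class \code{"reformulated_ode"}: list with
#'   \code{rhs(t, V)}, the driving constant \code{K}, \code{origin},
#'   \code{spec}, \code{params} and a \code{singular_at_origin} flag.
#' @export
classical_reformulation <- function(params, Pm, spec, phase,
                                    origin = NULL) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec),
            phase %in% c("inspiration", "expiration"))
  K <- airway_pressure(params, phase) - Pm
  R <- params$R; C <- params$C; alpha <- spec$alpha
  if (is.null(origin))
    origin <- if (phase == "inspiration") 0 else params$tb
  rhs <- switch(spec$family,
    classical = function(t, V) (K - V / C) / R,
    proportional = function(t, V)
      (K - V / C - R * (1 - alpha) * V) / (alpha * R),
    conformable = function(t, V)
      (K - V / C) * abs(t - origin)^(alpha - 1) / R,
    truncated_M = function(t, V)
      gamma(spec$beta + 1) * (K - V / C) *
        abs(t - origin)^(alpha - 1) / R
  )
  structure(list(rhs = rhs, K = K, origin = origin, spec = spec,
                 params = params, phase = phase,
                 singular_at_origin =
                   spec$family %in% c("conformable", "truncated_M") &&
                   alpha < 1),
            class = "reformulated_ode")
}

#' Integrate a reformulated phase equation numerically
#'
#' High-order adaptive integration (deSolve, \code{lsoda}, rel/abs
#' tolerance \code{1e-10}) of a [classical_reformulation()]. The
#' conformable and truncated-M equations are integrated in the warped time
#' \eqn{u = \mathrm{sgn}(t-o)|t-o|^\alpha/\alpha}, where they reduce to the
#' regular linear ODE \eqn{dV/du = \Gamma(\beta+1)(K - V/C)/R}; the result
#' is reported back on the requested \code{t_grid}. Decreasing grids
#' (integration backwards from a terminal anchor) are supported.
#'
#' @param ode A [classical_reformulation()].
#' @param t0 Initial time (s).
#' @param V0 Initial volume (L).
#' @param t_grid Monotone time grid starting at \code{t0}.
#' @return Numeric vector of volumes on \code{t_grid}.
#' @export
integrate_oracle <- function(ode, t0, V0, t_grid) {
  stopifnot(inherits(ode, "reformulated_ode"))
  if (abs(t_grid[1L] - t0) > 1e-12)
    stop("t_grid must start at t0", call. = FALSE)
  if (length(t_grid) == 1L) return(V0)
  spec <- ode$spec
  warped <- spec$family %in% c("conformable", "truncated_M")
  # lsoda is markedly less accurate on decreasing time grids (terminal
  # anchors integrate backwards); orient every problem forward by negating
  # the independent variable when needed.
  run_forward <- function(x_grid, rhs) {
    flip <- x_grid[length(x_grid)] < x_grid[1L]
    xs <- if (flip) -x_grid else x_grid
    f <- if (flip) function(x, y, p) list(-rhs(-x, y[[1L]]))
         else function(x, y, p) list(rhs(x, y[[1L]]))
    out <- deSolve::ode(y = c(V = V0), times = xs, func = f,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    unname(out[, "V"])
  }
  if (!warped) return(run_forward(t_grid, ode$rhs))
  gam <- if (spec$family == "truncated_M") gamma(spec$beta + 1) else 1
  Rr <- ode$params$R; C <- ode$params$C; K <- ode$K
  u_grid <- signed_power(t_grid - ode$origin, spec$alpha) / spec$alpha
  if (any(duplicated(u_grid)))
    stop("degenerate warped grid (points coincide at the origin)",
         call. = FALSE)
  run_forward(u_grid, function(u, V) gam * (K - V / C) / Rr)
}

#' Maximum governing-equation residual of a candidate solution
#'
#' Evaluates \eqn{\max_t |R\,D^\alpha V(t) + V(t)/C + P_m - P_{aw}|} over
#' the grid, using the analytic derivative of a [phase_solution] (or a
#' user-supplied \code{fprime} for a plain function). The conformable/M
#' derivative is taken about the solution's warp origin (or the
#' \code{origin} argument for plain functions). Grid points within
#' \code{1e-9} of a singular origin are nudged away by \code{1e-9} of the
#' grid span, since the derivative weight is singular there while the
#' residual's limit is finite.
#'
#' @param solution A [phase_solution] or a function \code{V(t)}.
#' @param params A [vent_params()].
#' @param Pm Residual pressure, cm H2O.
#' @param spec A [derivative_spec()] (ignored for a [phase_solution],
#'   which carries its own family).
#' @param phase \code{"inspiration"} or \code{"expiration"}.
#' @param t_grid Evaluation grid.
#' @param fprime Analytic derivative for a plain-function
#'   \code{solution}; finite differences are used when omitted.
#' @param origin Derivative base point for a plain-function solution
#'   (default 0).
#' @return Maximum absolute residual, cm H2O.
#' @export
residual_check <- function(solution, params, Pm, spec = NULL, phase,
                           t_grid, fprime = NULL, origin = 0) {
  stopifnot(inherits(params, "vent_params"),
            phase %in% c("inspiration", "expiration"))
  Paw <- airway_pressure(params, phase)
  if (inherits(solution, "phase_solution")) {
    if (solution$warp_kind == "power") {
      span <- diff(range(t_grid))
      near <- abs(t_grid - solution$warp_origin) < 1e-9
      t_grid[near] <- solution$warp_origin +
        sign(t_grid[near] - solution$warp_origin + .Machine$double.eps) *
          1e-9 * max(span, 1)
    }
    D <- evaluate_local_deriv(solution, t_grid)
    V <- evaluate_volume(solution, t_grid)
  } else {
    stopifnot(is.function(solution), is_derivative_spec(spec))
    if (spec$family %in% c("conformable", "truncated_M")) {
      span <- diff(range(t_grid))
      near <- abs(t_grid - origin) < 1e-9
      t_grid[near] <- origin +
        sign(t_grid[near] - origin + .Machine$double.eps) *
          1e-9 * max(span, 1)
    }
    D <- eval_local_derivative(solution, spec, t_grid, fprime = fprime,
                               origin = origin)
    V <- vapply(t_grid, solution, numeric(1))
  }
  max(abs(params$R * D + V / params$C + Pm - Paw))
}
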