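#' Closed-form volume trajectory for one breath phase
#'
#' Every closed-form solution of the single-compartment model, for every
#' derivative family, is an exponential relaxation in a (possibly warped)
#' time coordinate:
#' \deqn{V(t) = V_\infty + (V_0 - V_\infty)\,
#'   e^{-\lambda\,(w(t) - w(t_0))},}
#' where \eqn{w(t) = t} for the classical and proportional families and
#' \eqn{w(t) = \mathrm{sgn}(t - o)\,|t - o|^{\alpha}/\alpha} (signed power
#' about the warp origin \eqn{o}) for the conformable and truncated-M
#' families. The signed power is the unique continuous branch of
#' \eqn{(t - o)^\alpha} that recovers the classical limit at
#' \eqn{\alpha = 1} and yields decaying expiration curves for \eqn{t < o}.
#' The truncated-M rate carries the extra factor \eqn{\Gamma(\beta + 1)}.
#'
#' Objects are created by the solver functions
#' ([inspiration_solution()], [expiration_solution()],
#' [solve_linear_phase_ltp()], ...), not directly by users.
#'
#' @param family,alpha,beta Derivative family and orders.
#' @param phase \code{"inspiration"}, \code{"expiration"} or \code{NA}.
#' @param V_inf Asymptotic volume (L).
#' @param V0,t0 Anchor volume (L) and time (s); \code{evaluate_volume}
#'   returns exactly \code{V0} at \code{t0}.
#' @param rate Relaxation rate \eqn{\lambda} (1/s for identity warp,
#'   1/s^alpha-scaled otherwise).
#' @param warp_kind \code{"identity"} or \code{"power"}.
#' @param warp_origin Base point \eqn{o} of the power warp (and of the
#'   shifted conformable/M derivative the solution satisfies).
#' @return An object of class \code{"phase_solution"}.
#' @name phase_solution
#' @export
phase_solution <- function(family, alpha, beta, phase, V_inf, V0, t0,
                           rate, warp_kind, warp_origin) {
  stopifnot(warp_kind %in% c("identity", "power"))
  structure(list(family = family, alpha = alpha, beta = beta,
                 phase = phase, V_inf = V_inf, V0 = V0, t0 = t0,
                 rate = rate, warp_kind = warp_kind,
                 warp_origin = warp_origin),
            class = "phase_solution")
}

#' @export
print.phase_solution <- function(x, ...) {
  cat("<phase_solution>", x$family,
      if (!is.na(x$phase)) paste0("(", x$phase, ")"), "\n")
  cat("  alpha =", format(x$alpha))
  if (!is.na(x$beta)) cat("  beta =", format(x$beta))
  cat("\n  V_inf =", format(x$V_inf), "L   anchor V(",
      format(x$t0), ") =", format(x$V0), "L   rate =", format(x$rate), "\n")
  invisible(x)
}

# sgn(x) * |x|^a : continuous signed power used by the conformable/M warp
signed_power <- function(x, a) sign(x) * abs(x)^a

warp_value <- function(sol, t) {
  if (sol$warp_kind == "identity") t
  else signed_power(t - sol$warp_origin, sol$alpha) / sol$alpha
}

# d/dt of warp_value; |x|^(a-1) for the power warp (infinite at the origin
# when alpha < 1 -- the closed-form volume stays finite there)
warp_deriv <- function(sol, t) {
  if (sol$warp_kind == "identity") rep(1, length(t))
  else abs(t - sol$warp_origin)^(sol$alpha - 1)
}

#' Evaluate a phase solution
#'
#' @param solution A [phase_solution].
#' @param t Time(s), seconds.
#' @return Volume(s), litres.
#' @export
evaluate_volume <- function(solution, t) {
  stopifnot(inherits(solution, "phase_solution"))
  dw <- warp_value(solution, t) - warp_value(solution, solution$t0)
  solution$V_inf + (solution$V0 - solution$V_inf) *
    exp(-solution$rate * dw)
}

#' Classical time derivative dV/dt of a phase solution
#'
#' Analytic chain-rule derivative; infinite at the warp origin for the
#' conformable/M families with \code{alpha < 1} (the local-derivative
#' combination \eqn{|t-o|^{1-\alpha} V'(t)} remains finite there).
#'
#' @inheritParams evaluate_volume
#' @return dV/dt in L/s.
#' @export
evaluate_volume_deriv <- function(solution, t) {
  stopifnot(inherits(solution, "phase_solution"))
  dw <- warp_value(solution, t) - warp_value(solution, solution$t0)
  (solution$V0 - solution$V_inf) * (-solution$rate) *
    warp_deriv(solution, t) * exp(-solution$rate * dw)
}

#' Family derivative of a phase solution
#'
#' Evaluates the local derivative the solution's model equation uses:
#' proportional \eqn{(1-\alpha)V + \alpha V'}, conformable
#' \eqn{|t - o|^{1-\alpha} V'}, truncated-M the same over
#' \eqn{\Gamma(\beta+1)}, with \eqn{o} the solution's warp origin. For the
#' power-warped families the singular factors cancel analytically, so the
#' value is finite everywhere including the anchor.
#'
#' @inheritParams evaluate_volume
#' @return Derivative values (L/s, family-scaled).
#' @export
evaluate_local_deriv <- function(solution, t) {
  stopifnot(inherits(solution, "phase_solution"))
  V <- evaluate_volume(solution, t)
  if (solution$warp_kind == "identity") {
    Vp <- evaluate_volume_deriv(solution, t)
    w1 <- if (solution$family == "proportional") 1 - solution$alpha else 0
    w0 <- if (solution$family == "proportional") solution$alpha else 1
    w1 * V + w0 * Vp
  } else {
    # |t-o|^(1-a) * V'(t): the weight cancels warp_deriv exactly
    gam <- if (solution$family == "truncated_M") gamma(solution$beta + 1)
           else 1
    dw <- warp_value(solution, t) - warp_value(solution, solution$t0)
    (solution$V0 - solution$V_inf) * (-solution$rate / gam) *
      exp(-solution$rate * dw)
  }
}
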