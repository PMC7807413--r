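#' Ventilator and lung parameters
#'
#' Constants of the single-compartment pressure-volume controlled model:
#' airway resistance \code{R} (cm H2O s/L), lung compliance \code{C}
#' (L/cm H2O), ventilator driving pressure \code{Pd} (cm H2O, applied during
#' inspiration, zero during expiration), inspiratory time \code{tj} (s) and
#' breath length \code{tb} (s). Defaults are the reference setting
#' R = 10, C = 0.02, Pd = 20, tj = 1, tb = 3.
#'
#' @param R,C,Pd,tj,tb See description.
#' @return An object of class \code{"vent_params"}.
#' @export
#' @examples
#' vent_params()
vent_params <- function(R = 10, C = 0.02, Pd = 20, tj = 1, tb = 3) {
  stopifnot(is.numeric(R), R > 0, is.numeric(C), C > 0,
            is.numeric(tj), tj > 0, is.numeric(tb), tb > tj,
            is.numeric(Pd), Pd >= 0)
  structure(list(R = R, C = C, Pd = Pd, tj = tj, tb = tb),
            class = "vent_params")
}

#' @export
print.vent_params <- function(x, ...) {
  cat("<vent_params> R =", x$R, "cmH2O.s/L  C =", x$C, "L/cmH2O  Pd =",
      x$Pd, "cmH2O  tj =", x$tj, "s  tb =", x$tb, "s\n")
  invisible(x)
}

#' Residual-pressure policy
#'
#' How the constant residual pressure Pm is chosen:
#' \describe{
#'   \item{\code{classical_formula}}{the alpha-independent formula
#'     \eqn{P_m = P_d (e^{t_j/RC} - 1)/(e^{t_b/RC} - 1)}, derived from the
#'     classical model's end-of-breath condition \eqn{V_e(t_b) = 0} and used
#'     as-is for every family and order (the convention of the reference
#'     figures);}
#'   \item{\code{self_consistent}}{the Pm that enforces
#'     \eqn{V_i(t_j) = V_e(t_j)} for the chosen family and order, so the
#'     breath is exactly volume-continuous and empties at \eqn{t_b};}
#'   \item{\code{explicit}}{a user-supplied value.}
#' }
#'
#' @param mode One of the three modes.
#' @param value Pm in cm H2O, required (and \code{>= 0}) for
#'   \code{"explicit"}.
#' @return An object of class \code{"residual_policy"}.
#' @export
residual_policy <- function(mode = c("classical_formula", "self_consistent",
                                     "explicit"),
                            value = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L ||
        value < 0)
      stop("explicit mode requires a single value >= 0", call. = FALSE)
  } else if (!is.null(value)) {
    stop("'value' is only used with mode = \"explicit\"", call. = FALSE)
  }
  structure(list(mode = mode, value = value), class = "residual_policy")
}

# family-specific relaxation rate constant lambda_f for conformable/M
family_rate <- function(params, spec) {
  CR <- params$C * params$R
  switch(spec$family,
    conformable = 1 / CR,
    truncated_M = gamma(spec$beta + 1) / CR,
    stop("family_rate is only defined for conformable/truncated_M")
  )
}

# proportional decay rate lambda and denominator D = 1 + CR - alpha*CR
prop_rate <- function(params, alpha) {
  CR <- params$C * params$R
  D <- 1 + CR - alpha * CR
  list(D = D, lambda = D / (alpha * CR))
}

#' Residual pressure
#'
#' @param params A [vent_params()].
#' @param spec A [derivative_spec()] (used by the self-consistent mode).
#' @param policy A [residual_policy()]; default \code{classical_formula}.
#' @return Pm in cm H2O.
#' @export
#' @examples
#' residual_pressure(vent_params(), derivative_spec("classical"))
residual_pressure <- function(params, spec,
                              policy = residual_policy("classical_formula")) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec),
            inherits(policy, "residual_policy"))
  if (policy$mode == "explicit") return(policy$value)
  CR <- params$C * params$R
  if (policy$mode == "classical_formula")
    return(params$Pd * (exp(params$tj / CR) - 1) /
             (exp(params$tb / CR) - 1))
  # self_consistent: enforce Vi(tj) = Ve(tj) for the chosen family
  if (spec$family %in% c("classical", "proportional")) {
    lambda <- if (spec$family == "classical") 1 / CR
              else prop_rate(params, spec$alpha)$lambda
    params$Pd * (exp(lambda * params$tj) - 1) /
      (exp(lambda * params$tb) - 1)
  } else {
    lf <- family_rate(params, spec)
    u <- lf * params$tj^spec$alpha / spec$alpha
    v <- lf * (params$tb - params$tj)^spec$alpha / spec$alpha
    params$Pd * (1 - exp(-u)) / (exp(v) - exp(-u))
  }
}

#' Inspiration-phase volume solution, anchored at V(0) = 0
#'
#' Closed-form solution of \eqn{R\,D^\alpha V_i + V_i/C + P_m = P_d} on
#' \eqn{[0, t_j]} with \eqn{V_i(0) = 0}:
#' \itemize{
#'   \item proportional: \eqn{V_\infty = C(P_d - P_m)/(1 + CR - \alpha CR)},
#'     rate \eqn{\lambda = (1 + CR - \alpha CR)/(\alpha CR)}, identity warp;
#'   \item conformable: \eqn{V_\infty = C(P_d - P_m)}, rate \eqn{1/(CR)},
#'     warp \eqn{t^\alpha/\alpha};
#'   \item truncated-M: as conformable with rate
#'     \eqn{\Gamma(\beta+1)/(CR)}.
#' }
#'
#' @param params A [vent_params()].
#' @param Pm Residual pressure, cm H2O (see [residual_pressure()]).
#' @param spec A [derivative_spec()].
#' @return A [phase_solution].
#' @export
inspiration_solution <- function(params, Pm, spec) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec))
  if (Pm >= params$Pd)
    warning("Pm >= Pd: lung does not fill during inspiration")
  C <- params$C
  if (spec$family %in% c("classical", "proportional")) {
    alpha <- spec$alpha
    pr <- prop_rate(params, alpha)
    phase_solution(spec$family, alpha, spec$beta, "inspiration",
                   V_inf = C * (params$Pd - Pm) / pr$D,
                   V0 = 0, t0 = 0, rate = pr$lambda,
                   warp_kind = "identity", warp_origin = 0)
  } else {
    phase_solution(spec$family, spec$alpha, spec$beta, "inspiration",
                   V_inf = C * (params$Pd - Pm),
                   V0 = 0, t0 = 0, rate = family_rate(params, spec),
                   warp_kind = "power", warp_origin = 0)
  }
}

#' Expiration-phase volume solution, anchored at V(tb) = 0
#'
#' Closed-form solution of \eqn{R\,D^\alpha V_e + V_e/C + P_m = 0} on
#' \eqn{[t_j, t_b]} with \eqn{V_e(t_b) = 0}. For the conformable and
#' truncated-M families the derivative (and warp) is based at \eqn{t_b}
#' with the signed-power convention, so the curve decays towards \eqn{t_b}
#' and the \eqn{\alpha = 1} limit is the classical
#' \eqn{C P_m (e^{(t_b - t)/RC} - 1)}.
#'
#' @inheritParams inspiration_solution
#' @return A [phase_solution].
#' @export
expiration_solution <- function(params, Pm, spec) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec))
  C <- params$C
  if (spec$family %in% c("classical", "proportional")) {
    pr <- prop_rate(params, spec$alpha)
    phase_solution(spec$family, spec$alpha, spec$beta, "expiration",
                   V_inf = -C * Pm / pr$D,
                   V0 = 0, t0 = params$tb, rate = pr$lambda,
                   warp_kind = "identity", warp_origin = params$tb)
  } else {
    phase_solution(spec$family, spec$alpha, spec$beta, "expiration",
                   V_inf = -C * Pm,
                   V0 = 0, t0 = params$tb, rate = family_rate(params, spec),
                   warp_kind = "power", warp_origin = params$tb)
  }
}

#' Inspiration solution anchored at the tidal volume, V(tj) = VT
#'
#' The corrected closed form
#' \eqn{V(t) = V_\infty + (V_T - V_\infty)\, e^{-\lambda (w(t) - w(t_j))}}
#' with the same \eqn{V_\infty}, rate and warp as [inspiration_solution()].
#' The historically printed tidal-anchored inspiration formulas fail their
#' own anchor condition (they give \eqn{V_T \pm 2 V_\infty} at
#' \eqn{t = t_j}); set \code{verbatim = TRUE} to obtain those printed forms
#' as a plain function of t, retained for documentation tests only.
#'
#' @inheritParams inspiration_solution
#' @param VT Tidal volume, L (\code{>= 0}).
#' @param verbatim Return the uncorrected printed formula as a function?
#' @return A [phase_solution], or a function of \code{t} when
#'   \code{verbatim = TRUE}.
#' @export
inspiration_solution_from_tidal <- function(params, Pm, VT, spec,
                                            verbatim = FALSE) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec),
            VT >= 0)
  C <- params$C; R <- params$R; Pd <- params$Pd; tj <- params$tj
  if (verbatim) {
    if (spec$family %in% c("classical", "proportional")) {
      alpha <- spec$alpha
      pr <- prop_rate(params, alpha)
      return(function(t) {
        num <- alpha * C * R * Pd - alpha * C * R * Pm - alpha * R * VT -
          alpha * C * R^2 * VT + alpha^2 * C * R^2 * VT
        C * (Pd - Pm) / (-pr$D) +
          exp(-pr$lambda * (t - tj)) * num / (alpha * R * (-pr$D))
      })
    }
    lf <- family_rate(params, spec)
    alpha <- spec$alpha
    return(function(t)
      C * (Pd - Pm) +
        exp(-lf * signed_power(t - tj, alpha) / alpha) *
          (C * (Pd - Pm) + VT))
  }
  base <- inspiration_solution(params, Pm, spec)
  base$V0 <- VT
  base$t0 <- tj
  base
}

#' Expiration solution anchored at the tidal volume, V(tj) = VT
#'
#' Proportional:
#' \eqn{V(t) = -CP_m/D + (V_T + CP_m/D)\, e^{-\lambda (t - t_j)}} with
#' \eqn{D = 1 + CR - \alpha CR} (algebraically identical to the printed
#' transform-domain result, retrievable with \code{verbatim = TRUE});
#' conformable/truncated-M:
#' \eqn{V(t) = -CP_m + (CP_m + V_T)\, e^{-\lambda_f (t-t_j)^\alpha/\alpha}},
#' i.e. derivative and warp based at \eqn{t_j}.
#'
#' @inheritParams inspiration_solution_from_tidal
#' @return A [phase_solution], or a function of \code{t} when
#'   \code{verbatim = TRUE}.
#' @export
expiration_solution_from_tidal <- function(params, Pm, VT, spec,
                                           verbatim = FALSE) {
  stopifnot(inherits(params, "vent_params"), is_derivative_spec(spec),
            VT >= 0)
  C <- params$C; R <- params$R; tj <- params$tj
  if (verbatim) {
    if (spec$family %in% c("classical", "proportional")) {
      alpha <- spec$alpha
      pr <- prop_rate(params, alpha)
      return(function(t) {
        E <- exp(-pr$lambda * (t - tj))
        E * (-C * Pm + C * Pm / E - VT - C * R * VT +
               alpha * C * R * VT) / (-pr$D)
      })
    }
    lf <- family_rate(params, spec)
    alpha <- spec$alpha
    return(function(t)
      -C * Pm + exp(-lf * signed_power(t - tj, alpha) / alpha) *
        (C * Pm + VT))
  }
  if (spec$family %in% c("classical", "proportional")) {
    pr <- prop_rate(params, spec$alpha)
    phase_solution(spec$family, spec$alpha, spec$beta, "expiration",
                   V_inf = -C * Pm / pr$D,
                   V0 = VT, t0 = tj, rate = pr$lambda,
                   warp_kind = "identity", warp_origin = tj)
  } else {
    phase_solution(spec$family, spec$alpha, spec$beta, "expiration",
                   V_inf = -C * Pm,
                   V0 = VT, t0 = tj, rate = family_rate(params, spec),
                   warp_kind = "power", warp_origin = tj)
  }
}

#' Tidal volume
#'
#' The lung volume at the inspiration-to-expiration switch,
#' \eqn{V_T = V_i(t_j)} from the zero-anchored inspiration solution.
#'
#' @inheritParams inspiration_solution
#' @return Volume in L.
#' @export
tidal_volume <- function(params, Pm, spec) {
  evaluate_volume(inspiration_solution(params, Pm, spec), params$tj)
}

#' Mean alveolar pressure
#'
#' Average elastic pressure in the lung during inspiration plus the
#' residual pressure:
#' \eqn{P_{ma} = \frac{1}{C t_j} \int_0^{t_j} V_i(t)\,dt + P_m}.
#' Computed by adaptive quadrature of the closed-form inspiration solution;
#' for the classical/proportional families a closed-form antiderivative is
#' available as a cross-check.
#'
#' @inheritParams inspiration_solution
#' @param method \code{"quadrature"} (default, all families) or
#'   \code{"closed_form"} (classical/proportional only).
#' @return Pressure in cm H2O.
#' @export
mean_alveolar_pressure <- function(params, Pm, spec,
                                   method = c("quadrature", "closed_form")) {
  method <- match.arg(method)
  sol <- inspiration_solution(params, Pm, spec)
  tj <- params$tj
  if (method == "closed_form") {
    if (sol$warp_kind != "identity")
      stop("closed_form is only available for classical/proportional",
           call. = FALSE)
    A <- sol$V0 - sol$V_inf
    intV <- sol$V_inf * tj + A / sol$rate * (1 - exp(-sol$rate * tj)) *
      exp(sol$rate * sol$t0)  # t0 = 0 here, factor kept for clarity
  } else {
    intV <- adapt_quad(function(t) evaluate_volume(sol, t), 0, tj)
  }
  intV / (params$C * tj) + Pm
}

#' Airway pressure applied by the ventilator
#'
#' \code{Pd} during inspiration, 0 during expiration.
#' @inheritParams inspiration_solution
#' @param phase \code{"inspiration"} or \code{"expiration"}.
#' @return Pressure in cm H2O.
#' @export
airway_pressure <- function(params, phase) {
  stopifnot(phase %in% c("inspiration", "expiration"))
  if (phase == "inspiration") params$Pd else 0
}
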