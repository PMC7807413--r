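#' Derivative specification
#'
#' Describes which local derivative family an operation should use and its
#' order parameters. Four families are supported:
#' \describe{
#'   \item{\code{classical}}{the ordinary first derivative \eqn{f'(t)};}
#'   \item{\code{proportional}}{the PD-controller combination
#'     \eqn{\kappa_1(\alpha,t) f(t) + \kappa_0(\alpha,t) f'(t)}, with the
#'     linear choice \eqn{\kappa_1 = 1-\alpha}, \eqn{\kappa_0 = \alpha} used
#'     throughout the shipped solvers;}
#'   \item{\code{conformable}}{\eqn{t^{1-\alpha} f'(t)} for \eqn{t > 0};}
#'   \item{\code{truncated_M}}{\eqn{t^{1-\alpha} f'(t) / \Gamma(\beta+1)},
#'     the truncated Mittag-Leffler dilation of the conformable derivative.}
#' }
#' At \eqn{\alpha = 1} every family reduces to the classical derivative
#' (the truncated-M family additionally needs \eqn{\beta} with
#' \eqn{\Gamma(\beta+1) = 1}, i.e. \eqn{\beta = 1}). The proportional family
#' alone admits \eqn{\alpha = 0}, where it becomes the identity operator.
#'
#' @param family One of \code{"classical"}, \code{"proportional"},
#'   \code{"conformable"}, \code{"truncated_M"}.
#' @param alpha Derivative order. Must satisfy \code{0 < alpha <= 1}
#'   (\code{0 <= alpha <= 1} for the proportional family; ignored and fixed
#'   at 1 for \code{"classical"}).
#' @param beta Mittag-Leffler parameter, required (and \code{> 0}) only for
#'   \code{family = "truncated_M"}.
#' @param kappa_choice Which \eqn{(\kappa_0, \kappa_1)} pair the proportional
#'   family uses. Only \code{"linear"} (\eqn{\kappa_1 = 1-\alpha},
#'   \eqn{\kappa_0 = \alpha}) is shipped.
#'
#' @return An object of class \code{"derivative_spec"}.
#' @seealso [eval_local_derivative()]
#' @export
#' @examples
#' derivative_spec("proportional", alpha = 0.8)
#' derivative_spec("truncated_M", alpha = 0.7, beta = 0.8)
derivative_spec <- function(family = c("classical", "proportional",
                                       "conformable", "truncated_M"),
                            alpha = 1, beta = NULL,
                            kappa_choice = "linear") {
  family <- match.arg(family)
  kappa_choice <- match.arg(kappa_choice, "linear")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite number", call. = FALSE)
  if (family == "classical") {
    alpha <- 1
  } else if (family == "proportional") {
    if (alpha < 0 || alpha > 1)
      stop("proportional derivative requires 0 <= alpha <= 1", call. = FALSE)
  } else {
    if (alpha <= 0 || alpha > 1)
      stop(sprintf("%s derivative requires 0 < alpha <= 1", family),
           call. = FALSE)
  }
  if (family == "truncated_M") {
    if (is.null(beta) || !is.numeric(beta) || length(beta) != 1L ||
        !is.finite(beta) || beta <= 0)
      stop("truncated_M requires a single beta > 0", call. = FALSE)
  } else {
    if (!is.null(beta))
      stop("'beta' is only meaningful for family = \"truncated_M\"",
           call. = FALSE)
    beta <- NA_real_
  }
  structure(
    list(family = family, alpha = alpha, beta = beta,
         kappa_choice = kappa_choice),
    class = "derivative_spec"
  )
}

#' @export
print.derivative_spec <- function(x, ...) {
  cat("<derivative_spec> family =", x$family,
      " alpha =", format(x$alpha), sep = " ")
  if (x$family == "truncated_M") cat("  beta =", format(x$beta))
  cat("\n")
  invisible(x)
}

#' @export
#' @rdname derivative_spec
is_derivative_spec <- function(x) inherits(x, "derivative_spec")

# Scale factor on f'(t) in the equivalence form of the family derivative,
# taken with respect to the shifted time t - origin for conformable/M
# (the convention needed by the breath-anchored expiration solutions).
deriv_weight <- function(spec, t, origin = 0) {
  switch(spec$family,
    classical    = rep(1, length(t)),
    proportional = rep(spec$alpha, length(t)),
    conformable  = abs(t - origin)^(1 - spec$alpha),
    truncated_M  = abs(t - origin)^(1 - spec$alpha) / gamma(spec$beta + 1)
  )
}

# Multiplier on f(t) itself (nonzero only for the proportional family).
deriv_f_weight <- function(spec, t) {
  if (spec$family == "proportional") rep(1 - spec$alpha, length(t))
  else rep(0, length(t))
}
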