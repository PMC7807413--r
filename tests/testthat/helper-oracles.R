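# Independent oracles used across the suite.

# --- limit-quotient derivative oracle -------------------------------------
# Evaluates the raw limit definition of the conformable / truncated-M /
# classical derivative on a geometric epsilon sequence and extrapolates to
# eps = 0 by Neville's scheme (error series is polynomial in eps).
limit_quotient_oracle <- function(f, family, alpha, t, beta = NULL,
                                  eps0 = 1e-3, ratio = 0.5, levels = 8L) {
  quot <- function(eps) {
    shifted <- switch(family,
      classical   = t + eps,
      conformable = t + eps * t^(1 - alpha),
      truncated_M = t * truncated_mittag_leffler(beta, eps * t^(-alpha), 12L)
    )
    (f(shifted) - f(t)) / eps
  }
  eps <- eps0 * ratio^(0:(levels - 1L))
  d <- vapply(eps, quot, numeric(1))
  # Neville extrapolation to eps = 0
  for (m in 1:(levels - 1L)) {
    for (i in 1:(levels - m)) {
      d[i] <- (eps[i] * d[i + 1L] - eps[i + m] * d[i]) /
        (eps[i] - eps[i + m])
    }
  }
  d[1L]
}

# --- exact rational arithmetic --------------------------------------------
# Rationals as c(num, den) with integer values stored in doubles (all
# quantities here stay far below 2^53, so arithmetic is exact).
rat <- function(num, den = 1) {
  if (den < 0) { num <- -num; den <- -den }
  g <- rat_gcd(abs(num), den)
  if (g > 0) c(num / g, den / g) else c(num, 1)
}
rat_gcd <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }
rat_add <- function(x, y) rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
rat_mul <- function(x, y) rat(x[1] * y[1], x[2] * y[2])
rat_eq <- function(x, y) x[1] == y[1] && x[2] == y[2]
rat_num <- function(x) x[1] / x[2]

# Rational polynomials: list of rationals, ascending powers.
rp <- function(...) list(...)
rp_zero <- function() list(rat(0))
rp_add <- function(p, q) {
  n <- max(length(p), length(q))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- if (i <= length(p)) p[[i]] else rat(0)
    b <- if (i <= length(q)) q[[i]] else rat(0)
    out[[i]] <- rat_add(a, b)
  }
  out
}
rp_scale <- function(p, s) lapply(p, function(cf) rat_mul(s, cf))
rp_mul <- function(p, q) {
  out <- rep(list(rat(0)), length(p) + length(q) - 1L)
  for (i in seq_along(p)) for (j in seq_along(q))
    out[[i + j - 1L]] <- rat_add(out[[i + j - 1L]],
                                 rat_mul(p[[i]], q[[j]]))
  out
}
rp_eq <- function(p, q) {
  n <- max(length(p), length(q))
  for (i in seq_len(n)) {
    a <- if (i <= length(p)) p[[i]] else rat(0)
    b <- if (i <= length(q)) q[[i]] else rat(0)
    if (!rat_eq(a, b)) return(FALSE)
  }
  TRUE
}
rp_numeric <- function(p) vapply(p, rat_num, numeric(1))

rat_pow <- function(x, n) {
  out <- rat(1)
  for (i in seq_len(n)) out <- rat_mul(out, x)
  out
}

# Direct n-fold transform rule in rational arithmetic (mirrors the closed
# formula used by lt_nth_order_rule).
rational_lt_rule <- function(n, a) {   # a = rat(p, q)
  one_m_a <- rat_add(rat(1), rat_mul(rat(-1), a))
  first <- rp(one_m_a, a)              # (1-a) + a*s
  mult <- first
  if (n > 1) for (i in 2:n) mult <- rp_mul(mult, first)
  boundary <- vector("list", n)
  for (k in 0:(n - 1L)) {
    b <- rp_zero()
    for (r in 0:(n - 1L - k)) {
      deg <- n - 1L - k - r
      cf <- rat_mul(rat(choose(n, r)),
                    rat_mul(rat_pow(a, deg), rat_pow(one_m_a, r)))
      term <- rep(list(rat(0)), deg + 1L)
      term[[deg + 1L]] <- cf
      b <- rp_add(b, term)
    }
    boundary[[k + 1L]] <- rp_scale(b, rat_pow(a, k + 1L))
  }
  list(n = n, multiplier = mult, boundary = boundary)
}

# Iterated first-order rule in rational arithmetic: apply
# L{D phi} = (a s + 1 - a) L{phi} - a phi(0) to the previous fold, using
# exact binomial weights for (D^(m) phi)(0).
rational_lt_compose <- function(rule, a) {
  one_m_a <- rat_add(rat(1), rat_mul(rat(-1), a))
  first <- rp(one_m_a, a)
  m <- rule$n
  mult <- rp_mul(first, rule$multiplier)
  boundary <- vector("list", m + 1L)
  for (k in 0:m) {
    prev <- if (k < m) rp_mul(first, rule$boundary[[k + 1L]])
            else rp_zero()
    r <- m - k
    w <- rat_mul(rat(choose(m, r)),
                 rat_mul(rat_pow(a, m - r), rat_pow(one_m_a, r)))
    boundary[[k + 1L]] <- rp_add(prev, rp(rat_mul(a, w)))
  }
  list(n = m + 1L, multiplier = mult, boundary = boundary)
}

# Exact n-fold application of the proportional derivative to a polynomial
# (coefficients ascending in t), in rational arithmetic:
# D phi = (1 - a) phi + a phi'.
rational_prop_derivative_poly <- function(coefs, a) {
  one_m_a <- rat_add(rat(1), rat_mul(rat(-1), a))
  n <- length(coefs)
  out <- rep(list(rat(0)), n)
  for (i in seq_len(n)) {
    out[[i]] <- rat_add(out[[i]], rat_mul(one_m_a, coefs[[i]]))
    if (i > 1L)
      out[[i - 1L]] <- rat_add(out[[i - 1L]],
                               rat_mul(a, rat_mul(rat(i - 1), coefs[[i]])))
  }
  out
}

rational_poly_eval <- function(coefs, t_rat) {
  acc <- rat(0); pw <- rat(1)
  for (cf in coefs) {
    acc <- rat_add(acc, rat_mul(cf, pw))
    pw <- rat_mul(pw, t_rat)
  }
  acc
}

# --- smooth random test functions -----------------------------------------
# Deterministic family of smooth functions with analytic derivatives,
# indexed by a coefficient vector.
make_smooth_fn <- function(coef) {
  f <- function(t) coef[1] * sin(coef[2] * t) + coef[3] * exp(coef[4] * t) +
    coef[5] * t^2 + coef[6]
  fp <- function(t) coef[1] * coef[2] * cos(coef[2] * t) +
    coef[3] * coef[4] * exp(coef[4] * t) + 2 * coef[5] * t
  list(f = f, fp = fp)
}

random_smooth_fns <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    make_smooth_fn(round(stats::runif(6, -2, 2), 3)))
}

# --- reference parameters --------------------------------------------------
ref_params <- function() vent_params(R = 10, C = 0.02, Pd = 20,
                                     tj = 1, tb = 3)
ref_pm_classical <- function() {
  p <- ref_params()
  p$Pd * (exp(p$tj / (p$R * p$C)) - 1) / (exp(p$tb / (p$R * p$C)) - 1)
}
fig_alpha_grid <- c(0.25, 0.45, 0.65, 0.7, 0.8, 0.9, 0.95, 1)
fig_beta_grid <- c(0.5, 0.8, 1, 1.2, 1.5)

all_family_specs <- function(alpha, beta = 0.8) {
  list(derivative_spec("proportional", alpha),
       derivative_spec("conformable", alpha),
       derivative_spec("truncated_M", alpha, beta = beta))
}

# 50-point oracle-integration grid for a variant: starts at the solution's
# own anchor, avoids the conformable/M coefficient singularity at the warp
# origin when the origin is interior to the phase.
oracle_grid <- function(v, spec) {
  sol <- v$sol
  ends <- range(v$grid)
  far <- if (abs(sol$t0 - ends[1]) > abs(sol$t0 - ends[2])) ends[1]
         else ends[2]
  if (spec$family != "proportional" && abs(far - sol$warp_origin) < 1e-12)
    far <- far + sign(sol$t0 - far) * 0.05
  seq(sol$t0, far, length.out = 50)
}

# The four anchored solution variants for one (family, alpha, beta)
solution_variants <- function(params, Pm, spec) {
  VT <- tidal_volume(params, Pm, spec)
  list(
    insp_zero  = list(sol = inspiration_solution(params, Pm, spec),
                      phase = "inspiration",
                      grid = seq(0, params$tj, length.out = 200)),
    exp_tb     = list(sol = expiration_solution(params, Pm, spec),
                      phase = "expiration",
                      grid = seq(params$tj, params$tb, length.out = 200)),
    insp_tidal = list(sol = inspiration_solution_from_tidal(params, Pm, VT,
                                                            spec),
                      phase = "inspiration",
                      grid = seq(0, params$tj, length.out = 200)),
    exp_tidal  = list(sol = expiration_solution_from_tidal(params, Pm, VT,
                                                           spec),
                      phase = "expiration",
                      grid = seq(params$tj, params$tb, length.out = 200))
  )
}
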