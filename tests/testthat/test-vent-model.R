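test_that("residual pressure: formula value, reductions, edge cases", {
  p <- ref_params()
  sp <- derivative_spec("proportional", 0.8)
  # Pd = 0 gives Pm = 0 in every mode
  p0 <- vent_params(Pd = 0)
  expect_identical(residual_pressure(p0, sp), 0)
  expect_identical(
    residual_pressure(p0, sp, residual_policy("self_consistent")), 0)
  # reference value: 20 (e^5 - 1)/(e^15 - 1)
  expect_equal(residual_pressure(p, sp),
               20 * (exp(5) - 1) / (exp(15) - 1), tolerance = 1e-14)
  expect_equal(residual_pressure(p, sp), 9.019e-4, tolerance = 1e-4)
  # self-consistent mode reduces to the formula at alpha = 1 (beta = 1),
  # including on randomly drawn parameter sets
  set.seed(5)
  for (i in 1:5) {
    pr <- vent_params(R = stats::runif(1, 2, 30),
                      C = stats::runif(1, 0.005, 0.1),
                      Pd = stats::runif(1, 5, 40),
                      tj = stats::runif(1, 0.5, 2),
                      tb = stats::runif(1, 2.5, 6))
    base <- residual_pressure(pr, derivative_spec("classical"))
    for (sp1 in list(derivative_spec("proportional", 1),
                     derivative_spec("conformable", 1),
                     derivative_spec("truncated_M", 1, beta = 1))) {
      expect_equal(
        residual_pressure(pr, sp1, residual_policy("self_consistent")),
        base, tolerance = 1e-12)
    }
  }
  # explicit policy passthrough and validation
  expect_identical(
    residual_pressure(p, sp, residual_policy("explicit", 2.5)), 2.5)
  expect_error(residual_policy("explicit"), "value")
  expect_error(residual_policy("classical_formula", 1), "explicit")
})

test_that("boundary anchors hold for every family and order", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  for (a in c(0.7, 0.8, 0.9, 1)) {
    for (spec in all_family_specs(a)) {
      expect_lt(abs(evaluate_volume(inspiration_solution(p, Pm, spec), 0)),
                1e-12)
      expect_lt(abs(evaluate_volume(expiration_solution(p, Pm, spec),
                                    p$tb)),
                1e-12)
      VT <- tidal_volume(p, Pm, spec)
      expect_equal(
        evaluate_volume(inspiration_solution_from_tidal(p, Pm, VT, spec),
                        p$tj), VT, tolerance = 1e-14)
      expect_equal(
        evaluate_volume(expiration_solution_from_tidal(p, Pm, VT, spec),
                        p$tj), VT, tolerance = 1e-14)
    }
  }
})

test_that("inspiration residuals stay tiny under the formula Pm", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  tg <- seq(0, p$tj, length.out = 100)
  for (a in c(0.25, 0.65, 0.9)) {
    for (spec in all_family_specs(a)) {
      expect_lt(residual_check(inspiration_solution(p, Pm, spec), p, Pm,
                               phase = "inspiration", t_grid = tg),
                1e-10)
    }
  }
})

test_that("alpha = 1 collapses every family onto the classical solution", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  CR <- p$R * p$C
  tg_i <- seq(0, p$tj, length.out = 101)
  tg_e <- seq(p$tj, p$tb, length.out = 101)
  classical_i <- p$C * (p$Pd - Pm) * (1 - exp(-tg_i / CR))
  classical_e <- p$C * Pm * (exp((p$tb - tg_e) / CR) - 1)
  for (spec in list(derivative_spec("classical"),
                    derivative_spec("proportional", 1),
                    derivative_spec("conformable", 1),
                    derivative_spec("truncated_M", 1, beta = 1))) {
    expect_lt(max(abs(evaluate_volume(inspiration_solution(p, Pm, spec),
                                      tg_i) - classical_i)), 1e-12)
    expect_lt(max(abs(evaluate_volume(expiration_solution(p, Pm, spec),
                                      tg_e) - classical_e)), 1e-12)
  }
  # asymptote: V(t -> inf) -> C (Pd - Pm) ~ 0.39998 L
  expect_equal(inspiration_solution(p, Pm,
                                    derivative_spec("proportional", 1))$V_inf,
               p$C * (p$Pd - Pm), tolerance = 1e-14)
  expect_equal(p$C * (p$Pd - Pm), 0.39998, tolerance = 1e-4)
  # at alpha = 1 with the formula Pm, expiration meets inspiration at tj
  expect_equal(
    evaluate_volume(expiration_solution(p, Pm,
                                        derivative_spec("classical")),
                    p$tj),
    tidal_volume(p, Pm, derivative_spec("classical")), tolerance = 1e-12)
})

test_that("tidal volume: value, degenerate driving, monotonicity in Pm", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  sp1 <- derivative_spec("classical")
  expect_equal(tidal_volume(p, Pm, sp1),
               p$C * (p$Pd - Pm) * (1 - exp(-5)), tolerance = 1e-14)
  expect_equal(tidal_volume(p, Pm, sp1), 0.3973, tolerance = 1e-3)
  expect_warning(vt0 <- tidal_volume(p, p$Pd, sp1), "does not fill")
  expect_equal(vt0, 0)
  for (spec in all_family_specs(0.8)) {
    pms <- seq(0, 10, length.out = 15)
    vts <- suppressWarnings(
      vapply(pms, function(pm) tidal_volume(p, pm, spec), numeric(1)))
    expect_true(all(diff(vts) <= 1e-14))
  }
})

test_that("mean alveolar pressure: closed form, quadrature, degenerate", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  sp1 <- derivative_spec("classical")
  # closed form (Pd - Pm)(1 - (RC/tj)(1 - e^(-tj/RC))) + Pm ~ 16.03
  CR <- p$R * p$C
  closed <- (p$Pd - Pm) * (1 - CR / p$tj * (1 - exp(-p$tj / CR))) + Pm
  expect_equal(mean_alveolar_pressure(p, Pm, sp1), closed,
               tolerance = 1e-9)
  expect_equal(closed, 16.03, tolerance = 1e-3)
  # Pd = Pm: the lung never inflates, so Pma = Pm exactly
  expect_equal(
    suppressWarnings(mean_alveolar_pressure(p, p$Pd, sp1)), p$Pd,
    tolerance = 1e-12)
  # quadrature vs closed-form antiderivative, proportional alpha = 0.8
  sp <- derivative_spec("proportional", 0.8)
  expect_equal(mean_alveolar_pressure(p, Pm, sp, "quadrature"),
               mean_alveolar_pressure(p, Pm, sp, "closed_form"),
               tolerance = 1e-9)
  expect_error(
    mean_alveolar_pressure(p, Pm, derivative_spec("conformable", 0.8),
                           "closed_form"),
    "classical/proportional")
})

test_that("printed tidal-anchored inspiration forms miss their anchor by 2 V_inf", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  for (spec in all_family_specs(0.8)) {
    VT <- tidal_volume(p, Pm, spec)
    verb <- inspiration_solution_from_tidal(p, Pm, VT, spec,
                                            verbatim = TRUE)
    V_inf <- inspiration_solution(p, Pm, spec)$V_inf
    expect_equal(abs(verb(p$tj) - VT), 2 * V_inf, tolerance = 1e-12)
    # ... and fail the governing equation near tj, unlike the corrected form
    tg <- seq(0.2, p$tj, length.out = 50)
    verb_resid <- residual_check(verb, p, Pm, spec, "inspiration", tg,
                                 origin = 0)
    expect_gt(verb_resid, 1)
    corr <- inspiration_solution_from_tidal(p, Pm, VT, spec)
    expect_lt(residual_check(corr, p, Pm, phase = "inspiration",
                             t_grid = tg), 1e-8)
  }
})

test_that("tidal-anchored expiration matches its printed transform result", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  set.seed(31)
  # proportional: corrected assembly is algebraically the printed formula
  for (i in 1:50) {
    a <- stats::runif(1, 0.2, 1)
    tt <- stats::runif(1, p$tj, p$tb)
    spec <- derivative_spec("proportional", a)
    VT <- tidal_volume(p, Pm, spec)
    corr <- expiration_solution_from_tidal(p, Pm, VT, spec)
    verb <- expiration_solution_from_tidal(p, Pm, VT, spec,
                                           verbatim = TRUE)
    expect_equal(evaluate_volume(corr, tt), verb(tt), tolerance = 1e-12)
  }
  # alpha = 1 with the self-consistent Pm: the breath empties at tb
  sp1 <- derivative_spec("proportional", 1)
  Pm1 <- residual_pressure(p, sp1, residual_policy("self_consistent"))
  VT1 <- tidal_volume(p, Pm1, sp1)
  expect_lt(abs(evaluate_volume(
    expiration_solution_from_tidal(p, Pm1, VT1, sp1), p$tb)), 1e-10)
})

test_that("waveform assembly: continuity, emptying, mode agreement", {
  p <- ref_params()
  sp <- derivative_spec("proportional", 0.8)
  wf <- breath_waveform(p, sp, residual_policy("self_consistent"),
                        "anchored_start")
  expect_identical(wf$data$volume[1], 0)
  expect_lt(abs(wf$data$volume[nrow(wf$data)]), 1e-10)
  expect_lt(wf$jump_at_tj, 1e-14)
  # monotone rise then fall
  vi <- wf$data$volume[wf$data$phase == "inspiration"]
  ve <- wf$data$volume[wf$data$phase == "expiration"]
  expect_true(all(diff(vi) > 0))
  expect_true(all(diff(ve) < 0))
  # the two assembly modes coincide at alpha = 1
  sp1 <- derivative_spec("proportional", 1)
  wa <- breath_waveform(p, sp1, residual_policy("classical_formula"),
                        "anchored_start")
  wp <- breath_waveform(p, sp1, residual_policy("classical_formula"),
                        "boundary_anchored")
  expect_lt(max(abs(wa$data$volume - wp$data$volume)), 1e-10)
  # boundary-anchored at alpha < 1 records its discontinuity honestly
  wpf <- breath_waveform(p, sp, residual_policy("classical_formula"),
                        "boundary_anchored")
  expect_gt(wpf$jump_at_tj, 0)
  # multi-breath assembly is continuous across breath boundaries
  wm <- breath_waveform(p, sp, residual_policy("classical_formula"),
                        "anchored_start", n_points = 60L, n_breaths = 3L)
  expect_true(all(is.finite(wm$data$volume)))
  for (b in 1:2) {
    last_b <- wm$data$volume[max(which(wm$data$breath == b))]
    first_next <- wm$data$volume[min(which(wm$data$breath == b + 1L))]
    expect_lt(abs(first_next - last_b), 1e-14)   # continuity in litres
  }
})

test_that("pressure decomposition balances at the airway", {
  p <- ref_params()
  for (spec in all_family_specs(0.8)) {
    wf <- breath_waveform(p, spec, residual_policy("self_consistent"))
    pd <- pressure_decomposition(wf)
    expect_lt(max(pd$balance_residual), 1e-8)
    expect_true(all(pd$Paw[pd$phase == "inspiration"] == p$Pd))
    expect_true(all(pd$Paw[pd$phase == "expiration"] == 0))
  }
  # proportional steady state: Pl = R (1-a) V_inf, Pk = V_inf / C
  a <- 0.8
  sp <- derivative_spec("proportional", a)
  Pm <- ref_pm_classical()
  sol <- inspiration_solution(p, Pm, sp)
  sol$V0 <- sol$V_inf               # start at the fixed point
  tg <- c(0.2, 0.7)
  expect_equal(p$R * evaluate_local_deriv(sol, tg),
               rep(p$R * (1 - a) * sol$V_inf, 2), tolerance = 1e-12)
  # classical steady state: Pl -> 0, Pk -> Pd - Pm
  sol1 <- inspiration_solution(p, Pm, derivative_spec("classical"))
  expect_lt(abs(p$R * evaluate_local_deriv(sol1, 20)), 1e-12)
  expect_equal(evaluate_volume(sol1, 20) / p$C, p$Pd - Pm,
               tolerance = 1e-9)
})

test_that("proportional inspiration is bounded by and approaches V_inf", {
  p <- ref_params()
  Pm <- ref_pm_classical()
  for (a in c(0.45, 0.8, 1)) {
    sol <- inspiration_solution(p, Pm, derivative_spec("proportional", a))
    tg <- seq(0, 5, length.out = 200)
    V <- evaluate_volume(sol, tg)
    expect_true(all(V <= sol$V_inf + 1e-14))
    expect_true(all(diff(V) >= 0))                    # saturates at V_inf
    expect_true(all(diff(V[tg <= 1]) > 0))
    expect_lt(sol$V_inf - evaluate_volume(sol, 50), 1e-10)
  }
})
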