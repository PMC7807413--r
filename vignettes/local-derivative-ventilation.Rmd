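---
title: "Local-derivative models of pressure–volume controlled ventilation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-derivative models of pressure-volume controlled ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungvent)
```

## The model and its assumptions

A ventilated lung is treated as a single compartment. The ventilator
applies a constant driving pressure $P_d$ to the airway during the
inspiratory interval $[0, t_j]$ and zero pressure during expiration
$[t_j, t_b]$; $t_j$ and $t_b$ are clinician-set. The airway pressure
balance splits into a resistive drop proportional to flow
($P_l = R\,\dot V$), an elastic recoil proportional to volume
($P_k = V/C$) and a constant residual pressure $P_m$:

$$R\,\mathbf{D}^{\alpha} V(t) + \frac{1}{C} V(t) + P_m = P_{aw},
\qquad V_i(0) = V_e(t_b) = 0 .$$

The generalisation studied here replaces the time derivative by one of
three *local* derivatives of order $\alpha \in (0, 1]$ — operators
defined pointwise by a limit, with no memory kernel. For differentiable
$V$ they reduce to weighted first derivatives (the package's evaluation
path; the raw limit quotients survive only as a test oracle because they
are numerically fragile):

* **proportional** (PD-controller form): $(1-\alpha)V + \alpha V'$, with
  the linear gain pair $\kappa_1 = 1-\alpha$, $\kappa_0 = \alpha$. This
  is the only family that interpolates all the way to the identity
  operator at $\alpha = 0$. The general $(\kappa_0, \kappa_1)$ pair is
  accepted as callables by the calculus layer, but every shipped solver
  uses the linear pair — the only concrete pair the underlying theory
  gives;
* **conformable**: $t^{1-\alpha} V'(t)$, $t > 0$;
* **truncated-M**: $t^{1-\alpha} V'(t) / \Gamma(\beta+1)$, a
  Mittag-Leffler–dilated conformable derivative with a second parameter
  $\beta > 0$.

All three coincide with $V'$ at $\alpha = 1$ (the truncated-M family
additionally needs $\Gamma(\beta+1) = 1$, i.e. $\beta = 1$, which is why
its classical-correspondence tests pin $\beta = 1$).

## Closed-form phase solutions

Each phase is a constant-coefficient first-order problem, solved in the
transform domain for the proportional family (the transform of the
$n$-fold proportional derivative is a degree-$n$ polynomial multiplier
$(\alpha s + 1 - \alpha)^n$ minus boundary-value polynomials;
`lt_nth_order_rule()` builds them, and the single pole inverts by partial
fractions). Every solution has the shape

$$V(t) = V_\infty + (V_0 - V_\infty)\,
  e^{-\lambda\,(w(t) - w(t_0))},$$

an exponential relaxation in warped time $w$. For the proportional
family $w(t) = t$, $V_\infty = C K/(1 + CR - \alpha CR)$ and
$\lambda = (1 + CR - \alpha CR)/(\alpha C R)$, with $K$ the constant
right-hand side ($P_d - P_m$ or $-P_m$). For the conformable and
truncated-M families $V_\infty = CK$, $\lambda = 1/(CR)$ (times
$\Gamma(\beta+1)$ for M) and $w(t) = t^\alpha/\alpha$.

Two interpretation points were genuinely open and are resolved as
follows.

**Signed powers for terminal anchors.** The expiration solution anchored
at $t_b$ contains $(t - t_b)^\alpha$ with a negative base on
$[t_j, t_b)$. We take the continuous signed branch
$\mathrm{sgn}(x)\,|x|^\alpha$, the unique choice that recovers the
classical limit $C P_m (e^{(t_b - t)/RC} - 1)$ at $\alpha = 1$ and
produces decaying expiration curves. Consistently, such a solution
satisfies the conformable/M equation whose derivative is based at the
anchor, i.e. with weight $|t - t_b|^{1-\alpha}$;
`eval_local_derivative()` exposes this through its `origin` argument and
`classical_reformulation()` carries the same convention.

**Tidal-anchored inspiration erratum.** The transform-domain route for
the inspiration solution anchored at $V(t_j) = V_T$ admits a simple
consistency check: substituting $t = t_j$ must return $V_T$. The
historically printed forms return $V_T \pm 2 V_\infty$ instead — they
fail their own anchor (the suite verifies the discrepancy is *exactly*
$2 V_\infty$). The package implements the corrected form
$V_\infty + (V_T - V_\infty) e^{-\lambda (w(t) - w(t_j))}$, which
anchors exactly and has zero governing-equation residual; the verbatim
printed forms remain available behind `verbatim = TRUE` purely so the
documentation tests can demonstrate the defect. The tidal-anchored
*expiration* forms printed alongside are correct (the proportional one is
algebraically identical to our assembly, checked at random points to
1e-12).

## Residual pressure policies

$P_m$ is fixed by requiring the lung to empty at end-expiration,
$V_e(t_b) = 0$. Two policies ship:

* `classical_formula`: $P_m = P_d (e^{t_j/RC} - 1)/(e^{t_b/RC} - 1)$,
  the $\alpha$-independent value derived from the classical model. The
  reference figures use this one value for every family and order, so it
  is the default for figure-style (`boundary_anchored`) assembly — at
  $\alpha \ne 1$ it leaves a volume jump at $t_j$, which the waveform
  records in its metadata instead of hiding.
* `self_consistent`: the $P_m$ that enforces
  $V_i(t_j) = V_e(t_j)$ for the chosen family — for the proportional
  family $P_d(e^{\lambda t_j} - 1)/(e^{\lambda t_b} - 1)$, for
  conformable/M $P_d(1 - e^{-u})/(e^{v} - e^{-u})$ with
  $u = \lambda_f t_j^\alpha/\alpha$,
  $v = \lambda_f (t_b - t_j)^\alpha/\alpha$. Both reduce to the formula
  value at $\alpha = 1$ (property-tested on random parameter draws). This
  is the physically coherent option and the default for continuous
  (`anchored_start`) assembly.

Whether the original figures used a per-order $P_m$ is not stated
anywhere; providing both policies covers both readings.

## Parameters, defaults and units

| parameter | meaning | default | units |
|---|---|---|---|
| `R` | airway resistance | 10 | cm H₂O·s/L |
| `C` | lung compliance | 0.02 | L/cm H₂O |
| `Pd` | driving pressure | 20 | cm H₂O |
| `tj` | inspiratory time | 1 | s |
| `tb` | breath length | 3 | s |
| `alpha` | derivative order | 1 | – |
| `beta` | Mittag-Leffler parameter (M only) | – | – |

The defaults are the reference setting used throughout the comparative
figures; with them $RC = 0.2$ s, $P_m \approx 9.02\times10^{-4}$ cm H₂O
and the classical tidal volume is $\approx 0.397$ L. The tidal volume is
never specified independently; where a $V_T$ anchor is needed it defaults
to $V_i(t_j)$ computed from the same family, order and $P_m$.

## Numerical choices

* **Quadrature** (proportional integral/exponential, mean alveolar
  pressure): `stats::integrate` with absolute/relative tolerance 1e-10.
  The proportional-family mean alveolar pressure has a closed-form
  antiderivative used as a cross-check (agreement 1e-9 in the suite).
* **Oracle integration**: `deSolve::ode` (lsoda), rtol 1e-10 / atol
  1e-12. The conformable/M equations have a $t^{\alpha-1}$ coefficient
  singular at the warp origin while their solutions stay finite; the
  oracle therefore integrates in the warped time
  $u = \mathrm{sgn}(t-o)|t-o|^\alpha/\alpha$, where the equation is
  regular and linear. Terminal anchors would require integrating on a
  decreasing grid, where lsoda loses several digits; the oracle instead
  negates the independent variable and integrates forward.
* **Residual grids**: governing-equation residuals are evaluated from
  the analytic derivative of each closed form. At the warp origin the
  derivative weight $|t-o|^{\alpha-1}$ is singular although the
  local-derivative combination is finite; grid points within 1e-9 of the
  origin are nudged away by 1e-9 of the grid span.
* **Residual acceptance conditions**: the residual sweep over the full
  order grid ($\alpha$ from 0.25 to 1, $\beta$ from 0.5 to 1.5) is run
  under the self-consistent $P_m$. Under the order-blind formula $P_m$
  the terminal-anchored expiration reaches volumes of $10^6$–$10^{15}$ L
  at $\alpha \le 0.45$ ($e^{2\lambda}$ with $\lambda$ up to 23), where an
  absolute pressure residual of 1e-8 cm H₂O would demand ~1e-16
  *relative* accuracy — beyond double precision. With the self-consistent
  $P_m$ volumes stay near 0.4 L and the worst observed residual is
  ~1e-14; inspiration-phase residuals under the formula $P_m$ (which stay
  bounded) are additionally checked.
* **Exact coefficient algebra**: the transform-rule identity (direct
  $n$-fold rule equals the iterated first-order rule) is verified in
  exact rational arithmetic for $n \le 6$ and rational orders, realised
  with integer-scaled coefficients (all integers involved stay far below
  $2^{53}$, so the arithmetic is exact); the floating implementation is
  tied to the exact coefficients at 1e-13 and is bitwise-exact for dyadic
  orders.
* **Truncated Mittag-Leffler**: partial sums with default truncation 40
  and an early stop when a term falls below 1e-16 in magnitude.
* **Time grids**: uniform and endpoint-inclusive; the inspiration grid
  starts at $t = 0$ exactly (the closed forms are finite there even
  though the conformable/M ODE coefficient is not).

## Variation of parameters and the mass–spring application

For the forced oscillator
$m\,\mathbf{D}^\alpha\mathbf{D}^\alpha y + 2b\,\mathbf{D}^\alpha y + k y = g(t)$
the homogeneous basis comes from the auxiliary equation
$m\lambda^2 + 2b\lambda + k = 0$: each root yields the proportional
exponential $e^{(\lambda - (1-\alpha))t/\alpha}$, and the underdamped
pair is $e^{\mu t}\cos(\omega_\alpha t)$, $e^{\mu t}\sin(\omega_\alpha t)$
with $\mu = (-b - (1-\alpha)m)/(m\alpha)$ and
$\omega_\alpha = \sqrt{mk - b^2}/(m\alpha)$ — both arguments carry the
$1/\alpha$ scaling, the form under which the p-Wronskian takes its
closed form $(\sqrt{mk-b^2}/m)\,e^{2(-b-m+\alpha m)t/(m\alpha)}$
(verified to 1e-10). Three transcription details in the source theory
were resolved on algebraic grounds: the p-Wronskian determinant is a true
Wronskian (its printed second column repeats the first, which would make
it identically zero); the critical-damping exponential reads
$e_{-b/m}$ (no symbol $a$ exists in the model); and the trigonometric
arguments include $t/\alpha$, without which the printed Wronskian closed
form is false. The particular solution uses
$\gamma_1' = -y_2 g/(\alpha^2 W)$, $\gamma_2' = y_1 g/(\alpha^2 W)$ with
$W$ the classical Wronskian; the coefficients are integrated either by
per-point adaptive quadrature (`variation_of_parameters_particular`) or
as an ODE system along the grid (`solve_mass_spring`), and the defining
constraint $\gamma_1' y_1 + \gamma_2' y_2 = 0$ is asserted pointwise in
the suite. Initial data use the *proportional*-derivative value at $t_0$
so that $\alpha = 1$ reduces to the standard classical IVP; the source
theory states no initial data or forcing for this application, so all
test scenarios are synthetic (forcing $\cos t$, parameters spanning the
three damping cases).

Only the second-order path is implemented; the order-$n\alpha$ statement
of the method is not exercised beyond $n = 2$, matching the worked
content it comes from.

## What the tests do and do not show

The suite verifies *internal mathematical correctness*: boundary
conditions to 1e-12, governing-equation residuals to 1e-8 (measured
~1e-14), classical correspondence at $\alpha = 1$ to 1e-12, closed forms
against independent warped-time integration to 1e-6 relative, exact
transform algebra, and the qualitative figure claims (monotone
inspiration rise; the proportional curve tracking the classical one more
closely than conformable/M at the comparative settings). The model
itself remains a single linear compartment with constant $R$, $C$ and
$P_m$: no multi-compartment heterogeneity, nonlinear compliance, PEEP
beyond the constant offset, or patient-data fitting. Nothing here
validates the local-derivative families *against measured respiratory
data* — passing tests show the solutions solve their equations, not that
any $\alpha < 1$ describes a real lung better than $\alpha = 1$.

## Known limitations

* The conformable/M families are undefined at $t \le 0$ and carry the
  anchor-based-derivative convention described above for terminal
  anchors; users comparing against other conventions for negative bases
  will see different expiration curves.
* Multi-breath assembly repeats the single-breath pattern from the
  previous end volume — an approximation, since the underlying closed
  forms describe a single breath.
* The order-blind formula $P_m$ produces physically absurd expiration
  volumes at small $\alpha$; that is a property of the modelling
  convention, reproduced faithfully, not a numerical defect (see the
  residual-conditions note above).
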