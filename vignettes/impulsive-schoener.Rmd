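---
title: "Methods: simulating and certifying the impulsive delayed Schoener competition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and certifying the impulsive delayed Schoener competition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(schoenerimp)
```

## The model and its assumptions

`schoenerimp` works with the hybrid delay system

$$
\dot x_i(t) = x_i(t)\Big[\frac{a_{i0}(t)}{x_i(t-\tau_{i0}) + m_i(t)}
 - a_{ii}(t)\,x_i(t-\tau_{ii}) - a_{ij}(t)\,x_j(t-\tau_{ij}) - c_i(t)\Big],
 \quad t \ne \tau_k,
$$
$$
x_i(\tau_k^+) = (1 + h_{ik})\,x_i(\tau_k), \qquad i \in \{1,2\},\ j \ne i,
$$

with positive almost periodic coefficients, nonnegative pure delays (every
state on the right-hand side is retarded), and multiplicative jumps at
prescribed times $\tau_k$. The biological reading: saturating
resource-limited growth (Schoener's form $a_{i0}/(x_i+m_i)$), linear intra-
and inter-specific competition, a time-varying death rate, and instantaneous
stocking pulses ($h \ge 0$) from, e.g., periodic restocking. The state of
the system is a *function segment*: an initial history on $[-\tau, 0]$ with
$\tau = \max 2\tau_{ij}$ and a strictly positive right limit at $0$.

Almost periodicity is realized constructively: coefficients are finite
trigonometric sums (`qp_coef`) whose certified range is the amplitude
interval $[c - \sum|A_m|,\, c + \sum|A_m|]$, and impulse times are
$\tau_k = kP + J\sin(\nu k)$ (`schedule_generate`), which makes the family
of difference sequences $\tau_{k+j}-\tau_k$ uniformly almost periodic by
construction. Verifying almost periodicity of *arbitrary* inputs is out of
scope.

## Numerical integration

* **Scheme.** Classical fixed-step RK4 on each inter-impulse segment, with
  the grid snapped to every impulse time (each segment subdivided evenly
  with substep $\le$ `step`). At $\tau_k$ the stored grid keeps the
  left-continuous pre-jump value; the jump is applied exactly and the
  post-jump value opens a new segment at the same time. Adaptive stepping
  was rejected: fixed steps keep delayed lookups and reproducibility simple,
  and the systems of interest are non-stiff.
* **Method of steps.** Delayed states are evaluated by cubic Hermite
  interpolation of the stored solution *within* its segment (never across a
  jump). Delays far below the step — the worked example uses
  $\tau_{ij} = 10^{-4}$ against a default step of $0.01$ — are handled by
  the same interpolant; RK4 stage times marginally ahead of the newest grid
  point reuse the last segment cubic, so the $O(h^4)$ order is preserved
  (the observed order on an exact piecewise solution is $\approx 4$, tested
  at $\ge 3.5$).
* **Positivity.** The two-species system is integrated in log space
  ($z_i = \ln x_i$, jumps become shifts by $\ln(1+h_{ik})$) by default, so
  positivity is structural; linear-space integration is kept for
  cross-validation and the two agree to within $10\,h^4$ relative error on
  smooth stretches. The scalar logistic integrator defaults to linear space
  so that the convergence-order study is non-trivial (in log space the
  linear impulsive equation is integrated exactly).
* **Default step.** `min(0.01, theta/100)` for the two-species system, with
  `theta` the minimal impulse gap: this resolves the impulse-period
  oscillation. Test sweeps use step $0.05$, documented where they do; RK4
  error there is orders of magnitude below the $10^{-3}$ tolerances used in
  the certification checks.

## The scalar impulsive logistic layer

The comparison machinery reduces both species to the scalar equation
$\dot x = x(a - b\,x(t-\tau))$ with jumps. For $\tau = 0$ the equation has a
globally stable positive almost periodic orbit with the closed form
$x^*(t) = [\,b\int_{-\infty}^t W(t,s)\,ds\,]^{-1}$, where the Cauchy matrix
$W(t,s) = e^{-a(t-s)}\prod_{\tau_k \in (s,t]}(1+h_k)^{-1}$ is the transition
factor of the linearized reciprocal equation. Between impulses the integrand
is exactly $P\,e^{-a(t-s)}$ with a piecewise-constant product $P$, so each
segment is integrated **in closed form** (no quadrature error); the infinite
lower limit is truncated at $t - L$ with $L$ chosen so the tail envelope
falls below the `tol` argument. The orbit evaluator is validated three ways:
it satisfies the ODE between jumps (five-point stencil residual), it obeys
the jump relation $x^*(\tau_k^+) = (1+h_k)x^*(\tau_k)$, and long-time
simulations from arbitrary starts converge onto it.

## A sign erratum in the published lower bounds

The upper-bound chain ($B$, $M = a/(\eta B(1-e^{-a\theta}))$, and the
two-species $M_i$) is sound and is implemented as printed. The lower-bound
chain is not: it bounds $\prod (1+h_k)^{-1} \le e^{i(s,t)\,\xi}$ with
$\xi = \ln\sup_k 1/(1+h_k)$ and then substitutes the *upper* counting bound
$i(s,t) \le A(t-s)+A$ into the exponent. That substitution preserves the
inequality only when $\xi \ge 0$; the model's own setting ($h_k \ge 0$)
forces $\xi \le 0$, flipping it. The failure is not marginal: for the
impulsive logistic equation with $a = b = 1$, $h_k = 0.5$ on a period-5
schedule, the printed bound gives $N \approx 2.11$ while the true orbit
minimum is $\approx 1.00$ (the test suite computes exactly this
counterexample).

The package therefore evaluates **both** variants everywhere a lower bound
occurs (`logistic_scalar_bounds`, `permanence_bounds`, the orbit bracket):

* `*_printed` — the formula verbatim, exponent $\xi A$;
* the corrected value — exponent $\xi^+ A$ with $\xi^+ = \max(\xi, 0)$. For
  $h \ge 0$ this collapses to the classical comparison value ($N = a/D$,
  orbit floor $a/b$), which *is* a true bound: since every jump factor
  satisfies $(1+h_k)^{-1} \le 1$, the reciprocal solution obeys
  $u(t) \le b/a$ directly.

All trajectory-containment diagnostics, the invariant-set window, and the
stability constants use the corrected bounds; the printed values are kept
for reporting and comparison. Relatedly, condition H1 as printed
($r_i^l \ge \xi_i A$, a nonpositive right-hand side) does not make the lower
bound meaningful: the scalar lemma it feeds requires a strictly positive
growth rate. `check_H1` therefore reports both the printed condition
(`holds`) and the strict one (`strict`, $r_i^l > 0$); "certified" in this
package means both.

## Permanence and stability certification

All suprema/infima over $t$ are computed by interval arithmetic on the
certified coefficient ranges — conservative in exactly the way the theory's
own $f^l/f^u$ notation is — with dense sampling available as a diagnostic
refinement. The impulse-window products $\prod_{\tau_k \in [t-\tau,t)}$ are
piecewise constant in $t$ with breakpoints at $\tau_k$ and $\tau_k + \tau$;
the extrema are found by enumerating the breakpoints exactly. The half-open
window $[t-\tau, t)$ matches the product notation of the source material: an
impulse exactly at $t-\tau$ is included, one at $t$ excluded. Window
positions with an empty product (ahead of the first impulse, or length-0
windows) contribute the factor 1; this is the conservative direction for
both $B$ (infimum) and $D$ (supremum).

Conventions for degenerate schedules: an empty schedule has $\theta =
+\infty$, $A = 0$, $\xi = 0$, $\eta = 1$ and all window products 1, so every
formula reduces to its continuous-time counterpart (this reduction is
tested). $\eta$ is defined twice in the source (a two-factor product
starting at index 0 in one place, index 1 in another); both are two-term
products and coincide for stationary jump coefficients, and the package uses
the index-0 form with a single-factor fallback for one-point schedules.

Condition H2 (existence of $\lambda_1, \lambda_2 > 0$ with
$\lambda_1\alpha_1 > \lambda_2\beta_1$ and
$\lambda_2\alpha_2 > \lambda_1\beta_2$) is decided in closed form: feasible
iff $\alpha_1, \alpha_2 > 0$ and $\alpha_1\alpha_2 > \beta_1\beta_2$, the
admissible ratio interval being $(\beta_1/\alpha_1,\ \alpha_2/\beta_2)$. For
reproducibility the returned multipliers are normalized to $\lambda_2 = 1$
with the ratio at the geometric mean of the interval endpoints; degenerate
endpoints use fixed fallbacks ($\beta_1 = 0$: half the upper endpoint;
$\beta_2 = 0$: twice the lower endpoint; both: 1). A brute-force
$\lambda$-grid search over $10^{-8} \dots 10^{8}$ serves as the independent
oracle in the tests.

## The Lyapunov functional

`lyapunov_V` evaluates the stability proof's functional
$V = V_1 + V_2 + V_3 + V_4$ on the log scale. The double-integral memory
terms are reduced analytically by Fubini before quadrature: each term
$\int_{-\tau_a-\tau_b}^{-\tau_b}\int_{t+s}^{t}|\Delta z(r)|\,dr\,ds$ becomes
$\int_{t-\tau_a-\tau_b}^{t} w(r)\,|\Delta z(r)|\,dr$ with the tent weight
$w(r) = \min(\tau_a, \max(0, r-t+\tau_a+\tau_b))$ — cheaper and more
accurate than nested quadrature; the remaining single integrals use
composite trapezoid on at least 17 nodes per window (error $O(h^2)$ in the
node spacing, and the windows are at most $2\max\tau_{ij}$ long).

Because both trajectories jump by the same factor, log differences are
continuous across impulses and $V(\tau_k^+) = V(\tau_k)$ holds *exactly* in
theory. Numerically, $V_1$ is built from differences of $O(1)$ logarithms,
so its absolute rounding floor is $\sim 10^{-15}$; once $V$ has decayed
below $\sim 10^{-7}$, a $10^{-8}$ *relative* band is narrower than that
floor and no longer measurable. `lyapunov_checks` therefore reports the
relative violation with the denominator floored at $10^{-7}$ together with
the raw absolute discrepancy (asserted $< 10^{-12}$ in the tests). The decay
condition is checked only in sign (non-increase across checkpoints): the
published decay rate is state-dependent and its derivation is deferred to a
companion work, so no rate is estimated.

"Uniform asymptotic stability" is verified operationally: trajectory pairs
from distinct histories contract (terminal distance below $10^{-3}$ at
horizon 200; distance at least halves at each horizon doubling, down to an
integration noise floor of $10^{-12}$), and $V$ is non-increasing. No
attempt is made to certify uniformity over all initial data or to extract
$\varepsilon$-almost periods of the limit orbit.

## Synthetic scenarios: what they emulate and what they do not

`random_weak_model(seed)` draws the regime the certification theory is
*about*: resource supply $a_{i0} \approx 1$, half-saturation $m_i \approx
2$, intraspecific competition $a_{ii} \approx 1$, mortality $c_i \approx
0.1$ (each with small-amplitude harmonics at uniformly drawn incommensurate
frequencies), interspecific competition $2\cdot10^{-4} \dots 5\cdot10^{-4}$
(three to four orders below intraspecific — "weak competition"), delays up
to $10^{-3}$, and stocking pulses $h \le 0.1$ on period-5 schedules with up
to $\pm 0.5$ sinusoidal jitter. These ranges were fixed from the theory
side, before any sweep was run: they keep the conservative ceilings $M_i$
low enough that the growth infima $r_i^l$ stay strictly positive, which is
the regime in which the $N_i$ bound exists at all. Stronger impulses (such
as the worked example's $h = 0.5$) push the conservative $M_i$ so high that
$r_i^l < 0$ and no strict certificate is possible — such scenarios are still
simulated and bounded above, but their lower bound is vacuous.

What a green sweep does establish: on twenty seeded models the full chain
(certify H1 strictly, simulate, compare tails against $[N_i, M_i]$, check
invariance of $S$, certify H2, verify contraction and the $V$ properties)
holds end to end. What it does not establish: behavior outside the
weak-competition regime, tightness of any bound, almost periodicity of the
limit orbit in the formal sense, or anything about destructive impulses
($-1 < h < 0$), which the implementation accepts but the sweep does not
exercise.

## Known discrepancies in the worked example

The packaged scenario (`example1_model`) reproduces the published
worked-example *system* exactly, but several of its printed intermediate
constants are mutually inconsistent with the formulas they are supposed to
come from: the minimal gap is printed as 2 though the schedule spacing is 5;
one $\eta$ is printed as 4 though $\eta \le 1$ by definition; the $\xi_i$
are printed positive though $\ln(1/(1+h)) < 0$; and the quantities
$y_i^* \approx 0.7256, 0.5421$ are never defined (they behave like ceilings
$M_i$ from an unprinted derivation — fed in externally, the stability
constants do come out positive with tiny cross terms, which the tests
check). The package computes everything from the formulas ($\theta = 5$,
$\eta_1 = 1/1.5^2$, $\xi_1 = \ln(1/1.5)$, $M = (3.56, 2.89)$) and does not
emulate the printed intermediates. Consequently $r_i^l < 0$ there, the
strict certificate does not apply, and the scenario is validated
qualitatively: persistence of both species and contraction of distinct
histories, which the simulations show cleanly (tails in $[0.42, 0.66]$,
terminal pair distance $< 10^{-3}$ at horizon 200). One further slip: the
closing remark of the source quotes $h_{2k} = 0.6$ while the displayed
system and figures use $0.4$; the package uses $0.4$.

## Other numerical choices

* Finite schedules: all sequences are horizon-limited; $\inf/\sup$ over the
  impulse index are taken over the generated window. This is conservative
  for the window products (edge windows are empty) and exact for periodic
  schedules.
* `schedule_A` certifies the counting constant by exhaustive window
  enumeration over index pairs — for points $\tau_i \dots \tau_j$ the
  binding constraint is $(j-i+1) \le A(\tau_j - \tau_i + 1)$ — and the tests
  additionally verify minimality ($A - 1$ violates some window).
* Trajectory CSVs are written with 17 significant digits so the round trip
  through `read_trajectory` is bit-exact; jump records travel in a JSON
  sidecar.
* Degenerate inputs: empty tail windows, histories outside the invariant
  set, mismatched grids, insufficient history depth, and nonpositive states
  in linear space are errors, not silent results.

## Limitations

* The integrator is fixed-step and explicit; stiff parameterizations are
  out of scope.
* The closed-form orbit is implemented for the undelayed scalar equation
  only, as in the theory it supports.
* Interval-arithmetic suprema are conservative for multi-harmonic
  coefficients (amplitude bounds rather than exact ranges); dense sampling
  narrows but does not certify.
* The $\lambda$-grid H2 oracle and the certification sweeps are seeded and
  finite; they are consistency checks, not proofs.
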