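---
title: "Lifespan-based modeling of tumor growth inhibition: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan-based modeling of tumor growth inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstgi)
```

## The model

`lstgi` implements a mechanistic model of xenograft tumor growth built on a
single biological primitive: every tumor cell lives for exactly `T` days
(the doubling time) and divides at the end of its lifespan.  Tumor size
`w(t)` (grams or mm^3 — the model is agnostic, no density conversion is
ever applied) changes as the balance of a production rate and an
elimination rate, and because every cell that is produced is eliminated
(by division) exactly one lifespan later, elimination is production lagged
by `T`:

$$\frac{dw}{dt} = k_{in}(t) - k_{in}(t-T).$$

Division couples the two: a dividing cell is removed and replaced by
`p` daughter cells, where the *division efficiency* `p` is between 1
(stasis) and 2 (perfect doubling).  This gives the recursion

$$k_{in}(t) = p(w(t)) \cdot k_{in}(t-T), \qquad
  k_{in}(t) \equiv k_{in0} \text{ on } (-T, 0],$$

so that the growth equation is the delay differential equation (DDE)

$$\frac{dw}{dt} = \bigl(p(w(t)) - 1\bigr)\, k_{in}(t-T), \qquad w(0) = w_0.$$

Unrolling the recursion, the number of lagged factors at time $t$ is the
integer part of $t/T$; this integer-part structure makes the solution a
*discontinuous* function of `T`, which drives the estimation design below.

Tumor burden limits growth through the efficiency function.  The smooth
form used by default is

$$p(w) = 1 + (p_0 - 1)\bigl(1 + (w/w_{th})^{\psi}\bigr)^{-1/\psi},$$

which equals `p0` well below the threshold size `wth`, falls to 1 as
$w \to \infty$, and switches between the two regimes with sharpness `psi`
(default 20, fixed rather than estimated: at that value the function
already behaves as a natural switch, and it is practically
unidentifiable from growth curves).  Its $\psi \to \infty$ limit is the
piecewise form $p = p_0$ for $w \le w_{th}$ and
$1 + (p_0-1)\,w_{th}/w$ above — this limit is what makes the late growth
*linear* with slope

$$\text{slope} = \frac{(p_0 - 1)\, w_{th}}{T},$$

independent of `kin0` and `w0` (those only shift when measurable growth
begins).  Three parameterizations are exposed:

* `full` — biphasic exponential-then-linear growth, parameters
  `(T, kin0, p0, wth, w0)`;
* `linear_phase` — when all observations lie beyond the threshold only
  the product `pwth = (p0-1)*wth` is identifiable, so it replaces
  `(p0, wth)`;
* `constant_p` — constant efficiency; pure exponential growth with the
  closed form implemented in `closed_form_constant_p()` and envelope
  bounds in `asymptotic_bounds()`.

Purely exponential datasets are handled inside `full` by setting `wth` to
a sentinel far above anything observable (the AZD1208-style template uses
10^12 mm^3).

## Drug effects

The tumor is split into proliferating mass `M(t)` and a drug-damaged,
apoptotic pool `A(t)`; the observed size is `w = M + A`, and damaged
cells leave the tumor exactly `TA` days (the apoptosis duration) after
they were hit.  `A` therefore obeys the same lifespan bookkeeping as the
growth model: $A(t) = \int_{t-T_A}^{t} \text{inflow}(s)\, ds$.

**Non-cycle-specific** drugs kill proliferating cells at any point of the
cell cycle at rate $E(C(t))\,M(t)$, with $E = k_2 C$ (linear) or
$E_{max} C/(EC_{50}+C)$ by configuration.  Only cells that survive their
whole lifespan divide, so the lagged production term acquires the
survival factor $\exp(-\int_{t-T}^{t} E(C(s))\,ds)$ (exposure before
$t=0$ contributes nothing — no drug exists before the experiment):

$$\frac{dM}{dt} = (p(w)-1)\,k_{in}(t-T)\,
  e^{-\int_{t-T}^{t}E(C)\,ds} - E(C(t))\,M(t).$$

**Cycle-specific** drugs act only at the moment of division: a fraction
$E(C(t))$ of cells reaching the end of their lifespan is diverted to the
apoptotic pool instead of dividing, and the survivors divide with
efficiency `p`:

$$\frac{dM}{dt} = \bigl(p(w)\,(1-E(C(t))) - 1\bigr)\,k_{in}(t-T).$$

Because `E` is here a *fraction* of dividing cells, only the bounded Emax
form is admissible, and the constructor rejects the linear form.  A
consequence explored in the sensitivity fixtures is that the drug only
touches the thin time slice of cells that divide while concentrations are
high, so fitted `EC50` values are far below plasma peaks and dose
escalation saturates (little dose separation at a low `EC50`).

In both models the efficiency argument is the **total** size `w = M + A`
by default: the dying cells still occupy space and consume resources.
`p_of_total = FALSE` switches to `p(M)` for sensitivity exploration.

The delay signature is exact in this family: `w` cannot begin to shrink
before the first dose plus `TA`, because killed mass merely moves from
`M` to `A` until the pool starts draining.  Raising `TA` shifts the
onset of decline one-for-one and leaves the pre-dose curve untouched.

## Pharmacokinetic drivers

Plasma concentration is built by closed-form superposition of single-dose
solutions of linear compartmental models: mono-/bi-exponential bolus
disposition and Bateman absorption curves, including the degenerate
`kel = ka` limit $C = (D/V)\,k_a t\, e^{-k_a t}$ used for the oral
one-compartment template.  Dose-level-specific `(kel, V)` overrides
(observed nonlinear kinetics fit per dose group) are applied per dose
event, each event evolving with its own constants.  Doses are mg/kg,
volumes L/kg, and `unit_scale = 1000` converts dose/V to ng/mL; the
dimensionless sensitivity fixtures set `unit_scale = 1`.  The profile
object carries exact point and cumulative-integral evaluators, so the
survival exponent in the non-cycle model is a difference of
antiderivatives, not a quadrature.

## Numerics

The DDE is solved by the method of steps in compiled code: integration
restarts at every point of the breakpoint lattice
$\{d + iT + jT_A\}$ (doses $d$, $j \in \{0,1\}$), where the right-hand
side genuinely jumps — the production recursion gains a factor at every
multiple of `T`, boluses jump `C`, and the apoptotic outflow switches on
`TA` after each dose.  Within segments a fixed-step classical
Runge–Kutta scheme (step at most `T/80`, further capped by `TA/8`) is
used, and the full state and production-rate history is stored with
derivatives so lagged lookups are cubic-Hermite interpolations.  Two
conventions matter at breakpoints and were the subject of deliberate
design: a lag query landing exactly on a jump resolves to the *right*
piece for the stage opening a segment and the *left* piece for the stage
closing one, and queries are snapped to stored abscissae within 1e-9
because lag arithmetic is inexact in floating point.  With both in
place the solver shows fourth-order convergence and matches the
constant-efficiency closed form to ~1e-14 and an independent
second-order brute-force integrator to below 1e-5 at the default step.

The apoptotic pool can drift a few parts in 10^5 below zero once it
empties (inflow and lagged outflow are interpolated independently); it
is floored at zero below 1e-5 of the trajectory scale, and a violation
beyond 1e-4 is treated as a solver failure and raised as an error rather
than clipped.

The linearized reference model (linear growth `lambda1`, kill
`k2*C*x1`, and a damage chain of `n_transit` compartments with rate
`k1`, 3 by default) is an ordinary ODE and is integrated with `deSolve`,
restarting at bolus times.  Its mean transit time is reported as
`n_transit/k1` by default; the alternative `numerator = 4` convention is
available because both appear in the literature and they differ by one
mean lifetime — the package does not adjudicate.

## Estimation

The solution is discontinuous in `T` and `TA` (integer-part recursion
depth), so those two are estimated by **grid search** while all other
parameters are estimated by bounded Levenberg–Marquardt nonlinear least
squares at each grid node (`minpack.lm`), warm-started from the previous
node.  Bounds are enforced by smooth transforms — log for positive
parameters, scaled logit for `p0` in [1,2] and `Emax` in [0,1] — and
stand-alone fits are polished from several jittered starts (5 by
default, seeded).  After the coarse scan the winner's neighborhood is
rescanned on a fine lattice (0.002 day by default) aligned to absolute
multiples of the step, so refined nodes are reproducible and a truth
lying on the lattice can be recovered *exactly*.  Ties break toward
smaller `T`, then smaller `TA`.  Precision is reported as
CV% = 100·SE/estimate with SE from the asymptotic covariance
$s^2 (J^T J)^{-1}$, the Jacobian taken by central differences on the
natural scale; a singular Jacobian yields `NA` rather than a fabricated
CV%.

`fit_tgi_workflow()` mirrors the staged xenograft analysis: (1) grid `T`
and fit the growth parameters on the control arm; (2) fix the growth
stage, grid `TA` and fit the drug parameters on the treated arms
jointly; (3) optionally refit all continuous parameters simultaneously
on every arm with the lifespans fixed.  Keeping `T` from the control
stage is the default.  Two alternatives are provided because the staged
default is not always the best estimator: `regrid_T = TRUE` re-grids `T`
alongside `TA` in stage 2, and `joint_grid = TRUE` replaces stages 2–3
with one `(T, TA)` grid on *all* arms at which every continuous
parameter is refit.  On sparse biphasic designs with a cycle-specific
drug the staged default inherits a control-stage `T` that was estimated
jointly with different growth values, and the potency estimate absorbs
the mismatch; the joint mode keeps lifespans and continuous parameters
mutually consistent and is what the package's recovery experiments use.
Unweighted residuals are the default; `weighting = "proportional"`
divides residuals by the prediction and is the statistically matched
choice when errors scale with tumor size, as they do in caliper data and
in the synthetic generator.

Fitting a model whose solution costs ~1 ms still multiplies into minutes
across grids, so `tgi_model_spec(hmax = T/30)` lets the fit run the
integrator at a coarser step whose error (~1e-4) is far below
measurement noise; reported fits should be (and in the tests are)
polished or verified at the default step.

## The synthetic-study generator

`casestudy_template()` encodes three designs with truth values taken
from the published fitted estimates so the fixtures are biologically
realistic:

* **paclitaxel**: control + 30 mg/kg i.v. q4d×3 from day 8; `w0` 0.033 g;
  biphasic growth (T 1.46 d, p0 1.44, kin0 0.0404 g/d, wth 2.48 g) and a
  cycle-specific effect (TA 0.536 d, Emax fixed at 1, EC50 9.45 ng/mL).
  Observations every 3 days over days 6–39, the cadence of the digitized
  source study.
* **az968**: control + 10/20/30 mg/kg i.p. weekly×3; `w0` 180 mm^3;
  linear-phase growth (T fixed 1.28 d, pwth 80.8 mm^3, kin0 49.9 mm^3/d),
  non-cycle-specific linear effect (TA 5.56 d, k2 2.30e-3 mL/ng/d), and
  two-compartment absorption PK with dose-specific `kel` and `V`.
  Observations follow the animal protocol exactly: day of treatment,
  48 h and 120 h after, each week, plus 216 h after the last dose for
  treated arms.
* **azd1208**: control + 0.3–30 mg/kg p.o. once daily ×14; `w0`
  170 mm^3; exponential-only growth (T fixed at 3 d from the in-vitro
  doubling time, threshold sentinel), non-cycle-specific Emax effect
  (TA 1.92 d, Emax 0.159, EC50 182 ng/mL), one-compartment oral PK with
  `kel = ka = 5.52`/d.  Observations about three times weekly over
  days 0.5–16.

Noise is proportional by default (`y = w(1 + CV·ε) + SD·ε'`, CV 0.05),
the choice a caliper dataset motivates; non-positive draws are resampled
and counted in the provenance record, which together with the seed
regenerates any dataset bit-identically.  One pooled series per arm is
generated (the analyses the templates emulate fit group-level series);
per-animal replication can be expressed as additional arms.  What the
generator does **not** emulate — inter-animal variability, dropout,
caliper length/width raw measurements, model misspecification — bounds
what passing recovery tests show about real data: they demonstrate that
the estimation machinery is consistent under the model's own
assumptions, not that the model is true.

## Recovery experiments and problem sizes

The acceptance suite runs a parameter-recovery experiment on the
paclitaxel-like design: 20 replicates at 5% proportional noise, plus one
noiseless replicate.  Its analysis settings are: joint `(T, TA)` grid
(`T` in [1, 2] day step 0.1 — the biologically plausible band around
reported xenograft doubling times for this line; `TA` in [0.1, 1.5] day
step 0.2), proportional weighting, `EC50` the only free drug parameter
(`Emax` stays fixed at 1: with a single dose level `Emax` and `EC50` are
jointly unidentifiable, which is also why the source analysis fixed it),
fine lattice 0.002 day for the noiseless replicate — on which the
generating `T` = 1.46 and `TA` = 0.536 are lattice points, making exact
recovery well-defined — and 0.01 day for the noisy replicates, where
grid exactness is not the question and the coarser lattice keeps the
20-replicate experiment to a few minutes.  Typical results: noiseless
recovery is exact on the grid and <1% on continuous parameters; noisy
medians land within ~1% (p0), ~3% (wth) and ~6% (EC50) of the truth.
The model-concordance experiment generates an AZ968-like study and fits
both the lifespan model (T fixed at 1.28 d as in the source analysis —
linear-phase data identify only `pwth/T`) and the linearized reference
model; the two potency estimates agree within a few percent, mirroring
the published 2.30e-3 vs 2.0e-3 mL/ng/day concordance.

## Known limitations

* The cell population is unstructured: all cells sit at the same point
  of their lifespan, and the cycle-specific model cannot identify
  *which* cycle phase a drug targets.
* The pre-experiment history is the constant `kin0`; time-varying
  histories are out of scope.
* Grid search has no conventional standard errors, so `T` and `TA` are
  reported without CV%.
* Pointwise monotonicity of `w` in potency holds during treatment, but
  deeply suppressed tumors regrow marginally faster through `p(w)`, so
  post-treatment curves can cross by ~0.1% — a model property, not a
  solver artifact.
* Plasma concentration drives effect directly; effect compartments,
  intra-tumor PK gradients and resistant subpopulations are not modeled.
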