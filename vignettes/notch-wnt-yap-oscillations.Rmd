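---
title: "Modeling Notch-Wnt-YAP oscillations in epidermal differentiation"
author: "epiosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Notch-Wnt-YAP oscillations in epidermal differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiosc)
```

## The biological question

Basal-layer keratinocytes come in two functional flavors: epidermal stem
cells (SCs), which express the Notch ligand Delta/DLL at high levels, and
transit amplifying cells (TACs), in which a contacting SC can activate
Notch signaling and thereby trigger terminal differentiation. `epiosc`
implements two linked mechanistic models of this system:

1. a **population model** for the density of terminally differentiated
   cells (TDCs) produced in the basal layer by Delta-Notch contact, with an
   analytic threshold on Delta expression below which a cell cannot act as
   a stem cell; and
2. a **regulatory-network model** of one interacting SC-TAC pair, in which
   Notch activity in the TAC, Wnt activity in the SC, Wnt activity in the
   TAC and nuclear YAP activity in the TAC are coupled through
   interlocked positive and negative feedback loops and can sustain limit
   cycle oscillations. The oscillation is the proposed engine of TAC
   differentiation: the cell visits high-Wnt/low-Notch and
   low-Wnt/high-Notch states periodically.

## The TDC population model

The TDC density `C` obeys

```
dC/dt = ( k1 * d / (k2 + C) - kd1 ) * C
```

a Michaelis-Menten-type production law in which the SC-surface Delta
concentration `d` plays the role of the enzyme, `k2` is the fold decrease
in production from Notch-independent apoptosis, and `kd1` is the rate of
TDC movement into the suprabasal layers. By the homeostasis argument the
TAC and TDC densities in the basal layer are equal, so a single density
appears.

`C = 0` is always a steady state. For `d` above the critical level

```
d_cr = k2 * kd1 / k1
```

a second, positive state `C = k1*d/kd1 - k2` exists; it is stable and the
zero state is unstable. Below `d_cr` only the zero state exists (stable).
At `d = d_cr` the two merge; the flow is non-positive for all `C >= 0`, so
the merged state attracts from the right (strictly it is semistable; the
report labels it stable, which is how the merged state behaves for
physical, non-negative densities, and records `semistable_at_zero`
internally). The stable branch is therefore piecewise linear in `d`: zero
up to `d_cr`, slope `k1/kd1` above it.

Only the ratio `k1/kd1` and `k2` are identifiable from the steady-state
relation, so `tdc_params_ratio()` constructs parameter sets directly from
the ratio (with `kd1 = 1`). The reference curve uses `k1/kd1 = 0.01` and
`k2 = 0.05`, giving `d_cr = 5`:

```{r tdc}
p <- tdc_params_ratio(ratio = 0.01, k2 = 0.05, d = 10)
critical_delta(p)
tdc_steady_states(p)
```

## The four-variable activity network

All activities are normalized by the Hill half-saturation constant and are
dimensionless; time is in arbitrary units (the package deliberately does
not calibrate the time axis to hours, since any such calibration rests on
circadian arguments outside the equations). Each activity obeys
*regulation - degradation + generation*:

```
dA_Notch/dt = kNotch * H(A_WntSC | A_YAP, A_WntTA) - kdNotch*A_Notch + kPNotch
dA_WntSC/dt = kWntSC * H(A_Notch)                  - kdWntSC*A_WntSC + kPWntSC
dA_WntTA/dt = kWntTA * H(- | A_Notch)              - kdWntTA*A_WntTA + kPWntTA
dA_YAP/dt   = kYAP   * H(A_Notch)                  - kdYAP*A_YAP     + kPYAP
```

where `H(x | y1, y2, ...) = x^n / (1 + x^n + sum(yi^n))` is the activating
Hill form and `H(- | y) = 1 / (1 + y^n)` the pure-repression form
(`hill_response()`). The wiring encodes: Wnt in the SC drives Delta
expression and hence Notch activity in the contacting TAC; nuclear YAP and
TAC Wnt oppose it through in-cis Delta inhibition; TAC Notch activates SC
Wnt (a positive loop through the cell pair) and nuclear YAP (a negative
loop, YAP feeding back onto Notch), and represses Wnt in its own cell (a
double-negative loop). The interplay of the positive loops with the
Notch-YAP negative loop generates relaxation-type limit cycles at the
biologically realistic Hill coefficient `n = 2`; `n` is kept as an integer
by default and non-integer values are accepted numerically but flagged.

The default `network_params()` values are the oscillatory baseline used
throughout (`kNotch = 1`, `kWntSC = 1.4`, `kWntTA = 1`, `kYAP = 0.188`,
degradation 0.2 for the three fast variables and `kdYAP = 0.02`, basal
production 0.1 everywhere except `kPNotch = 0.05`, `n = 2`). The slow YAP
degradation makes YAP the slow variable of the relaxation oscillation;
with these rates the period is about 529 time units.

Two structural properties anchor the numerics and are enforced by
property-style tests: the non-negative orthant is forward-invariant (each
right-hand side is non-negative where its own variable vanishes), and each
variable is ultimately trapped in `[kP/kd, (k + kP)/kd]`. The trapping box
also bounds the search region for multistart equilibrium finding.

## Deterministic simulation and oscillation metrics

`integrate_network()` wraps an adaptive Dormand-Prince 4(5) integrator
(deSolve's `ode45`; relative tolerance 1e-8, absolute 1e-10) and reports
on a regular grid. Internal scans that need thousands of long integrations
(amplitude scans, hysteresis sweeps) use `lsoda` with tighter tolerances
instead, purely for speed; both solvers agree to well below the metric
tolerances.

Initial conditions are not part of the model definition; the default is
`(0.1, 0.1, 0.1, 0.1)` and all metrics discard a burn-in window (default:
the first half of the horizon), after which limit-cycle attraction has
erased the start. `oscillation_metrics()` detects local extrema with a
prominence filter (1% of the variable's post-burn-in range; ties broken by
earliest time) and defines the period as the mean inter-peak interval. A
variable counts as **sustained** when three conditions hold in the
analysis window: amplitude above 1e-3 a.u., successive inter-peak
intervals within 5% of their mean, and the amplitude of the last quarter
of the window at least half that of the preceding quarter. The third
condition is deliberate: near a subcritical Hopf point a stable focus can
ring for thousands of time units above the amplitude threshold with a
perfectly regular period, and the trend test is what separates such
decaying spirals from true cycles at finite horizon.

`phase_relations()` classifies pairs as *aligned* when the peaks of one
variable fall near the peaks of the other (within 0.15 cycle) and
*anti-phase* when the peaks of one fall near the **troughs** of the other.
Anti-phase is peak-to-trough rather than "peaks half a cycle apart"
because relaxation cycles are strongly asymmetric: at the baseline the
TAC-Notch peak sits on the TAC-Wnt trough (the biologically meaningful
opposition) while the two peak times are about 0.69 cycle apart, so a
half-cycle peak-offset rule would misclassify exactly the relation the
model is built to produce.

```{r limitcycle}
traj <- integrate_network(network_params(), t_end = 3000)
m <- oscillation_metrics(traj)
m
subset(phase_relations(m), var_a == "A_Notch" & var_b != "A_Notch")
```

## The terminal-differentiation ablation

When a TAC differentiates, the daughter moves suprabasally and loses
integrin signaling, which removes the Notch-driven nuclear import of YAP.
`ablation_experiment()` integrates the full system, zeroes YAP production
terms at a switch time (default: four detected Notch periods, matching the
few-cycles narrative), continues state-continuously, and polishes the
final state to the exact equilibrium of the ablated vector field by Newton
iteration (residual below 1e-9).

Which terms to zero was a genuinely open design point. Removing only the
Notch-driven Hill term (`kYAP`) leaves the basal production running and
sends nuclear YAP to `kPYAP/kdYAP = 5`, a *high* value, contradicting the
observed low-YAP outcome in differentiated cells; zeroing both `kYAP` and
`kPYAP` (the default, interpretable as the loss of all integrin-dependent
nuclear import) reproduces the full observed pattern: the oscillation
stops, TAC Notch and SC Wnt settle above their pre-switch time averages,
TAC Wnt below, and nuclear YAP decays to zero.

## Bifurcation analysis

Equilibria solve a genuinely one-parameter problem in disguise: at a fixed
point the three downstream activities are explicit functions of
`A_Notch`. The package still treats the problem in full 4-D —
`find_equilibria()` polishes Latin-hypercube multistarts (default 64,
fixed seed) with Newton iterations using the analytic Jacobian, verifying
each root to `max|rhs| < 1e-10` — and the test suite uses the 1-D
reduction as an independent oracle for equilibrium counts.

`continue_equilibria()` implements pseudo-arclength continuation:
predictor along the unit null vector of the extended Jacobian
`[J | dF/dp]` (the parameter derivative is analytic, since each rate
enters one equation linearly), Newton corrector orthogonal to the
tangent, adaptive step (default arclength 0.02, halved on corrector
failure). Fold traversal is automatic, which matters for the bistable
parameter set (`kWntSC = 0.85`, `kYAP = 0.02`) whose S-shaped branch
cannot be traced by natural-parameter stepping. At every accepted point
the four eigenvalues are recorded. Special points are refined by
bisection *along the branch* to a parameter tolerance of 1e-5: a **Hopf
point** where the leading eigenvalue real part crosses zero with nonzero
imaginary part, a **fold** where the branch parameter passes an extremum
(equivalently, a real eigenvalue crosses zero). Tracking the maximum real
part over *all* eigenvalues, rather than over the complex pair only,
avoids spurious detections where the pair momentarily collides into two
real eigenvalues (this happens on the `kYAP` branch around 0.182-0.183
while the equilibrium stays unstable throughout).

```{r hopf}
br <- continue_equilibria(network_params(), "kPNotch", c(0.03, 0.08))
hopf_points(br)[, c("param", "A_Notch")]
```

`oscillatory_range()` operationalizes "parameter range supporting limit
cycles" as the Hopf-to-Hopf interval, optionally cross-validated by
simulation (large amplitude at the midpoint, collapse just outside each
end). `scan_table()` runs all 12 one-at-a-time scans. One parameter needs
special handling: varying `kPWntTA`, the branch has a *single* Hopf point
near 0.099 and the cycle is born subcritically there — simulated
large-amplitude oscillations persist up to a cycle fold near 0.106-0.107
and extend down to the physical boundary 0. For a bracket without a Hopf
pair the scan therefore falls back to an **amplitude scan**: coarse-grid
simulation (horizon 8000, burn-in 60%) plus bisection on the sustained
flag at each boundary. The `method` column of the scan table records
which route produced each row. This also explains why published
oscillatory-range endpoints obtained by limit-cycle continuation can
differ slightly from Hopf-to-Hopf values at subcritical ends.

`hysteresis_sweep()` complements continuation with the quasi-static
protocol: step the parameter, integrate to steady state from the previous
settled state (chunks of 1500 time units until `max|rhs| < 1e-8`, then a
Newton polish). On the bistable set the up-sweep jumps at the upper fold
and the down-sweep at the lower fold, and the two jump intervals bracket
the fold parameters from continuation — a cross-method consistency check
that the tests enforce within one sweep step.

## Stochastic ensembles

The partial-stochastic model perturbs the ODEs in two ways
(`noise_spec()`): a Gaussian perturbation of each initial-condition
component (sd `ic_sigma = 0.05`, truncated at zero) and an additive
Euler-Maruyama increment `sigma * sqrt(dt) * eta` at every fixed step
(`dt = 0.01`, which satisfies the explicit-Euler stability bound
`dt < 0.1/max(kd)` by a wide margin). The inner loop is compiled (Rcpp)
and draws its normals from R's RNG, so per-trajectory seeds derived once
from the master seed give reproducible, order-independent ensembles; two
runs with equal seeds are bit-identical. Ensembles default to 1000
trajectories summarized by per-time mean and min/max envelope against the
adaptive-RK deterministic reference; trajectories reaching non-finite
values are excluded and counted (more than 1% is an error), and negative
excursions are not clamped by default (a reflect-at-zero mode exists, and
the negative-sample fraction is reported).

The noise amplitude default deserves its own paragraph. Additive noise on
a limit cycle diffuses the oscillation *phase*; the mean of dephased
cycles flattens even though every single trajectory keeps oscillating at
full amplitude. At `sigma = 0.01` the accumulated per-period fluctuation
(`sigma * sqrt(period)` on the order of 0.23 a.u.) rivals the Notch
amplitude (0.66 a.u.): measured over cycles 3-6 the ensemble mean retains
only about 10% of the deterministic amplitude and the envelope is wider
than the oscillation itself — a regime in which the stochastic mean does
*not* track the deterministic cycle. The default is therefore
`sigma = 0.001`, for which (same window, 1000 trajectories) the mean
retains about three quarters of the deterministic amplitude, the envelope
stays visibly narrower than the oscillation, the envelope contains the
deterministic path everywhere, and the largest mean-vs-deterministic
deviations localize at the cycle extrema — where the near-zero slope lets
asymmetric fluctuations accumulate. `deviation_report()` quantifies all
of this (per-variable RMSE, envelope widths, and the distance of the
largest deviation to the nearest deterministic extremum, in time and in
fractions of a period). The ensemble horizon is 3000 time units
(about 5.7 periods) with the mean analyzed after 50% burn-in.

## What the generator does and does not emulate

The scenario presets (`scenario_preset()`, `run_scenario()`) materialize
the study conditions exactly: the threshold response curve, the Hopf pair
in `kPNotch`, the baseline limit cycle, the stochastic ensemble, the
bistable/hysteresis set, the ablation protocol, and the 12-row
oscillatory-range table. All inputs are printed parameter values; there
is no external data. Consequently the tests certify *internal*
correctness and reproduction of the published numbers — they say nothing
about how well a single SC-TAC pair with normalized activities describes
real epidermis. Known limitations of scope, inherited from the model
itself: no spatial lattice of Delta-Notch signaling (one interacting pair
only), no coupling of the activities to downstream cell-cycle effectors,
no suprabasal stratification dynamics, no limit-cycle (Floquet)
continuation — cycle existence between Hopf points is cross-checked by
simulation instead — and arbitrary time units throughout.

## Problem sizes and reproducibility

The suite and the acceptance analyses run at the sizes used throughout
this vignette: deterministic horizons of 3000 time units for limit-cycle
metrics, 8000 for near-boundary amplitude classification, 12-row
continuation scans with arclength step 0.02 and refinement to parameter
tolerance 1e-5, hysteresis sweeps of 25 quasi-static steps, and stochastic
ensembles of 1000 trajectories at `dt = 0.01`. `scripts/acceptance.R`
recomputes the six continuation scans behind the published
oscillatory-range endpoints from scratch and writes the eight endpoint
values as JSON; all randomness (the multistart sample) is controlled by
its `--seed` argument, and the continuation itself is deterministic.
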