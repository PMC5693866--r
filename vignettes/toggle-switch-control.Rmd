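---
title: "Balancing a bistable toggle switch in silico: models, controllers and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing a bistable toggle switch in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model of the
LacI/TetR toggle switch it simulates, the numerical choices behind the
phase-portrait tools, the control laws, the synthetic-data generator, and
the calibration machinery, with the reasoning behind every tunable default.

## The circuit model

The toggle switch consists of two genes, *lacI* and *tetR*, whose products
repress each other's transcription. Repression can be relieved chemically:
aTc sequesters TetR and IPTG sequesters LacI. The model tracks six state
variables per cell: two mRNAs, two proteins (identified one-to-one with
their fluorescent reporter signals, in arbitrary units), and the two
intracellular inducer concentrations. Gene expression is described by four
pseudo-reactions per branch — transcription with Hill-type regulation,
first-order translation, and first-order degradation/dilution:

$$\frac{d\,\mathrm{mRNA}_L}{dt} = k^{m0}_L + k^m_L\,
h^-\!\big(\mathrm{TetR}\cdot h^-(\mathrm{aTc},\theta_{aTc},\eta_{aTc}),
\theta_{TetR},\eta_{TetR}\big) - g^m_L\,\mathrm{mRNA}_L$$

with $h^-(x,\theta,\eta) = 1/(1+(x/\theta)^\eta)$ the decreasing Hill
function, and symmetrically for the *tetR* branch with (LacI, IPTG).
Proteins follow $d P/dt = k^p\,\mathrm{mRNA} - g^p P$. The free-repressor
construction — total repressor multiplied by a decreasing Hill function of
its inducer — encodes allosteric sequestration: saturating inducer makes
the repressor invisible to its operator.

All rates are per minute. The shipped defaults (`default_toggle_params()`,
also in `inst/extdata/reference_params.yml`) are the fitted values of the
calibrated circuit; under the reference inducer conditions (aTc 20 ng/mL,
IPTG 0.25 mM) they make the circuit bistable, with a LacI-dominant (RFP)
attractor near (2576, 73) a.u., a TetR-dominant (GFP) attractor near
(56, 1073) a.u., and a saddle near (526, 287) a.u.

### Inducer exchange

Inducer transport across the membrane is slow on the timescale of the
control experiments and is modelled explicitly. Two variants exist:

* **symmetric** — internal aTc is slaved algebraically to the external
  concentration; IPTG relaxes as $d\,\mathrm{IPTG}/dt =
  k_{IPTG}(u_{IPTG}-\mathrm{IPTG})$.
* **asymmetric** (the reference model) — each inducer has separate import
  and export rates, selected by the sign of $(u - x)$; the boundary
  $u = x$ is assigned to the export branch, where the rate vanishes
  anyway. The default rates make aTc load quickly
  ($k^{in}_{aTc} = 0.162\,\mathrm{min}^{-1}$) and unload slowly
  ($k^{out}_{aTc} = 0.020$), consistent with strong binding/adsorption,
  while IPTG loads slowly ($k^{in}_{IPTG} = 0.0275$) and unloads faster
  ($k^{out}_{IPTG} = 0.111$). This asymmetry is what lets a short aTc
  pulse balance a four-times-longer IPTG phase in the periodic-forcing
  protocols.

The symmetric-variant rate $k_{IPTG} = 0.04\,\mathrm{min}^{-1}$ is an
order-of-magnitude choice consistent with the asymmetric rates; the
symmetric variant is retained for completeness but no headline analysis
depends on it.

## Stochastic interpretation

The same pseudo-reactions define a continuous-time Markov chain on the
four gene-expression species, with propensities equal to the deterministic
rate laws (`propensities()` and the drift-equivalence test make this
identification exact). Arbitrary fluorescence units are treated as
molecule counts one-to-one — the calibration fixes no system size, so the
initial state is rounded and the chain jumps in unit steps.

Simulation uses the **first-reaction method**: one exponential candidate
waiting time per channel, $\tau_i = \mathrm{Exp}(1)/a_i$, firing the
earliest. The compiled core (`src/ssa.cpp`) adds two rules for
time-varying inputs:

* internal inducers evolve deterministically between events via the exact
  exponential solution of the exchange ODE (they are not CTMC species);
* propensities are frozen between events and recomputed after every event
  and at every input breakpoint; a candidate jump that would cross a
  breakpoint is rejected and the clock advances to the breakpoint.

The freeze-and-recompute rule is an approximation whose error is governed
by the change of propensities over one inter-event gap; at the fitted copy
numbers events are milliseconds-to-seconds apart while exchange
half-times are tens of minutes, so the error is negligible. An all-zero
propensity state (possible only with degenerate rate sets) is reported as
frozen and the clock advances to the next breakpoint.

## Phase-portrait numerics

Phase-plane objects live in the (LacI, TetR) plane via quasi-steady-state
reduction of the fast mRNA subsystem ($\mathrm{mRNA} = f/g^m$, mRNA
half-life 5 min versus protein half-life 42 min) with the internal
inducers at their input-determined steady values. Stability calls,
however, always use the eigenvalues of the full 4x4 gene-expression
Jacobian at the lifted state: a point is stable iff all real parts are
below $-10^{-9}\,\mathrm{min}^{-1}$, a threshold that guards against
misclassifying numerically marginal roots.

* `find_equilibria()` runs damped Newton from a log-spaced multi-start
  grid spanning $[10^{-2}, 10\times]$ the full-induction protein level on
  each axis (equilibria span two orders of magnitude), merging roots
  closer than $10^{-3}$ relative distance. A brute-force 400x400
  sign-change scan of the reduced field serves as the independent oracle
  in the test suite.
* `nullclines()` solves each one-dimensional zero problem by bracketed
  root finding; each component is strictly monotone along its grid line,
  so the root is unique.
* `separatrix()` traces the stable manifold of the saddle by backward-time
  integration from $\pm\varepsilon$ offsets along the stable eigenvector
  ($\varepsilon = 10^{-3}$ of the saddle norm), truncated at the domain
  boundary.
* `time_averaged_field()` first relaxes the input-driven inducer
  subsystem — which is autonomous and independent of the proteins — onto
  its periodic orbit by iterating the exact piecewise-exponential period
  map until the relative sup-norm change per period is below $10^{-6}$
  (at least 5, at most 50 periods), then averages the reduced field along
  the orbit. Because the averaged field is separable in the two
  regulation functions, its nullclines are explicit graphs and null
  points reduce to a one-dimensional sign-change scan plus root
  polishing; 240 time samples per period resolve the orbit far below the
  field's curvature scale.

## Control

Two independent controller branches act through the inducers: aTc steers
LacI-RFP, IPTG steers TetR-GFP, each bounded in $[0, 50]$ ng/mL and
$[0, 0.5]$ mM with basal levels (20, 0.25). Measurements are read every
`dt_meas` = 5 min (a microscopy-rate cadence; the raw plant state by
default, with a hook for injecting measurement noise) and inputs are
zero-order-held between readings.

The **PI law** is
$u_{aTc} = \mathrm{clamp}\big(u^0_{aTc} + K^L_P(\mathrm{LacI}^* -
\mathrm{LacI}) + K^L_I I_L\big)$, symmetrically for IPTG/TetR. The
integral is accumulated by the trapezoidal rule on the measurement grid
(matching the held inputs) and the first $t_d = 120$ min of error are
discarded to curb start-up windup. The default gains are
$K^L_P = 3.3\times 10^{-2}$, $K^L_I = 1.32\times 10^{-4}$,
$K^T_P = 1.65\times 10^{-2}$, $K^T_I = 4.6\times 10^{-4}$, with the
integral gains read **per minute** of accumulated error. This reading is a
deliberate design decision: rescaling the published per-second figures by
60 makes the integral term dominate within two control steps and the
simulated loop limit-cycles between the attractor basins, while the
per-minute reading reproduces the documented behavior — the controlled
cell circles its target without committing. The **bang-bang law** applies
the maximal inducer when the measured level is strictly below target and
the minimal one otherwise (ties take the minimal branch); it ignores the
gain fields entirely.

When targets are unset, the closed-loop harness uses the saddle
coordinates at the basal inputs — the natural "balanced, undecided"
setpoint.

A cell is **committed** to an attractor when its (LacI, TetR) point is
within 0.1 relative Euclidean distance of that attractor in log
coordinates. The log metric makes the rule symmetric across the two
attractors despite their very different absolute levels; the figures that
motivated the rule label fates only visually, so a quantitative threshold
had to be chosen once and is used consistently everywhere (closed-loop
commitment checks, post-release fate labels).

## Periodic forcing

`run_periodic_forcing()` applies a two-phase alternating protocol
(`forcing_schedule(t_IPTG, t_aTc)`) to an independent stochastic
population, then reverts to basal inputs at `t_release`. Cells start from
the GFP-dominant steady state (the pre-culture condition). For the
120 min / 0.5 mM IPTG + 30 min / 50 ng/mL aTc protocol the time-averaged
field has a single null point in the balanced region: cells whose
commitment dynamics (hours) are slower than the forcing period follow the
averaged field and orbit that point without committing; on release all
cells fall into the RFP basin. The 180/30 protocol parks the population
lower, near the separatrix, and the post-release fates split. The
180 min-phase IPTG concentration is configurable: one figure caption
prints 50 mM for this protocol while the system-wide maximum is 0.5 mM
elsewhere — almost certainly a typo — and all shipped runs use 0.5 mM.

## Synthetic calibration data

`gen_calibration_experiment()` emulates the step-response calibration
campaign: `n_cells` cells (default 9, the experimental count) simulated
under a step schedule exercising one switching direction, channel-averaged
and then degraded with multiplicative log-normal measurement noise
(median 1). Phenotypic heterogeneity multiplies a subset of kinetic
parameters (defaults: the four production rates) by per-cell log-normal
factors. Both CVs default to modest values — heterogeneity 0.1, noise
0.05 — chosen once to visibly spread an in-silico population the way real
cell populations spread; log-normal keeps everything positive and matches
the multiplicative character of expression variability. The generator is
a pure function of its seed.

What it does **not** emulate: imaging artifacts, segmentation error,
mother-machine geometry, cell filamentation or exclusion rules, growth
rate feedback, or division/partitioning noise. Passing recovery tests on
these data therefore certify the estimation machinery, not robustness to
real microscopy pathologies.

## Calibration

The objective is the mean squared relative deviation between the
deterministic model prediction and the averaged traces, over all
experiments, channels and time points. Relative deviations weight the
low-expression phases — where switching happens — as heavily as the
high-expression plateaus. Integration failures return a large finite
penalty so the global optimizer can continue. Each experiment starts from
the deterministic equilibrium under its first input condition approached
from the GFP-dominant side, reflecting pre-equilibrated cells.

Optimization runs a (mu/mu_w, lambda) covariance-matrix-adaptation
evolution strategy, written in-package (`cma_es()`) with Hansen's standard
parameter recommendations, in log10-parameter space with box bounds
(rates span orders of magnitude, and log-space makes the default step
size `sigma0 = 0.3` mean "a factor of two"). Bounds are enforced by
evaluating at the feasible projection plus a quadratic distance penalty.
Restarts re-seed from uniform draws in the log box. The exchange
parameters stay out of the default fit vector — mirroring their original
manual adjustment — unless explicitly listed as free.

`recovery_report()` compares fitted to generating values and flags
practically unidentifiable directions: a parameter is *sloppy* when a
±50% perturbation of its fitted value moves the objective by less than
0.01 (one percent mean squared relative deviation). The threshold is
absolute because the objective at a successful noiseless fit is itself
near zero, making relative criteria degenerate.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: 64 Newton starts for
equilibrium finding (the brute-force oracle uses a 400x400 grid), a
200x200 grid with 240 orbit samples for averaged fields, 500 stochastic
replicates for the ensemble-mean law, 16-cell populations over 40 h for
forcing runs, $10^4$ draws for the waiting-time and selection laws, and a
1500-evaluation CMA-ES budget for the four-parameter recovery
(thresholds and degradation rates; identifiable to well under 1% on
noiseless data). These sizes were chosen as the smallest that leave each
statistical check comfortably powered.

## Known limitations

* No bifurcation continuation: equilibrium structure is analyzed at fixed
  inputs only, and the input-plane stability map is only a coarse scan.
* The CTMC treats fluorescence units as counts; absolute noise magnitudes
  therefore inherit the arbitrary unit scale.
* Time-varying propensities use freeze-and-recompute rather than exact
  time-dependent thinning; adequate here, but not for models whose inputs
  move on the inter-event timescale.
* No model-predictive control or state estimation; the controllers are
  deliberately the simple laws they are, and follower populations are
  open-loop.
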