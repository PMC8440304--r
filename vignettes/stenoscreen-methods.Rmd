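---
title: "Methods: virtual patient haemodynamics and stenosis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual patient haemodynamics and stenosis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stenoscreen` builds virtual patient databases (VPDs) of the aorto-iliac
bifurcation with a one-dimensional blood-flow model and uses them to
train and evaluate machine-learning classifiers that screen for arterial
stenosis from pressure and flow-rate waveforms.  This vignette is the
package's account of the underlying science: the model and its
assumptions, the tunable parameters, the numerical choices, and the
design decisions taken where more than one defensible option existed.

## The physical model

Each vessel is a deforming impermeable tube carrying incompressible
blood.  Averaging over the cross-section gives mass and momentum
equations in the area `A(x,t)` and mean velocity `U(x,t)`:

$$A_t + (AU)_x = 0, \qquad
  U_t + U U_x + \frac{1}{\rho} P_x = \frac{f}{\rho A},$$

with wall friction $f = -2(\zeta + 2)\mu\pi U$, where $\zeta$ encodes the
assumed velocity profile.  The system is closed by an elastic tube law

$$P = P_{ext} + P_d + \beta\,\frac{\sqrt{A}-\sqrt{A_d}}{A_d},
  \qquad \beta = \tfrac{4}{3}\,E\,h\sqrt{\pi},$$

relating pressure to the deviation of the area from its diastolic
reference $A_d$.  The formulation deliberately drops three-dimensional
flow features (vortices, recirculation, asymmetric lumen shapes): the
screening hypothesis concerns space-averaged waveforms, which the 1D
model captures at a computational cost that permits thousands of
simulated patients.

The network is the abdominal aorta bifurcating into the two common
iliacs.  A periodic volumetric flow rate, represented by a Fourier
series truncated at the 5th order (11 free coefficients, the constant
sine term being identically zero), drives the aortic inlet.  Each iliac
terminates in a three-element Windkessel model — proximal resistance
R1, compliance C, distal resistance R2 — standing in for the distal
vasculature.  Measurements are taken at three sites: the inlet (P1, Q1)
and the two iliac outlets (P2, Q2, P3, Q3).

Stenoses are parameterised on the normalised vessel axis by a severity
$S$ and extent $[b, e]$; the diastolic area is scaled by

$$A_n(x_n) = \Big(1-\frac{S}{2}\Big) +
             \frac{S}{2}\cos\!\Big(\frac{2\pi (x_n-b)}{e-b}\Big)$$

inside $[b, e]$ and is 1 elsewhere.  The map is continuous at the edges
and reaches its minimum $1-S$ at the midpoint.  Only the diastolic area
profile of the diseased vessel changes; wall thickness and Young's
modulus keep their sampled values.  At most one vessel per patient is
diseased.

### Unprinted constants

The model family's usual reference values are adopted and are all
configurable through `blood_model()` and the study configuration:
$\rho = 1060$ kg m⁻³, $\mu = 4$ mPa s, $\zeta = 9$, $P_{ext} = 0$,
$P_d = 75$ mmHg, cardiac period $T = 1$ s, Windkessel outflow pressure
0.  The default inlet waveform is a half-sine systolic ejection (peak
60 mL s⁻¹ over a systole of $0.3\,T$, zero in diastole) projected onto
the 5th-order Fourier basis; it is qualitatively representative of
abdominal aortic inflow and its projection defines the mean values of
the 11 inlet coefficients used by the population sampler.

## Numerical scheme

The solver (in compiled code, `src/solver.cpp`) uses a MacCormack
predictor–corrector on a uniform grid per vessel.  The results of the
study depend on *converged periodic waveforms*, not on a particular
discretisation, so the scheme was chosen for robustness and simplicity
in the smooth-flow regime the population inhabits; the invariant suite
(lumped-model steady state, junction mass balance, mirror symmetry,
monotone grid refinement) is the arbiter of correctness.

Boundary treatment is by Riemann invariants $W_{1,2} = U \pm 4c$ with
$c = \sqrt{\beta / (2\rho A_d)}\,A^{1/4}$:

* **Inlet**: the Fourier flow rate is imposed through the incoming
  characteristic; the outgoing invariant is interpolated at the foot of
  its characteristic and a scalar Newton solve recovers the boundary
  area.
* **Bifurcation**: conservation of mass plus continuity of total
  pressure $P + \tfrac{1}{2}\rho U^2$ (the standard choice for this
  model family; a static-pressure option is provided via
  `solver_config(junction_rule = "static_pressure")`), solved by a
  damped 3×3 Newton iteration to relative increment $10^{-13}$.
* **Outlets**: the Windkessel compliance pressure is advanced
  implicitly; the coupled boundary area solves a scalar Newton
  iteration.

The time step is fixed per simulation from a CFL condition (default
Courant number 0.7) using the maximum wave speed evaluated at a capped
pressure of 260 mmHg plus an 8 m s⁻¹ velocity margin covering stenotic
jets.  Each vessel uses 41 nodes by default (`elements = 40`,
grid spacing ≈ 2 mm), which resolves the shortest admissible stenosis
(10% of the vessel length) with several nodes.

Cycles are integrated until the relative L2 change of the inlet
pressure waveform between successive cycles falls below
`periodic_tolerance` (default $10^{-4}$).  The approach to the periodic
state is dominated by a slow Windkessel volume mode with time constant
$\approx R_2 (C + C_{vessel})$; the solver therefore seeds the
compliance pressures and the 1D fields from the lumped (0D) mean state
and applies Aitken extrapolation of the geometric convergence of the
compliance pressures every third cycle, which reduces a typical run
from ~18 to ~5 cycles with no change to the converged state (the
convergence criterion is unchanged).  Numerical blow-up (negative area
or NaN) and failure to reach periodicity raise classed errors
(`stn_simulation_failure`, `stn_nonconvergence`); the VPD builder logs
and resamples such patients.

The final cycle is resampled to 256 uniform samples — ample for
waveforms later truncated to 5 harmonics.

## The virtual population

The 25 network parameters are sampled independently and normally with
standard deviation 20% of the mean (`sample_healthy()`), with means:

| Parameter | Aorta | Iliac |
|---|---|---|
| Length | 8.6 cm | 8.5 cm |
| Wall thickness | 1.03 mm | 0.72 mm |
| Reference diameter | 1.72 cm | 1.2 cm |
| Young's modulus | 500 kPa | 700 kPa |

and Windkessel means $R_1 = 6.81\times 10^{7}$ Pa s m⁻³,
$R_2 = 3.10\times 10^{9}$ Pa s m⁻³, $C = 3.67\times 10^{-10}$ m³ Pa⁻¹
(both outlets share the distributions but are sampled independently; the
two iliac vessels share one sampled geometry/stiffness, imposing
left–right symmetry of the vessels but not of the distal beds).

Two sampling decisions deserve note.  First, the published parameter
table prints an R1 standard deviation of $1.36\times 10^{6}$, which is
20% of the mean divided by ten; the stated 20%-of-mean rule is taken as
authoritative (the printed value looks like a typo) and the default SD
is $1.362\times 10^{7}$, with `r1_sd_printed = TRUE` available to
reproduce the printed value.  Second, non-positive draws of quantities
that must be positive are redrawn rather than clipped, preserving
continuous distributions without point masses; Fourier coefficients
with zero mean stay exactly zero.

Disease assignment (`sample_disease()`) makes an expected 50% of
patients healthy and spreads the rest equally over the three vessels.
The geometry is sampled sequentially from uniform distributions under

$$0.2 \le r \le 0.8,\quad 0.1 \le b \le r-0.05,\quad
  r+0.05 \le e \le 0.9,\quad 0.5 \le S \le 0.9,$$

where the reference location $r$ enforces a minimum stenosis extent of
10% of the vessel.  The sampling order follows the listing above
($r, b, e, S$); severity is independent of the bounds of the others, so
the order only matters for reproducibility of streams, not for the
marginal distributions.

Simulated patients pass three hard inlet-pressure filters (strict
inequalities, evaluated in mmHg): maximum below 225, minimum above 25,
pulse pressure below 120.  `build_vpd()` repeats sample → simulate →
filter until each class reaches its target, skipping simulation for
classes already full, and aborts with diagnostics if the acceptance
rate falls below a configurable floor.

The full-scale design follows the events-per-variable (EPV) rule: with
a minimum of 12 training examples of the rarest class per input
dimension, at most 66 input dimensions and two-thirds of the VPD used
for training, each diseased class needs $12 \times 66 / (2/3) = 1188$
patients and the balanced healthy class $3564$ (EPV 36)
(`epv_requirements()`).

## The surrogate generator

`surrogate_vpd()` produces VPD-shaped cohorts without solving the
physics: each measurement is a band-limited (5-harmonic) waveform with
patient-level amplitude/mean/phase variability and class-dependent
perturbations that grow with severity and are exactly symmetric under
the iliac relabelling.  It emulates the *statistical shape* of solver
output — periodicity, band-limitedness, physiological pressure ranges,
subtle class signal — and is used where the ML layer, not the physics,
is under test.  It does **not** emulate wave reflection physics, the
nonlinear severity response, or parameter–waveform correlations, so
classifier accuracies obtained on it say nothing quantitative about
real (or simulated-physics) data; tests that pass on the surrogate
demonstrate the correctness of the learning machinery, no more.

## Features and classifiers

Waveforms are reduced to the 11 Fourier coefficients
$\{b_0, a_1..a_5, b_1..b_5\}$ per measurement by linear least squares
on the uniform grid (equivalent to the discrete transform there, hence
exact for band-limited inputs).  Feature matrices are standardised by
Z-score using training-set statistics only — the conventional choice,
made explicit here because pooled standardisation would leak test
information; zero-variance coordinates receive SD 1 with a warning so
degenerate inputs cannot crash a pipeline.

The cost-weighted logistic regression is implemented in the package
(loss, analytic gradient, deterministic full-batch BFGS from a zero
start, relative-loss tolerance $10^{-8}$, no regularisation by default
with an optional L2 flag for numerical stability; the intercept is an
appended constant feature).  Class imbalance is handled by the weight
$w$ solving $r = w\,m^{(1)}/m^{(2)}$; $r = 1$ is the default
everywhere.  On linearly separable training sets the optimum is at
infinity and the optimiser stops at its iteration cap with a tiny
gradient; this is detected and treated as benign convergence.

SVM (RBF and linear kernels), Gaussian naive Bayes and random forest
are adapters over `e1071` and `randomForest`; the package contributes
their configuration (cost weights via class weights, a one-off
grid search for the forest's tree count and size that is then frozen),
not their internals.  SVM decision values are used only for ranking and
tie-breaks, never as probabilities.

Multiclass ensembles: one-vs-all (4 members, argmax of member
probabilities), one-vs-one (6 pairwise members, majority vote), and the
custom probabilistic configuration (CPC; 3 disease members, healthy by
default unless the maximum disease probability reaches the boundary
B).  Tie-breaks are deterministic and documented: class order
C1 < C2 < C3 < C4 for argmax ties, summed member scores then class
order for vote ties.  Predicted probabilities are clipped to
$(10^{-12}, 1-10^{-12})$ so that the CPC boundary rule at $B = 1$
classifies every patient healthy even when an activation saturates in
floating point.  The boundary value used for headline multiclass tables
is not dictated by anything in the problem; the conventional midpoint
$B = 0.5$ is the default, and ROC sweeps cover the full range.

## Metrics and the reporting convention

Sensitivity and specificity are recalls of the positive and negative
outcome; the F score is
$F = (\delta^2+1)\mathcal{P}\mathcal{R} / (\delta^2\mathcal{P} +
\mathcal{R})$ with $\delta = 1$ throughout.  For binary screening
configurations the package reports **sensitivity as the recall of the
disease-present outcome** and **specificity as the recall of the
disease-absent outcome**, while the F score is computed for the
configuration's own positive class (healthy for the entire-network
configuration, the target vessel for individual-vessel ones) on
$w$-weighted counts.  This is the only convention simultaneously
consistent with the balanced worked examples (F = 8/13 and 2/7, printed
as 0.61 and 0.28 — the printed values correspond to truncation at two
decimals) and with the tabulated best-combination scores it must
reproduce (0.6429 for the entire-network case; 0.8437 for the aortic
individual-vessel case under weighted-balanced counts), and the
acceptance tests pin it down numerically.

Five-fold validation means five independent random 2/3–1/3 splits (not
a partition); per-fold metrics are retained and averaged.  ROC curves
for the CPC sweep 101 evenly spaced boundaries plus the exact endpoints
0 and 1; only the healthy-class curve is complete by construction
(every patient is healthy at $B = 1$ and none at $B = 0$) and its AUC
is computed by the trapezoidal rule on FPR-sorted points.  Disease
classes' curves are reported without forcing completeness.

## Problem sizes used by the test suite

The shipped tests exercise the physics on single patients and small
cohorts and the ML layer on surrogate cohorts of 200–360 patients; the
end-to-end screening check builds a 600-patient solver cohort
(300 healthy / 100 per diseased vessel — the full design's 3:1:1:1 mix
at one-twelfth scale) and requires the all-measurement RBF-SVM
entire-network classifier to beat naive classification
($S_e + S_p > 1$) in at least four of five folds.  These sizes are the
package's choice of a demonstration scale: large enough for the
qualitative behaviour to be stable under the fixed seeds, small enough
to run routinely.  Full-scale results (7128 patients) are obtained with
the same functions by raising the targets in the study configuration.

## Known limitations

* Parameters are sampled independently; real arterial parameters are
  correlated, so the virtual population is broader than a physiological
  one and classification is correspondingly harder.
* One stenosis per patient, three vessels, constant properties along
  each vessel, elastic (not viscoelastic) walls.
* No measurement noise model: the Fourier truncation would filter
  additive white noise anyway, but structured measurement error is out
  of scope.
* The 1D model has no empirical stenosis pressure-loss term; trans-
  stenotic losses are viscous and inertial only, which is consistent
  with the model family but understates severe-jet losses.
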