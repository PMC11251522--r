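---
title: "Mechanistic analysis of multiphasic transcription factor-nucleic acid binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic analysis of multiphasic transcription factor-nucleic acid binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

## The problem

Transcription factors such as estrogen receptor alpha (ERα) and Sox2 bind
both DNA and RNA, and solution measurements of those interactions by
fluorescence polarization (FP) and surface plasmon resonance (SPR) show
kinetics that a single-step binding scheme cannot produce: biexponential
dissociation from every ligand, and — for the ERα DNA-binding domain with its
basic hinge extension — a striking "lagged triphasic" association in which a
fast binding phase is separated from a second one by a 10–20 minute quiescent
interval. `bindkin` packages the full analysis route for such data:

* candidate mass-action reaction schemes and their rate laws, including an
  isomer-limited sequential-binding scheme with *feedback-catalyzed*
  isomerization that can generate the lag;
* error-controlled simulation of the two-phase (association, then
  dilution-induced dissociation) experimental protocol;
* the equilibrium and progress-curve regressions used on FP/SPR data;
* trace normalization, initial-rate extraction, and phase-count
  classification;
* a seeded synthetic-data generator so the entire pipeline can be exercised
  and validated at desk scale.

## Reaction schemes

`build_scheme()` constructs five networks. Species names follow the field's
convention: `E` free protein monomer, `L` free (labeled) nucleic acid, `EL`
the initial 1:1 complex, `ELstar` an isomerized complex, `E2L` a
two-protein complex.

The **sequential protein-binding scheme** (`"sequential"`) is
`E + L ⇌ EL` and `E + EL ⇌ E2L`: after initial binding, an additional
monomer binds the complex with its own rates. If the second monomer binds
less stably, dissociation is biphasic — the inferred description of Sox2 HMG
binding to its cognate DNA site and to a G-quadruplex RNA.

The **locked-conformation scheme** (`"locked"`) is `E + L ⇌ EL ⇌ EL_locked`,
where the locked complex must isomerize back before the ligand can leave.
Its signature is that a *short* pre-incubation ablates the slow dissociation
phase (there has been no time to lock), which `run_variable_incubation()`
reproduces; that signature is what rules the model out for ERα.

The **protein/ligand isomer schemes** (`"protein_isomer"`, `"ligand_isomer"`)
let one binding partner interconvert between two states with different
binding rates. No rate constants were ever measured for these; they are
provided structurally for completeness.

The **feedback-isomerization scheme** (`"feedback"`) is the mechanistically
novel one:

```
E + L  ⇌ EL           (k1, k_m1)
EL     ⇌ EL*          (k2, k_m2)          intrinsically slow
EL + EL*  → 2 EL*     (k_alpha)           feedback catalysis
EL + E2L  → EL* + E2L (k_beta)            feedback catalysis
E + EL* ⇌ E2L         (k3, k_m3)
E + EL  → E2L         (k3b, irreversible)
```

Isomerization of the initial complex is slow on its own (`k2` ≈ 1e-5 s^-1)
but is catalyzed by collision with an already-isomerized or higher-order
complex. That autocatalysis is what produces a lag: almost nothing happens
until a seed population of `EL*`/`E2L` exists, after which conversion runs
away. At high protein the direct `k3b` route short-circuits the lag, so the
lag is only visible at low-to-intermediate protein — the concentration
dependence seen in the FP data.

`feedback_rhs()` implements the coupled rate equations. As published, the
free-protein equation omits the consumption of `E` by the `k3b` route, so
the printed system leaks protein at rate `+k3b·[E]·[EL]` (summing the five
equations with protein weights 1, 0, 1, 1, 2 leaves exactly that term). The
package default adds `−k3b·[E]·[EL]` to the free-protein derivative so
that total protein is conserved; `verbatim = TRUE` reproduces the printed
system exactly so the leak can be audited (`conserved_totals()` provides the
conservation basis from the stoichiometric null space). Two further unit
decisions: `k2` is printed with bimolecular units but multiplies `[EL]`
alone, so it is treated as first-order (1e-5 s^-1); `k3b` is irreversible
exactly as printed (`k_m3` routes `E2L` only to `E + EL*`). All internal
units are molar and seconds; readers convert nM/µM and minutes/hours on
input.

The observable is the relative predicted anisotropy
(`relative_anisotropy()`):

\[
A_{rel} = \frac{[E_2L] + \tfrac12([EL^*]+[EL])}{[E_2L]+[EL^*]+[EL]+[L]}
\]

i.e. a stoichiometry-weighted bound fraction: free ligand contributes 0,
single-protein complexes 0.5, two-protein complexes 1. Isomerized or locked
complexes share their parent's weight, since the published observable is
defined only for the feedback scheme and anisotropy tracks bound protein
mass, not conformation. Being a ratio, `A_rel` is invariant under uniform
dilution — which is why the dissociation trace starts exactly where the
association trace ends in the two-phase protocol.

## The simulated protocol

`sim_protocol()` encodes the study conditions: 5 nM ligand, total protein on
the two-fold grid 2^-12 … 2^0 µM, a 1.5 h association phase, a 10^6-fold
dilution emulating competitor addition (the published simulations model
competitor this way; biphasicity was shown to be competitor-independent, and
an explicit competitor species is out of scope), and a 1 h dissociation
phase. Variable pre-incubation (`run_variable_incubation()`) replaces the
association duration; jump dilution uses d_f ≈ 80.

Integration is error-controlled, adaptive and stiff-capable
(`deSolve::ode`, lsoda — rate constants span nine orders of magnitude in the
feedback set). Choices that matter:

* Default tolerances `rel_tol = 1e-10`, `abs_tol = 1e-14` M. The published
  simulations report on a fixed 25 ms grid; here `dt_out` is purely a
  sampling grid (default 1 s; 25 ms is supported but only costs memory).
  `hmax` and the initial step are tied to the phase duration, not to
  `dt_out`, so refining the reporting grid cannot change the step sequence —
  halving `dt_out` reproduces shared points bit-for-bit.
* The phase-2 absolute tolerance is divided by the dilution factor, keeping
  it meaningful for the post-dilution concentration scale.
* Species slaved to a fast equilibrium (e.g. `EL*` when `k3·[E]` is ~10^3
  s^-1) sit numerically at zero with solver noise well above `abs_tol`;
  negative excursions within `max(1e3·abs_tol, 1e-5·max concentration)` are
  clamped to zero, anything larger raises an integration error. Conservation
  (< 1e-6 relative drift) and matrix-exponential oracles on first-order
  subnetworks (< 1e-6 relative) independently confirm the accuracy of the
  meaningful components.

## Regression models

Five models cover the fits used on real data (`eval_model()` evaluates them,
`fit_*()` estimate them by unweighted least squares on linear axes, as the
source analyses did):

1. **Hill isotherm** — `A = A_min + (A_max − A_min)·E^n/(E^n + Kd^n)`.
2. **Two-transition isotherm** — an `alpha`-weighted sum of the quadratic
   tight-binding (ligand-depletion) form in `Kd1` and a hyperbola in `Kd2`,
   for ligands with a sub-ligand-concentration first transition (Sox2 with
   CBS DNA and G4 RNA).
3. **Monophasic association** — single observed rate.
4. **Biphasic association** — fast/slow rates with fraction `beta_fast` of
   the dynamic range on the fast phase.
5. **Biexponential dissociation** — with the two constraints the protocol
   requires: `A_max` fixed to the internal-control level at the moment
   dissociation was induced (a fixed `A_max` is reported exactly as
   supplied), and an optional monophasic constraint (`k_fast = 0`,
   `beta_fast = 0`).

Numerical choices: Levenberg–Marquardt (`minpack.lm::nlsLM`) behind a small
deterministic multi-start; dissociation constants fitted on log scales
(they sit 7–9 decades below the signal, and a linear parameterization makes
the start singular), with ordering `Kd1 ≤ Kd2` enforced by
`Kd2 = Kd1 + exp(ldK)` and ties between equal-RSS starts broken toward
larger `alpha`; rate initializations are data-driven — the slow rate from a
log-linear fit of the final 20 % of the trace, the fast rate from the first
10 %, the amplitude split from extrapolating the slow phase to zero — so
fits are deterministic; exponential phase labels are swapped post-fit if
needed so `k_fast ≥ k_slow` always; tight optimizer tolerances with a
default-tolerance retry for exactly-zero-residual fits. Model choice between
mono- and biphasic association, when not specified, uses a small-sample
corrected information criterion; a fitted rate ratio below 3 triggers a
phase-indistinguishable warning rather than an error.

## Trace analysis

* `to_fraction_bound()` rescales raw anisotropy against the two internal
  controls. Control levels are scalars (means of each control's final
  10-minute plateau) because the controls are flat by design and scalar
  levels inject less noise; a time-matched option exists for drifting
  controls. Values are deliberately not clamped to [0, 1].
* `spr_delta_ru()` subtracts the reference flow cell (linear interpolation
  onto the sample grid), then the baseline-window mean, re-zeroing the
  segment at its own start.
* `initial_rate_fp()` fits a cubic smoothing spline (smoothness by
  generalized cross-validation), and divides the spline slope at the first
  point by the spline dynamic range. The estimate is invariant under affine
  signal transforms, so raw anisotropy works as well as fraction bound.
* `initial_rate_spr()` is the windowed 3-second slope over the segment's
  dynamic range; segments with negligible range are excluded (their
  normalized slope is meaningless).
* `fit_kon()` regresses rate on concentration with zero intercept after
  pruning the high-concentration plateau. The published analyses pruned "to
  the initial linear phase" by eye; the package's deterministic rule —
  include points, in ascending concentration, while the local secant slope
  stays at or above half the slope through the two lowest concentrations —
  is auditable and reproduces a manual mask on linear-plus-plateau series.
* `kd_from_rates()` is the koff/kon arithmetic producing the candidate
  K_d of each kinetic phase, displayed at two significant figures
  (`format_kd()`).

### Phase-count classification

`classify_phases()` reproduces the visual taxonomy (monophasic / biphasic /
lagged triphasic) with fixed, configurable rules:

* The signal derivative is taken analytically from a GCV smoothing spline
  fitted in log-time. Association phases here are separated by orders of
  magnitude in timescale; log-time resolves both and suppresses spline
  ringing at sharp rises.
* *Lagged triphasic*: two derivative maxima separated by a minimum below
  25 % of the first maximum, where the sub-threshold interval lasts at least
  2 minutes. The threshold formalizes what was identified visually; the
  minimum duration ensures a lag is a sustained quiescent interval, not a
  smoothing ripple (the published lags last 10–20 minutes).
* *Biphasic*: the two-exponential fit beats the one-exponential fit by the
  information criterion **and** both phases are resolved: rate ratio ≥ 3,
  fast fraction not pinned at 0/1, and a fast-phase half-life of at least
  three sampling intervals. The last rule matters at high protein: a
  pseudo-first-order phase with k ≈ 1 s^-1 completes within the instrument
  dead time / first samples, and claiming a kinetic phase from fewer than
  ~3 points is not defensible — such a burst is treated as an unresolved
  offset, which is exactly why high-concentration association *appears*
  monophasic in both the real and simulated data.
* Everything else is monophasic.

With the reference feedback parameter set the full titration classifies as
lagged at low-to-intermediate protein, never regains the lag once it
disappears with rising concentration, and is monophasic at 1 µM; raising the
reverse isomerization rate `k_m2` from 3.2e-3 to 10 s^-1 (the RNA-like
variant) abolishes the lag across the entire grid.

## Synthetic data

The generator's defaults are the study conditions: 5 nM ligand; serial
two-fold protein dilutions; FPCD competitor emulated as a 10^6 dilution;
FPJD as an ~80-fold dilution; SPR with 5 min association and a 30–60 min
wash. Published values never fixed the raw-signal scale or the noise, so the
package chooses once: anisotropy 0.06 free / 0.16 saturated (all recoveries
are invariant to this affine mapping), Gaussian noise sigma 0.005 anisotropy
units (0.5 RU with optional 0.01 RU/s common-mode drift for SPR) — levels
that keep parameters on the published scale identifiable. Replicates use
independent seeds only, since replicate-to-replicate variability structure
was never reported. The SPR wash is modeled as first-order clearance of the
free solutes (the chip retains complexes; buffer flow removes everything
else).

`catalog()` carries the published constants (equilibrium and kinetic, in
molar/seconds) for the eight interactions; `make_fixtures()`,
`run_recovery()` and `kinetic_report()` chain generation, fitting and
reporting into a deterministic, byte-reproducible pipeline. Parameter
recovery on noiseless data is exact to well below 0.1 % relative for every
catalog entry; at sigma = 0.005 the median recovered value over 200 seeds
stays within 5 % of the generating value for every parameter, including the
ligand-depletion-limited `Kd1` of the two-transition fits (individual noisy
replicates of that parameter scatter more — it is weakly identified below
the ligand concentration, which is why it was only ever reported as a
bound).

What passing these tests shows — and does not. The generator reproduces the
*statistical structure* of the assays (curve families, noise, controls,
protocol timing), so green tests demonstrate that the estimation pipeline is
correct and well-conditioned under those conditions. It does not emulate
plate-position effects, photobleaching, temperature drift, SPR mass
transport (acknowledged to deflate apparent association rates, and
deliberately left uncorrected here as well), or instrument dead time beyond
the sampling-resolution rule above; agreement with synthetic data therefore
cannot certify accuracy on a real instrument's systematics.

## Problem sizes

The test suite and the acceptance script run at desk scale: 1 s reporting
grids over 1.5 h association / 1 h dissociation phases (3,600–5,400 points
per trace), 13-point titrations, 15-point isotherms, and 200-seed recovery
studies — a few minutes end to end.

## Known limitations

* The feedback scheme is a *framework* model; exhaustively fitting its nine
  constants to data by iterative integration and regression was never
  practical, and no global fit to traces is attempted here either.
* The 2:1-initial-complex variant of the feedback scheme is mentioned as
  possible but its equations were never given; it is not implemented.
* The ligand-isomer scheme has no published rate constants and is
  structural only.
* The locked-conformation prediction of a "~5 % slow phase after a 2 min
  incubation" depends on rate constants that were never stated; the package
  reproduces the qualitative direction (short incubation → smaller slow
  phase), not that number.
* Fit uncertainties are asymptotic standard errors; the published constants
  instead carry mean ± half-range across replicate experiments, which is a
  reporting convention, not a fitter feature.
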