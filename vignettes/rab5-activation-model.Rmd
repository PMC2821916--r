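---
title: "Kinetics of delayed-onset Rab5 activation: model, analysis and synthetic experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of delayed-onset Rab5 activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rab5onset)
```

## The model

Rab5 is a small GTPase of the early endosome, active when GTP-bound. Its
exchange factor (GEF) Rabex-5 reaches the membrane-bound substrate
Rab5-GDP by two routes: a **direct** pathway, in which Rabex-5 binds the
endosomal membrane through its early-endosomal-targeting domain, and an
**indirect** pathway, in which a cytosolic Rabex-5/Rabaptin-5 complex is
recruited by Rab5-GTP itself — the product of the reaction — forming a
positive feedback loop through the Rabex-5/Rabaptin-5/Rab5-GTP tripartite
complex.

Write `z` for the Rab5-GTP concentration (total Rab5 `z_tot`, all
membrane-associated), `x0` for cytosolic Rabex-5, `x1` for directly
membrane-bound Rabex-5 and `x2` for the tripartite complex, with
`x0 + x1 + x2 = x_tot`. Direct targeting is fast relative to the other
steps and is treated as an equilibrium, `x1 = sigma * x0`, which reduces
the dynamics to two variables:

    dz/dt  = alpha * (x1 + x2) * (z_tot - z) - beta * z
    dx2/dt = gamma * x0 * z - lam * x2
    x0     = (x_tot - x2) / (1 + sigma),   x1 = sigma * x0

`alpha` (M^-1 s^-1) is GEF catalysis per unit enzyme; `beta` (s^-1) is
GAP-driven hydrolysis with the GAP concentration absorbed; `gamma`
(M^-1 s^-1) and `lam` (s^-1) are formation and dissociation of the
tripartite complex, with cytosolic Rabaptin-5 absorbed into `gamma`;
`sigma` (dimensionless) is the direct-targeting equilibrium constant.
Everything inside the model is molar and seconds; fg/cell and hours appear
only at the data boundary (below).

## Steady states, threshold, sensitivity

Eliminating `x2` through its own equilibrium turns the steady-state
condition into a quadratic in `z`, solved in closed form
(`steady_state_general()`); all roots, including unphysical negative ones,
are enumerated by `find_steady_states()`.

* **Direct only** (`gamma = 0`): a hyperbola,
  `z = alpha*x1*z_tot / (alpha*x1 + beta)`, half-maximal at
  `x_tot = beta*(1+sigma)/(alpha*sigma)` (`midpoint_direct()`), Hill
  coefficient 1.
* **Indirect only** (`sigma = 0`): `z = 0` until `x_tot` exceeds the
  **delayed-onset threshold** `lam*beta/(gamma*alpha*z_tot)`
  (`onset_threshold()`), then a rational increasing branch. The threshold
  is inversely proportional to total Rab5: doubling `z_tot` halves it.

The negative branch below threshold is unphysical; the package returns the
stable branch and documents the clamp. At the threshold the zero branch and
the companion branch cross and **exchange stability** — a transcritical
bifurcation, not a fold — so the system is never bistable.
`bifurcation_scan()` verifies this structure numerically: it tracks all
branches with Jacobian-based classification (`classify_stability()`,
"marginal" when the leading eigenvalue is within `1e-9 * beta` of zero),
locates the crossing by bisection to relative precision `1e-6`, and counts
sign changes of the stable branch's slope (zero folds expected).

**Sensitivity.** The published description of the sensitivity measure is a
normalized-slope notion; the package operationalizes the Hill coefficient
with the standard 10–90% rule, `n_H = ln(81)/ln(x90/x10)`, with the two
crossing points interpolated linearly in `log(x)` because response curves
span decades. The midpoint normalized-slope measure is kept as a secondary
diagnostic (`normalized_slope()`); the two coincide for true Hill
functions but not for delayed-onset curves, which are steepest at the
threshold. For the indirect branch the 10–90% rule evaluates analytically
to `ln81 / ln(9*(lam/gamma + 0.9*z_tot)/(lam/gamma + 0.1*z_tot))`:
independent of `alpha` and `beta`, equal to 1 when `lam/gamma << z_tot`,
and approaching 2 when `lam/gamma >> z_tot` — i.e. when cellular Rab5 sits
below the affinity of the tripartite complex. The reference illustration
curves use `alpha = beta = gamma = 1, lam = 100, sigma = 0.1`; the total
Rab5 for those illustrations is not fixed by the published constants, and
the package uses `z_tot = 10`, the value consistent with a delayed onset
at `x_tot = 10`.

## From blots to molarity

`fit_standard_curve()` fits background-corrected band intensity against a
dilution series of purified protein by ordinary least squares; inverse
prediction refuses extrapolation outside the calibrated range unless
explicitly allowed. `intensity_to_fg_per_cell()` divides the
inverse-predicted mass by lysate cell count times transfection efficiency
(0.8 BHK-like, 0.2 NF73-like), and `fg_per_cell_to_molar()` applies
`M = mass / (mw * volume)` with an 80 fL mean cell volume. Default
molecular masses: 40 kDa for the indirect-only Rabex-5 truncation, 24 kDa
for Rab5, 51 kDa for GFP-Rab5 — all overridable in `cell_constants()`.
Printed concentrations in this literature carry one significant figure;
comparisons therefore use `signif(x, 1)` (or order-of-magnitude rounding
where a value is quoted as a power of ten), while exact values are always
reported alongside.

The rate constants used for unit conversion are `beta = 0.2` s^-1
(intrinsic hydrolysis `2e-3` s^-1 times a 100-fold GAP enhancement,
`estimate_beta()`) and `alpha = 2e4` M^-1 s^-1, giving
`beta/alpha = 1e-5` M. The GAP enhancement is a lower estimate; a stronger
GAP scales `beta` up and every downstream `lam/gamma` estimate down in
proportion, which `estimate_beta()` makes explicit.

## The synthetic experiment generator

`generate_dataset()` emulates a Tet-Off induction experiment: enzyme
abundance rises as a saturating exponential
`x(t) = baseline + (plateau - baseline)*(1 - 2^(-t/half_time))` from a
leaky baseline of one tenth of the plateau (an order-of-magnitude
induction). Three preset scenarios (`rab5_scenario()`) fix the study
conditions:

| scenario | sigma | z_tot (M) | profile (fg/cell) | 95% plateau |
|---|---|---|---|---|
| `nf73` | 0 | 2.5e-5 | 1.5 → 15, half-time 2.765 h | ~12 h |
| `bhk_gfp_rab5` | 0.1 | 1.2e-5 | 3.2 → 32, half-time 1.6 h | ~7 h |
| `bhk_endogenous` | 0 | 6e-6 | 3.2 → 32, half-time 1.6 h | ~7 h |

All presets share `alpha = 2e4`, `beta = 0.2`, `gamma = 1e4`,
`lam = 9.375e-2`, i.e. a true affinity `lam/gamma = 9.375e-6` M — exactly
the value implied by an onset threshold of 12 fg/cell at
`z_tot = 2.5e-5` M with `beta/alpha = 1e-5` M. Under the `nf73` profile
the enzyme crosses that threshold at exactly 6 h, so with sampling at
0/3/6/9/12 h the expected onset interval is (6, 9) h. In
`bhk_endogenous` the threshold sits at 50 fg/cell, above the 32 fg/cell
plateau, so the activity stays flat; in `bhk_gfp_rab5` the doubled Rab5
level and the active direct pathway produce activation already at the
first post-induction point.

Observations: replicate enzyme bands and a pull-down-like activity readout
`(background + scale * z/z_tot) * noise`, both with multiplicative
lognormal noise (unit mean, default CV 15% — a stated default, not a
measured value; densitometry and fluorescence are positive and
scale-proportional); three replicate arms per condition, mirroring
triplicate immunoblots; and endosome diameters
`(d0 + k*(z/z_tot)^(1/3)) * noise` per endosome, reported as the 90
largest of 30 cells x 20 endosomes. The cube-root is a
volume-proportional enlargement heuristic: only the monotonicity of the
observation map and the max-of-sample protocol are relied upon downstream,
never the exponent.

**Quasi-steady state.** Induction takes hours while the activation
kinetics relax in seconds (`1/beta = 5` s), a timescale separation of
order 1e3, so the generator computes `z(t)` from the steady-state curve by
default. A full-ODE mode exists for validation; it starts from the
pre-induction steady state at the leaky baseline and, for `sigma = 0`
(where the zero state of the deterministic equations is invariant), adds a
small basal exchange source `beta * 1e-4 * z_tot` that stands in for
GEF-independent exchange and molecular-number fluctuations. The two modes
agree within 5% wherever activation exceeds 1% of `z_tot` (verified in
the test suite).

What the generator does **not** emulate: cell-to-cell expression
variability beyond the transfection-efficiency fraction, image formation
and segmentation of real micrographs, Dox pharmacology, enzyme
degradation (the less stable direct-pathway construct declines after its
plateau in real blots), or correlated replicate errors. Passing tests
therefore certify the analysis pipeline's arithmetic and statistical
behaviour under the model's own assumptions, not the biology of real
lysates.

## Onset detection and affinity inference

`detect_onset()` has no published statistical rule to follow, so the
default codifies a conservative reading of the experiments: onset is the
first time point whose replicate-mean readout exceeds the control-arm mean
by `k = 3` control SDs *and stays above at every later point*; the
interval is (previous point, that point), and the enzyme level at onset is
read at the **lower edge** — matching the use of the 6-h level when
activation appears between 6 and 9 h. A least-squares change-point variant
is available behind `method = "changepoint"`. Either the pull-down or the
endosome-size readout can drive detection (`readout=`); the activity
readout is the default because it is the more direct proxy of `z`.

`infer_affinity()` inverts the threshold relation at the onset enzyme
level, `lam/gamma = x_onset * z_tot / (beta/alpha)`. When no onset occurs
within the observation window the plateau level gives a **lower bound**
instead (returned as a typed result, not an error, so the silent-plateau
experiment remains a first-class outcome).

`recover_parameters()` fits `log(lam/gamma)`, `log(scale)` and
`log(background)` (optionally `log(sigma)`) by Levenberg–Marquardt on
log-scale residuals of the activity readout against the quasi-steady-state
model, using the replicate-mean measured enzyme (converted to molar) as
predictor and including the control arm, which anchors the background. The
recovery study design samples the `nf73` kinetics at 0–15 h in 1.5 h steps
with 3 replicates, so that several points lie on the rising branch.
Because the predictor is itself noisy, the point estimate carries a mild
attenuation bias; the bootstrap therefore perturbs the enzyme predictor by
its replicate-estimated standard error in addition to resampling
residuals, and reports the **basic (reflected)** bootstrap interval, which
corrects first-order bias. A design whose readout never leaves the control
band raises a typed identifiability error carrying the lower bound.

## Numerical choices

* Integration: `deSolve::ode` (lsoda), `rtol = 1e-8`, `atol = 1e-12` M —
  `lam` can exceed other rates by 1e2–1e4, hence the stiff-capable
  solver. Negative excursions within `10 * atol` are clamped; larger ones
  raise. Default initial state `(0, 0)`, the suppressed pre-induction
  condition.
* Steady states: closed-form quadratic with the numerically stable
  formula; long-time integration (`simulate_to_steady()`, horizon
  doubling until scaled derivatives fall below `1e-10`) serves as the
  independent dynamic route in the tests, alongside a brute-force scalar
  root scan.
* The transcritical point is bisected in log-x to relative `1e-6`;
  marginal stability means `|Re(lambda_max)| < 1e-9 * beta`.
* 10–90% crossings are interpolated linearly in `log(x)`; grids that do
  not bracket both levels are refused with instructions to widen.
* Problem sizes in the test suite — 100-draw parameter sweeps
  (log-uniform over 1e-2…1e2), 20-seed pipeline replications, 60-draw
  bootstraps — keep each property check to seconds while leaving the
  acceptance behaviour statistically stable.

## Known limitations

* The affinity estimate inherits the full uncertainty of `beta/alpha`:
  the 100-fold GAP enhancement is a floor, so `lam/gamma` is best read as
  an upper estimate with the stated scaling caveat.
* The quadratic steady-state reduction assumes the complex equilibrates;
  near the threshold the true dynamics slow down critically, and the
  full-ODE mode lags the quasi-steady state exactly there (softened
  further by the ignition source). Onset intervals are therefore
  discretization-limited by the sampling grid, never sharper.
* One induction curve cannot identify all five rate constants;
  `recover_parameters()` deliberately fits only the affinity ratio (and
  optionally `sigma`) with `alpha`, `beta`, `z_tot` supplied.
* Endosome size is a monotone proxy observation, not a mechanistic fusion
  model.
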