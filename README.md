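# rab5onset

Kinetic modeling of delayed-onset Rab5 activation by Rabex-5 and
Rabaptin-5.

Rab5 is the master GTPase of early-endosome fusion; it is switched on
(GDP → GTP) by its exchange factor Rabex-5. Rabex-5 reaches the membrane
two ways: **directly**, through its early-endosomal-targeting domain, or
**indirectly**, as a cytosolic Rabex-5/Rabaptin-5 complex recruited by
Rab5-GTP itself — a positive feedback loop. `rab5onset` implements the
two-variable kinetic model of this system, its steady-state and stability
analysis, the per-cell protein-quantification arithmetic that connects
immunoblot densitometry to molar concentrations, a seeded generator of
synthetic Tet-Off induction experiments, and the inference pipeline that
turns an observed activation onset into an estimate of the affinity of
the Rabex-5/Rabaptin-5/Rab5-GTP tripartite complex. It is aimed at
quantitative cell biologists and modelers of small-GTPase switches.

## The model

With `z` the Rab5-GTP concentration (total `z_tot`), `x2` the tripartite
complex, `x0` cytosolic and `x1 = σ·x0` directly membrane-bound Rabex-5
(`x0 + x1 + x2 = x_tot`):

    dz/dt  = α (x1 + x2)(z_tot − z) − β z
    dx2/dt = γ x0 z − λ x2

The direct pathway alone yields a Michaelis–Menten-like hyperbola with
midpoint `β(1+σ)/(ασ)` and Hill coefficient 1. The indirect pathway alone
is silent until total Rabex-5 crosses the **delayed-onset threshold**

    x_thr = λβ / (γα z_tot),

then rises along a branch whose 10–90% Hill coefficient approaches 2 when
`λ/γ ≫ z_tot`. The onset is a transcritical exchange of stability (no
bistability). Inverting the threshold at the measured onset enzyme level
gives the in-cell affinity of the tripartite complex:
`λ/γ = x_thr · z_tot / (β/α)`.

## Worked example

Steady-state analysis with the reference constants
(`α = β = γ = 1, λ = 100, z_tot = 10`):

```r
library(rab5onset)
p  <- kinetic_params(alpha = 1, beta = 1, gamma = 1, lam = 100,
                     sigma = 0, z_tot = 10)
onset_threshold(p)
#> [1] 10
rc <- response_curve(p, 10^seq(-2, 4, length.out = 400), "indirect_only")
hill_coefficient(rc)
#> [1] 1.932876
```

The feedback loop ignites only above 10 concentration units of total
Rabex-5, and the response is ultrasensitive (Hill ≈ 1.9, vs exactly 1 for
the direct pathway).

End-to-end synthetic experiment — a Rabex-5-deficient fibroblast
(NF73-like) induction assay, indirect pathway only, sampled at
0/3/6/9/12 h:

```r
sc    <- rab5_scenario("nf73")
ds    <- generate_dataset(sc, seed = 1)
onset <- detect_onset(ds)
onset
#> Onset detected between 6 and 9 h; enzyme at onset 11.5 fg/cell (3.6e-06 M)
infer_affinity(onset, z_tot = sc$params$z_tot,
               beta_over_alpha = sc$beta_over_alpha)
#> Tripartite-complex affinity: lambda/gamma = 8.995e-06 M (~1e-05 M)
```

Activation appears between 6 and 9 h after induction; the enzyme level at
the 6-h lower edge (~12 fg/cell, i.e. 3.75e-6 M for a 40 kDa protein in
an 80 fL cell) converts — with `z_tot = 2.5e-5` M and `β/α = 1e-5` M —
into a tripartite-complex affinity of ≈1e-5 M, recovering the generator's
true value (9.375e-6 M) to within the sampling-grid discretization. A
silent experiment (no onset at the 32 fg/cell plateau with endogenous
Rab5) instead yields the lower bound `λ/γ ≥ 6e-6` M.

A command-line surface over the same functions is available via
`rab5_cli()` (subcommands `simulate`, `curve`, `threshold`, `bifurcate`,
`quantify`, `generate`, `infer`) and the wrapper script
`inst/scripts/rab5onset-cli.R`.

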