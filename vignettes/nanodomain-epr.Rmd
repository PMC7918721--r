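---
title: "Resolving membrane nanodomains from nitroxide EPR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving membrane nanodomains from nitroxide EPR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ghostepr)
```

## The problem

A lipophilic nitroxide spin probe partitioned into the plasma membrane of a
living cell reports, through its X-band EPR spectrum, the ordering and
rotational dynamics of its immediate lipid environment on the nanometre
scale.  A membrane that is laterally heterogeneous — a mosaic of nanodomains
with different fluidity — produces a spectrum that is a weighted
superposition of several spectral components, one per domain type.  This
package implements the full computational chain for resolving that
superposition: a forward lineshape model, a hybrid evolutionary fit repeated
over many independent runs, condensation of the resulting solution cloud
into discrete domain groups (the GHOST procedure), and replicate-level
statistics for comparing conditions (e.g. receptor-expressing cells vs.
controls, or cholesterol depletion vs. untreated).

## Forward model

Each domain component is described by six parameters:

| parameter | meaning | unit | default bounds |
|---|---|---|---|
| `S` | order parameter (1 = perfectly ordered, 0 = isotropic) | — | [0, 1] |
| `tau_c` | rotational correlation time | ns | [0.05, 5] |
| `pA` | hyperfine polarity correction factor | — | [0.85, 1.15] |
| `pg` | g-tensor polarity correction factor | — | [0.999, 1.001] |
| `W` | residual Lorentzian broadening | mT | [0, 0.5] |
| `d` | domain proportion (fraction of probes) | — | [0, 1], Σd = 1 |

The probe's rotation is assumed *fast but restricted* (wobble in a cone):
the rhombic hyperfine and g tensors are motionally averaged to effective
axial values

    A_par  = pA (a_iso + 2/3 S ΔA),   A_perp = pA (a_iso − 1/3 S ΔA),

with `a_iso = tr(A)/3` and `ΔA = A_zz − (A_xx + A_yy)/2`, and analogously
for g with `pg`.  This preserves the trace, `(A_par + 2 A_perp)/3 = pA
a_iso`, and interpolates between the rigid limit (S = 1) and complete
isotropic averaging (S = 0).  The order parameter maps to a cone half-angle
through `S = ½ cosθ₀ (1 + cosθ₀)`.

Line positions follow the standard high-field resonance condition `B = hν /
(g_eff μ_B) − m_I A_eff(θ)` for the three ¹⁴N hyperfine lines (m_I = −1, 0,
+1) at director tilt θ.  Line widths are

    ΔB(θ, m_I) = W + κ · τ_c · Var_cone[B_inst],

an intrinsic Lorentzian floor plus a motional term proportional to the
correlation time and to the variance of the instantaneous (rigid-limit)
resonance field over the accessible cone.  κ defaults to the electron
gyromagnetic ratio expressed in 1/(ns·mT); the variance is evaluated by
Gauss–Legendre × midpoint quadrature over the cone (8 polar × 16 azimuthal
nodes).  The term vanishes identically at S = 1 (closed cone) and is exactly
linear in τ_c — both limits are asserted in the test suite.  Because the
membrane normal of a cell suspension takes all orientations, the component
spectrum is a powder average over `cos θ ∈ [0, 1]`, computed with 64-node
Gauss–Legendre quadrature (validated against Monte-Carlo orientation
sampling with 10⁵ draws to within 1% of peak amplitude).

The spectrum of K domains is the pointwise superposition `Σ d_k ·
component_k` on a common field grid.

Normalization: the analytic first-derivative shape is detrended so its
trapezoid integral over the sweep is exactly zero, and scaled so the
reconstructed absorption (cumulative trapezoid integral) has unit double
integral.  Enforcing the contract numerically on the output grid — rather
than relying on unit-area Lorentzians — matters because Lorentzian tails
leave any finite sweep window.

Field modulation (0.2 mT) is recorded as metadata; the default rendering is
the analytic first derivative, since 0.2 mT is small relative to the
linewidths here.  An opt-in pseudo-modulation flag renders the first
harmonic of the modulated absorption instead.

Magnetic tensor defaults (A = 0.63/0.58/3.36 mT, g =
2.0088/2.0061/2.0027) are standard doxyl-nitroxide literature values for a
5-doxyl fatty-acid probe.  They are exposed as inputs everywhere and treated
as configuration, not as measured truth.

## Hybrid evolutionary fitting (HEO)

Fitting a K-component model to a 1024-point spectrum is a multimodal
problem: strongly overlapping components admit "merged" local optima in
which two domains are absorbed into one effective component.  A single local
optimizer finds such optima readily; the method therefore combines a global
genetic search with simplex refinement, repeated over many independent
seeded runs.

One run (`heo_run()`):

1. **GA phase** — real-coded genetic algorithm over the 5K nonlinear
   parameters: tournament selection (size 2), BLX-0.5 blend crossover
   (probability 0.9), per-gene Gaussian mutation (probability 0.25, sd 5% of
   the bound width), elitism, and 15% "random immigrants" per generation.
   The immigrants keep the population exploring after the bulk converges —
   without them virtually every run collapses into the merged optimum.
   Defaults: population 96, 40 generations.
2. **Simplex phase** — Nelder–Mead refinement in *bound-normalized*
   coordinates (the raw parameters span three orders of magnitude in scale;
   refining unscaled cripples the simplex).  Up to three good, mutually
   distant GA individuals are refined (up to 3 restarts × 1000 iterations
   each), and the best refined result is returned.  Refining several
   candidate basins per run roughly doubles the fraction of runs that find
   the true decomposition, at modest cost.

**Proportions are not searched.**  The model is linear in `d`, so at every
objective evaluation the component amplitudes are profiled out by
non-negative least squares (exhaustive support enumeration, exact for
K ≤ 5) and renormalized to Σd = 1.  This variable-projection step removes
K dimensions from the global search, handles the arbitrary amplitude scale
of measured spectra, and keeps the simplex constraint exact — a softmax
reparameterization of `d` was considered and rejected because it slows
convergence without adding anything.

The goodness of fit is `χ² = Σ (y_sim − y_meas)² / σ²`, with σ estimated
from the outer 5% of field points of the measured spectrum when not
supplied.  The statistic is invariant under a common amplitude rescaling of
both spectra and σ.

`multi_run()` repeats this with seeds `base_seed + 0 … n_runs − 1`.  The
reference protocol uses 200 runs per spectrum; the package's own acceptance
checks use 50 (and the test suite 40) — at these sizes roughly half of the
runs reach the global basin on the shipped presets, which is ample for the
condensation stage while keeping a full pipeline around six minutes on one
CPU.  All run, stage and noise seeds derive deterministically from a single
pipeline seed, and identical configurations reproduce byte-identical
artifacts.

## GHOST condensation

The solution cloud from all runs is condensed into discrete domain groups:

1. **Goodness-of-fit filter** — keep the best half of runs by χ² rank
   (`fit_keep_fraction = 0.5`).
2. **Density filter** — explode each kept run into K points, one per fitted
   domain, with coordinates (S, τ_c, W, pA) normalized to [0, 1] by the fit
   bounds; drop points with fewer than 5 neighbours within radius 0.05.
3. **Slicing** — cover the S axis with overlapping slices (width 0.05, step
   0.025); link points within a slice when closer than 0.05 in the
   normalized (τ_c, W, pA) subspace; merge links across slices
   (union-find).  The connected components are the domain groups, labelled
   by descending mean S: domain 1 is the most ordered.

Group summaries report per-parameter means, standard errors from the
diagonal of the member covariance matrix (the between-run spread of the
condensed solutions), and proportions as the mean fitted `d` renormalized
to 100% across groups — `d` carries the spin-population meaning, so it is
preferred over member counts.  The slicing thresholds are not published for
the reference implementation; the defaults above are package choices, all
configurable and recorded in the output metadata.  The slicing procedure is
deterministic, order-invariant, and equals the connected components of the
corresponding pairwise linkage graph (asserted against a brute-force oracle
in the tests).

GHOST diagrams (`make_diagram()`) are the 2-D cross-sections S–τ_c, S–W and
S–pA with the remaining parameters encoded as RGB intensities (red = τ_c,
green = W, blue = pA, normalized to bounds).

With strongly overlapping domains, equivalent fits can swap component roles
(two components exchange their τ_c assignments at indistinguishable χ²),
which fragments the condensation into more clusters than there are domain
types.  `intermediate_order()` handles this when the quantity of interest
is the intermediate domain's order parameter: groups are assigned to three
domain types by the optimal proportion-weighted 1-D partition of their mean
S, and the middle type's weighted mean is reported; with exactly three
groups this is simply the middle group.

## Condition comparison

Independent replicates (separate spectra, each fitted and condensed
independently) are compared per domain and parameter.  Domains are matched
across conditions by S rank.  The effect measure is the relative change
`(mean_cond − mean_ctrl)/mean_ctrl` with a first-order (delta-method)
standard error, tested with a two-sided equal-variance Student's t test at
p < 0.05 (Welch available via `var_equal = FALSE`).  No multiple-testing
correction is applied by default, matching common practice for this
four-parameter report; a Bonferroni flag exists.  The tests act on
per-replicate group means (not pooled clouds): replicates are the
independent unit.  Null simulations in the test suite confirm the nominal
type-I error (0.05 ± 0.02 over 1000 comparisons).

## Synthetic data

`make_preset()` ships five three-domain parameter sets emulating the
studied cell systems (αT3-1, αT4, HEK-HAGnRH-R, HEK-293, and HEK-HAGnRH-R
after methyl-β-cyclodextrin cholesterol depletion).  Only the
intermediate-domain order parameters of the receptor-expressing presets
(S = 0.37 and 0.41) are published values; every other number is a
package-chosen plausible default from typical membrane nitroxide-EPR ranges
(documented as such), with domain 1 the most ordered and most abundant and
the depletion preset lowering all three order parameters.  `generate_spectrum()`
adds seeded white Gaussian noise at a peak-to-noise ratio (default snr 50,
chosen to match visually clean cell spectra); an optional linear baseline
drift supports robustness checks.  What the generator does *not* emulate:
probe reduction kinetics, instrument drift, cell-to-cell variability, or
any mismatch between the fitted model family and reality — passing tests
demonstrate correct inversion of the model on data from the same model
family, not accuracy on arbitrary real spectra.

## Numerical choices and degenerate inputs

* Powder quadrature: 64 Gauss–Legendre nodes on cos θ (configurable); cone
  variance on 8 × 16 nodes.  Widths are floored at 10⁻³ mT so lines stay
  integrable on the grid.
* The lineshape accumulation loop runs in single precision (double
  accumulation elsewhere); the shape is subsequently detrended and rescaled
  by its own integrals, and fit-relevant χ² contrasts are on the percent
  scale, far above the ~10⁻⁶ relative float error.
* Genomes whose lines leave the sweep window (absorption integral ≤ 0) get
  a large finite penalty rather than an error, keeping the simplex stable.
* Degenerate K (fitting more components than the data contain) resolves as
  coinciding components or a vanishing proportion; both are legal outcomes.
* Singleton GHOST groups report means with `NA` standard errors; an empty
  retained set after filtering is an explicit error.
* Ties in the NNLS support enumeration resolve toward the smaller residual;
  exact zeros in `d` are allowed.

## Problem sizes

The shipped acceptance script runs the two preset pipelines at 50 HEO runs
each (K = 3, snr 50, 1024-point spectra, 64-node powder grid), about six
minutes per pipeline on one CPU.  The test suite uses 40 runs for the
end-to-end checks and smaller budgets for unit-level fitting tests; these
sizes are the package's chosen desk-scale defaults, and `n_runs = 200`
reproduces the reference protocol scale.

## Known limitations

* Fast-motion regime only: no stochastic-Liouville slow-motion simulation,
  no saturation or power effects, ¹⁴N probes only.
* The exact linewidth expression and the GA/condensation hyperparameters of
  the reference software are not published; this package's versions are
  documented reconstructions with the same parameter roles, so fitted τ_c
  and W are comparable within the package but not necessarily across
  implementations.
* With strongly overlapping components (the realistic regime here), a
  minority of runs still lands in merged local optima; the χ² filter is
  what keeps them out of the condensation, so very small `n_runs` (< ~20)
  makes group detection fragile.
* Proportion standard errors combine fit spread only; they do not model
  residual correlation between overlapping components.
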