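# ghostepr

Resolving plasma-membrane lateral nanodomains from nitroxide spin-probe EPR
spectra: forward lineshape simulation, multi-run hybrid evolutionary
fitting (HEO), GHOST condensation of the solution cloud into domain groups,
and replicate-level condition comparisons.

## The problem

A lipophilic nitroxide probe (e.g. a 5-doxyl fatty-acid ester) partitioned
into the plasma membrane of living cells reports local lipid ordering,
rotational dynamics and polarity through its three-line ¹⁴N EPR spectrum.
When the membrane is a mosaic of nanodomains with different fluidity, the
measured first-derivative spectrum is a weighted superposition of several
spectral components.  Each component is parameterized by an order parameter
S (1 = perfectly ordered, 0 = isotropic), a rotational correlation time τc
[ns], polarity correction factors pA and pg that scale the hyperfine and g
tensors, a residual Lorentzian broadening W [mT], and its proportion d
(Σd = 1).

The probe's motion is fast but restricted (wobble in a cone), so the
rhombic tensors average to effective axial values

    A∥ = pA (a_iso + ⅔ S ΔA),   A⊥ = pA (a_iso − ⅓ S ΔA),

lines sit at `B = hν/(g_eff μB) − m_I A_eff(θ)` for m_I ∈ {−1, 0, +1}, and
widths are `W + κ τc Var_cone[B_inst]` — intrinsic broadening plus a
motional term that vanishes at S = 1 and is linear in τc.  Component
spectra are powder averages over all membrane-normal orientations (64-node
Gauss–Legendre).

Because the decomposition is multimodal, the fit is a hybrid evolutionary
optimization (real-coded GA + Nelder–Mead refinement) repeated over many
independent seeded runs; the GHOST procedure then filters the solution
cloud by goodness of fit and local density and groups it along the
order-parameter axis, yielding the number of distinguishable domain types,
their mean parameters with errors, and their proportions.

## Worked example

```r
library(ghostepr)

## synthesize a three-domain spectrum emulating an alphaT3-1 cell membrane
## (domain-2 order parameter planted at 0.37), fit it with 50 independent
## HEO runs (K = 3) and condense the solution cloud
cfg <- pipeline_config(preset = "aT3", snr = 50, K = 3, n_runs = 50,
                       seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
print(res$groups)
#> GHOST condensation: 3 domain group(s)
#> domain 1: S = 0.496 (se 0.00955), tau_c = 2.61 ns (se 0.0554), d = 39.3%, 7 points
#> domain 2: S = 0.393 (se 0.00546), tau_c = 1.7 ns (se 0.0904), d = 40.3%, 10 points
#> domain 3: S = 0.093 (se 0.00107), tau_c = 0.6 ns (se 0.0254), d = 20.4%, 12 points
intermediate_order(res$groups)
#> [1] 0.3929645
```

Three domain types are resolved, labelled by descending order parameter.
The intermediate group's mean S (0.393) recovers the planted value (0.37)
within the method's spread at this scale, and the proportions (≈39/40/20%)
track the planted 45/35/20%.  When condensation fragments overlapping
domains into more than three clusters, `intermediate_order()` assigns the
clusters to three domain types before reporting.
`make_diagram(attr(res$groups, "points"), "S-tauc")` returns the
corresponding GHOST diagram point table (RGB encodes τc, W, pA), and
`plot()` renders it.

Conditions are compared on independent replicates, each fitted and
condensed separately:

```r
reps_a <- lapply(1:4, function(i) {
  sp <- generate_spectrum(make_preset("aT3"), snr = 50, seed = 100 + i)
  ghost_condense(multi_run(sp, K = 3, n_runs = 50, base_seed = 1000 * i))
})
# ... same for the control preset, then:
# compare_conditions(reps_a, reps_ctrl)   # relative changes + t tests
```

A thin command-line front end covering `synth`, `simulate`, `fit`,
`ghost`, `compare` and `run` lives at `inst/cli/ghostepr.R`
(`Rscript ghostepr.R --help`), and `run_pipeline(pipeline_config(...))`
orchestrates the whole chain with deterministic seed fan-out and
JSON/CSV artifacts.

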