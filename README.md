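# crowdcycle

Quantifying how tissue crowding regulates the cell cycle during collective
epithelial migration.

In FUCCI-labelled expanding monolayers (e.g. MDCK tissues released from a
stencil), cells at the free edge cycle and divide while cells in the dense
centre stall in G0/G1 — yet a low but nonzero pool of S/G2/M cells persists
in the bulk. `crowdcycle` implements a minimal two-population
reaction-diffusion model of this behaviour, its Bayesian calibration to
replicated density profiles, the traveling-wave analytics that link the
calibrated rates to tissue invasion speed, and a synthetic-data generator
emulating the underlying experiments so the whole pipeline is testable
without external data.

## The model

Two density fields on the tissue, ρ₁ (G0/G1 + postmitotic) and ρ₂ (S/G2/M),
in cells/mm², with total ρ = ρ₁ + ρ₂:

    ∂ₜρ₁ = D Δρ₁ − k₁ ρ₁ f(ρ) + 2 k₂ ρ₂ g(ρ)
    ∂ₜρ₂ = D Δρ₂ + k₁ ρ₁ f(ρ) − k₂ ρ₂ g(ρ)

Cell motility is linear diffusion (D, µm²/h); k₁ (G1→S) and k₂ (division,
whence the factor 2) are intrinsic rates modulated by nonincreasing
crowding functions of the *total* density, by default linear ramps
f(ρ) = (1 − ρ/K₁)₊ and g(ρ) = (1 − ρ/K₂)₊. Setting f = g ≡ 1 gives the
density-independent (exponential growth) submodel; Heaviside steps give a
reduced model with closed-form traveling-wave structure. Key derived
quantities: the growth-matrix eigenvalue λ(ρ) (local net growth rate),
per-phase durations 1/(k₁f), 1/(k₂g), the pulled-front minimum speed
c_min = 2√(D λ(0)), and the reduced-model bulk/edge S/G2/M composition.

The package provides:

* `simulate_model()` — conservative finite-volume method-of-lines solver
  (radially symmetric or 1-D Cartesian, zero-flux boundaries, compiled
  right-hand side);
* `fit_cellcycle()` — ensemble-MCMC calibration of (D, k₁, k₂, K₁, K₂, σ)
  to replicated density profiles, returning a fitted-model object with
  `print`, `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`
  methods, plus `identifiability_report()` for practical-identifiability
  verdicts;
* `min_wave_speed()`, `fkpp_wave_speed()`, `reduced_bulk_edge()`,
  `wave_report()`, `measure_wave_speed()` — front-speed analytics;
* `expansion_scenario()`, `colonization_scenario()`, `scratch_scenario()`
  — synthetic FUCCI experiments with known ground truth;
* `run_simulate()` / `run_synth()` / `run_fit()` / `run_wave()` and a thin
  CLI (`inst/cli/crowdcycle.R`) driven by YAML configurations.

## Worked example

Traveling-wave analytics at the calibrated posterior modes for MDCK tissue
expansions, `(D, k1, k2, K1, K2) = (1300, 0.612, 0.457, 4965, 5435)`:

```r
library(crowdcycle)
wave_report(mdck_modes())
#> Traveling-wave analytics
#>   minimum front speed c_min      = 33.62 um/h
#>   Fisher-KPP approximation       = 26.08 um/h
#>   r = k1 k2/(k1+k2)              = 0.2616 1/h
#>   regime diagnostic 4r/(k1+k2)   = 0.98
#>   reduced model (supercritical): rho2 bulk = 1892, edge - bulk = 470 cells/mm^2
```

The tissue invades at ~33.6 µm/h regardless of the crowding thresholds
(the front is pulled by the low-density edge, where f = g = 1); the
single-population Fisher-KPP approximation underestimates the speed
because the two cell-cycle stages have comparable timescales
(diagnostic 0.98, far from the ≪1 regime). Because K₁ < K₂, the reduced
model is on the supercritical branch: a positive S/G2/M pool persists in
the crowded bulk, and its excess at the tissue edge equals K₂ − K₁ = 470
cells/mm². Density-dependent phase durations at the same estimates:

```r
phase_durations(mdck_modes(), c(0, 3500, 4000))
#>    rho T_G1_postM   T_SG2M   T_total
#> 1    0   1.633987 2.188184  3.822171
#> 2 3500   5.537710 6.146139 11.683849
#> 3 4000   8.406990 8.287651 16.694641
```

A full synthetic-calibration loop (generate a noisy 11-replicate tissue
expansion at known parameters, refit, inspect recovery):

```r
obs <- expansion_scenario(grid = cc_grid("radial", 5000, 150), seed = 7)
fit <- fit_cellcycle(obs, settings = mcmc_settings(steps = 600, seed = 11))
round(coef(fit), 3)
#>        D       k1       k2       K1       K2    sigma
#> 1321.175    0.614    0.454 4963.851 5434.891   34.041
```

(about a minute on one core; all five generating parameters are recovered
within 2%, including the ordering K₁ < K₂).

## Documentation

The methods vignette (`vignettes/cell-cycle-crowding.Rmd`) documents the
model assumptions, numerics, calibration design, the synthetic-data
generator and its limitations, and known caveats.
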