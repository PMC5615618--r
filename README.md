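# spanel — spatial panel econometrics for areal health data

`spanel` implements the spatial econometric workflow used in province-scale
environmental-health studies: does air pollution (PM2.5) relate to
respiratory-disease mortality once the *spatial* structure of both is taken
seriously? Province panels violate the independence assumptions of ordinary
panel regression — pollution drifts across borders, and mortality clusters
regionally — so the analysis proceeds in two stages:

1. **Exploratory spatial analysis.** Global Moran's I,

   `I = [Σᵢ Σⱼ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄)] / [S² Σᵢ Σⱼ wᵢⱼ]`,

   tested against its permutation null (E[I] = −1/(n−1)), plus the Moran
   scatterplot classification of each region into HH / LH / LL / HL
   quadrants.

2. **Spatial panel regression.** Fixed-effects Spatial Durbin (SDM),
   Spatial Lag (SLM) and Spatial Error (SEM) models,

   `y_t = ρ W y_t + δ W(Σₖ xₖ,t) + X_t β + μ + γ_t 1 + ε_t`,
   `ε_t = λ M ε_t + ψ_t`,

   estimated by concentrated maximum likelihood: β and σ² are profiled
   out, the log-Jacobian `T·ln|I − ρW|` is evaluated through the
   eigenvalues of the row-standardized weight matrix, and the scalar
   spatial parameter is maximized on its admissible interval
   (1/ω_min, 1). Standard errors come from the numerical Hessian of the
   full likelihood.

The contiguity structure of the 31 Chinese provinces (Rook rule, with the
island Hainan assigned its nearest neighbour Guangdong) ships as a packaged
adjacency table, and a calibrated synthetic-panel generator reproduces the
marginal moments and spatial dependence of the 31-province × 2004–2008
mortality/PM2.5 panel, so the entire pipeline runs and is tested without
restricted registry data.

## Worked example

```r
library(spanel)
adj   <- china_adjacency()          # packaged 31-province contiguity table
W     <- contiguity_weights(adj)    # row-standardized Rook weights
panel <- china_like_fixture(seed = 42)   # synthetic 155-row province panel

moran_by_year(panel, "pm25", W)
#>   year moran_i    z  p_value
#> 1 2004   0.612 5.42 5.83e-08
#> 2 2005   0.640 5.66 1.55e-08
#> 3 2006   0.585 5.21 1.84e-07
#> 4 2007   0.627 5.65 1.63e-08
#> 5 2008   0.578 5.22 1.78e-07

fit_slm(panel, W)
#> SLM panel fit (twoway effects): N = 31 regions, T = 5 periods
#>   rho    = 0.2737 (z = 3.32)
#>   pm25          0.0331  (se 0.00323, p 1.11e-24)
#>   lngdp         0.3938  (se 0.136, p 0.00387)
#>   lnhos        -0.3689  (se 0.103, p 0.000364)
#>   lncost       -1.0967  (se 0.231, p 1.98e-06)
#>   popudens      0.0025  (se 0.000446, p 3.28e-08)
#>   sigma2_e      0.0617  (se 0.00704, p 1.95e-18)
#>   logLik = -5.43425, pseudo R2 = 0.739
```

Reading the output: the simulated PM2.5 surface is strongly spatially
clustered every year (Moran's I ≈ 0.6, p ≪ 0.01); in the SLM fit the
spatial autoregressive parameter ρ is positive and significant (mortality
in a province co-moves with its neighbours'), and the PM2.5 coefficient
(~0.033 deaths per 10,000 per µg/m³ here) is positive — the qualitative
pattern the workflow is designed to surface. `fit_sdm()`, `fit_sem()` and
`fit_ols()` complete the model set and `model_report()` lays the fits out
side by side; `run_full_analysis()` runs descriptives, per-year Moran
tables, quadrant classification and all models in one seeded, hashed,
reproducible pass.

Note that the spatial parameters from two-way fixed-effects ML at T = 5
carry the well-known downward incidental-parameter bias (no Lee–Yu-type
correction is applied); see the methods vignette
(`vignettes/spatial-panel-methods.Rmd`) for the estimator's exact
definition, the generator's calibration, and this limitation quantified.

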