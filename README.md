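# envage

Multiplexed environmental exposures and multidimensional aging metrics.

Urban residents face a correlated mixture of environmental stressors —
particulate matter (PM10, PM2.5, PM2.5–10), nitrogen oxides (NO2, NOx),
road-traffic noise, and, protectively, residential green and blue space.
Because these exposures are strongly collinear, and because aging is
multidimensional (a whole-body clock, physical frailty, brain structure
and cognition), apportioning the mixture's contributions requires
dedicated tools. `envage` provides them for epidemiologists and
biostatisticians working with cohort data of this shape:

* **PhenoAge** — phenotypic age in years from the published Gompertz
  mortality-model equations over nine clinical biomarkers plus
  chronological age:
  `PhenoAge = 141.50225 + ln(−0.00553 · ln(1 − risk)) / 0.090165`, with
  `risk = 1 − exp(−e^xb (e^{120γ} − 1)/γ)`, `γ = 0.0076927`, and the
  published linear predictor `xb`.
* **Frailty phenotype score** — count (0–5) of the five Fried criteria,
  complete-case, with an optional documented binarization adapter.
* **WQS regression** — `wqs()` fits `y = β₁ Σᵢ wᵢ qᵢ + zᵀγ + ε` with
  nonnegative weights summing to 1 and a fixed effect direction:
  quartile-scored exposures (protective ones reversed), 40/60
  training/validation split, bootstrap weight estimation (softmax
  reparameterization, covariates profiled out exactly), simplex
  averaging, and held-out inference on the index.
* **SOM subpopulations** — `som_subpop()` trains a batch self-organizing
  map on standardized exposures, Ward-clusters the codebook weighted by
  unit occupancy, picks the number of subpopulations from the WSS/BSS
  elbow, names clusters by their elevated exposure family (air
  pollution / green space / blue space / noise / rural-urban fringe),
  and contrasts aging metrics against a reference subpopulation.
* **Association engine** — covariate-adjusted OLS scans per IQR increase
  in each exposure, Benjamini–Hochberg FDR families, stratified and
  residential-stability sensitivity variants, descriptive group tests,
  and a 3-class latent-class model for individual socioeconomic status.
* **Synthetic cohorts** — a seeded Gaussian-copula generator emulating
  the documented exposure correlation structure (green buffers
  ρs = 0.813, blue buffers 0.629, green–blue 0.18, co-emitted pollutants
  > 0.6), imaging-subcohort demographics (age 55.46 ± 7.37 y), five
  exposure archetypes, and planted mixture effects with namespaced
  ground-truth columns for recovery testing.

## Worked example

```r
library(envage)

cohort <- simulate_cohort(cohort_config(n = 5000, seed = 1))

fit <- wqs(phenoage ~ age + sex, cohort,
           exposures = exposure_names(), n_boot = 100, seed = 1)
fit
#> Weighted quantile sum regression (positive direction)
#>   exposures: 11, q = 4, bootstraps: 100/100 converged
#>   split: 2000 train / 3000 validation
#>   index effect (validation): 1.625 (95% CI 1.404, 1.847; p = <2e-16)
#>   top weights: pm10 = 0.387, pm25 = 0.236, nox = 0.096
```

The cohort plants a mixture effect on PhenoAge through PM10, PM2.5, NOx
and 24-h noise; the fitted weights put the mass on exactly those
components, and the validation-set index effect (years of phenotypic age
per quartile-step of the weighted mixture) is strongly positive.

```r
som_fit <- som_subpop(cohort, exposures = exposure_names(), seed = 1)
som_fit
#> SOM exposure-pattern subpopulations
#>   grid 10x10, 20 epochs, selected k = 5 (elbow: max second difference of WSS/TSS)
#> subpopulation
#>         blue space rural-urban fringe      air pollution        green space
#>                597               1498               1039               1207
#>              noise
#>                659
#>   reference: green space

compare_subpopulations(som_fit$assignment, cohort$phenoage, cohort,
                       covariates = c("age", "sex"))
#>        subpopulation beta    se ci_low ci_high        p    n
#> 1         blue space 1.06 0.290  0.497    1.63 2.43e-04 5000
#> 2 rural-urban fringe 1.92 0.224  1.479    2.36 1.57e-17 5000
#> 3      air pollution 3.96 0.245  3.477    4.44 3.84e-57 5000
#> 4              noise 3.04 0.281  2.493    3.59 4.51e-27 5000
```

The map recovers the five planted exposure archetypes, and — relative to
the green-space subpopulation — the air-pollution subpopulation shows the
worst covariate-adjusted phenotypic aging (≈ 4 years), with noise and
fringe groups in between.

`run_pipeline(pipeline_config(n = 5000, seed = 1), "out/")` executes the
whole chain (simulate → WQS → SOM → associations) and writes CSV/JSON
outputs plus a manifest with per-file checksums.

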