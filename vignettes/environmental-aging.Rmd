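---
title: "Methods: multiplexed environmental exposures and multidimensional aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed environmental exposures and multidimensional aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envage)
```

# The scientific problem

Urban environments expose people to a *mixture* of correlated stressors at
once: particulate matter (PM10, PM2.5, PM2.5–10), nitrogen oxides (NO2,
NOx), road-traffic noise, and — with the opposite sign — residential green
and blue space. Because these exposures are strongly collinear (co-emitted
pollutants routinely correlate above 0.6), one-exposure-at-a-time
regressions cannot apportion their contributions to health outcomes, and
aging itself is multidimensional: a whole-body clock (phenotypic age), a
physical-function score (the Fried frailty phenotype), and brain measures
(volumes, cognition, optionally a precomputed brain age) need not respond
to the same exposure in the same way.

`envage` implements the two estimators this problem calls for — weighted
quantile sum (WQS) mixture regression for *individual* contributions and
self-organizing-map (SOM) subpopulation discovery for *joint* exposure
patterns — together with the aging metrics, the exposure preprocessing,
a covariate-adjusted association engine with Benjamini–Hochberg false
discovery control, and a seeded synthetic cohort generator that emulates
the data structure of a large UK population cohort whose individual-level
records are access-restricted.

# Phenotypic age

PhenoAge converts a Gompertz proportional-hazards prediction of 10-year
mortality into years. Three fixed published equations are composed: a
linear predictor over nine clinical biomarkers plus chronological age
(C-reactive protein entering as its natural log),

\[ xb = -19.907 - 0.0336\,\mathrm{albumin} + 0.0095\,\mathrm{creatinine}
 + 0.1953\,\mathrm{glucose} + 0.0954\,\ln \mathrm{CRP}
 - 0.012\,\mathrm{lymph\%} + 0.0268\,\mathrm{MCV} + 0.3306\,\mathrm{RDW}
 + 0.00188\,\mathrm{ALP} + 0.0554\,\mathrm{WBC}
 + 0.0804\,\mathrm{age}, \]

the 120-month risk
\(1 - \exp(-e^{xb}(\exp(120\gamma) - 1)/\gamma)\) with
\(\gamma = 0.0076927\), and the year scale
\(141.50225 + \ln(-0.00553 \ln(1 - \mathrm{risk}))/0.090165\).
The constants are frozen in `phenoage_constants()` and never
re-estimated. Units matter (g/L, µmol/L, mmol/L, mg/L, %, fL, %, U/L,
10⁹/L, years): the reader warns — without failing — when values fall
outside generous physiological ranges, which almost always indicates a
unit mix-up rather than genuine data.

One numerical subtlety: for risks extremely close to 1 the *risk* itself
is not representable in double precision while its complement is, so
`phenoage_from_risk()` also accepts the survival probability directly,
and `compute_phenoage()` composes the three maps on the log-survival
scale, which is algebraically identical and saturation-proof.

The frailty phenotype score counts five Fried criteria and is strictly
complete-case: a missing component makes the score missing. The optional
`fried_components()` adapter binarizes raw questionnaire fields with
documented conventional cutoffs (sex-specific grip strength, lowest
activity category, slow self-reported pace, frequent exhaustion, any
unintentional weight loss); these cutoffs are this package's
interpretation of the standard operationalization, not values fixed by
the source model.

Continuous outcomes are z-scored (n−1 divisor). Skewed scores are first
rank-inverse-normal transformed (Blom offsets); the normality screen is
|skewness| > 1 — a deliberately concrete, testable stand-in for the usual
informal "if not normally distributed".

# Exposure preprocessing

WQS operates on quantile scores \(q_i \in \{0, \dots, q-1\}\). The
default `q = 4` (quartiles) follows the dominant convention in the WQS
literature; results can be quantile-count sensitive, so `q` is exposed
everywhere. Boundaries are type-7 empirical quantiles fitted on training
data only and reused verbatim on validation or new data — the
training/validation contract is bit-reproducible and leak-free.
Intervals are right-closed (boundary values fall in the lower bin) and
out-of-range values clamp to the extreme scores.

Because green and blue space are protective, their scores are *reversed*
(`s -> q-1-s`) before entering a single-direction index, so a positive
weight reads "less green space contributes to worse aging". Reversal is
an involution and leaves other columns untouched.

The day–evening–night noise metric energy-averages the three period
levels over 12/4/8 hours (07–19/19–23/23–07, matching a 23:00–07:00
night window) with +5 dB evening and +10 dB night penalties. Single-
exposure sensitivity models scale each exposure by its IQR so slopes
read per-IQR-increase.

# Weighted quantile sum regression

`wqs(formula, data, exposures, ...)` fits, for a fixed direction,

\[ y = \beta_0 + \beta_1 \textstyle\sum_i w_i q_i + z^\top\gamma +
   \varepsilon, \qquad w_i \ge 0,\; \textstyle\sum_i w_i = 1,\;
   \mathrm{sign}(\beta_1) \text{ fixed}, \]

by splitting the sample 40% training / 60% validation, estimating the
weights on bootstrap resamples of the training rows (default 500),
averaging converged bootstrap weight vectors back onto the simplex, and
testing the averaged index on the validation rows with ordinary least
squares (normal-theory SE, two-sided p, 95% CI — the CI method is a
documented package choice).

The per-bootstrap problem is solved with exact constraints: weights
through a softmax reparameterization, the sign constraint through
\(\beta_1 = \pm e^\eta\), and the covariate coefficients profiled out in
closed form by Frisch–Waugh residualization, leaving a low-dimensional
smooth objective that one deterministic start (uniform weights, OLS-scale
effect) plus four random restarts of BFGS optimizes; each function
evaluation is a \(p \times p\) quadratic form, so hundreds of bootstraps
run in seconds. The test suite holds this optimizer to an exhaustive
0.05-resolution simplex grid search on 3-exposure problems. Bootstraps
that fail to converge are excluded from the average and counted;
bootstraps converging with a near-zero effect still contribute weights
(signal-weighted averaging variants are deliberately out of scope). With
`direction = "both"`, one fit per direction is returned.

Under a null outcome the enforced-sign effect shrinks toward the zero
boundary rather than reaching it; the honest inference is the
validation-set p value, whose type-I behavior the acceptance suite
measures at ~5% over 200 seeded replicates.

# SOM subpopulation discovery

`som_subpop()` standardizes exposures, trains a rectangular batch SOM
(default 10 × 10, 20 epochs) with a Gaussian neighborhood whose radius
decays linearly from half the grid side to 0.1, and then clusters the
*units* rather than the participants (the standard two-stage SOM–Ward
approach): Ward's method on the occupied codebook vectors, weighted by
unit occupancy, with participants inheriting the cluster of their
best-matching unit (Euclidean distance, ties to the lowest unit index).

The codebook is linearly initialized along the first two principal
components — the conventional batch-SOM initialization — which makes
training fully deterministic; random initialization proved prone to map
folding on small grids.

The number of subpopulations is chosen from the within/between sum of
squares: for every candidate k the package computes WSS(k) and BSS(k) of
the induced participant partition (verified to satisfy the Huygens
decomposition WSS + BSS = TSS to 1e−8) and selects the k maximizing the
second difference of WSS/TSS — the sharpest elbow. Endpoints of the
candidate range cannot host a second difference; with fewer than three
candidates the smallest k is kept and the trace says why.

Clusters are named after their elevated exposure family (air pollution,
green space, blue space, noise); a cluster whose family means all stay
within ±0.25 standardized units is the moderate-everything "rural-urban
fringe". The naming profiles use skew-screened rank-normal z scores: the
blue-space percentage marginals are so right-skewed that plain z means
would drag every non-blue cluster negative and mask the fringe profile.
Aging metrics are contrasted against the green-space subpopulation
(configurable) by dummy-coded covariate-adjusted OLS.

# Association engine

`fit_linear()` runs complete-case OLS with dummy-coded categorical
covariates (alphabetical reference levels), refusing rank-deficient
designs by naming the collinear columns. `bh_adjust()` applies
Benjamini–Hochberg step-up adjustment — which controls the false
discovery rate, although the procedure is sometimes loosely described as
family-wise control — with the family composition configurable;
`single_exposure_scan()` forms one family from all exposure × outcome
models in a run and reports its own family size rather than hard-coding
any published test count. Stratified scans drop the stratifying
covariate; a residence filter (≥ 5 years at the current address) supports
the exposure-stability sensitivity analysis. Individual SES is a 3-class
latent-class model over income, education and employment: multinomial
item-response EM with five seeded starts, a guard that errors if the
log-likelihood ever decreases, and classes ordered into high/medium/low
by their affinity for the top income level.

# The synthetic cohort generator

The generator is the package's stand-in for restricted individual-level
data, and its defaults *are* the study conditions every downstream test
assumes:

* **Correlation structure.** A Gaussian copula with latent correlation
  \(2\sin(\pi\rho_s/6)\) reproduces target Spearman correlations exactly
  in the large-sample limit (monotone marginal transforms preserve
  ranks). Stated targets: green buffers 0.813, blue buffers 0.629,
  green–blue 0.18, co-emitted pollutants 0.70 pairwise (PM2.5–10
  excepted); the two noise metrics get 0.85 because one is an energy
  component of the other; all remaining entries default to a weak
  positive 0.2 — flagged as interpolation, not an asserted fact. Nearly
  singular targets are repaired to the nearest PSD matrix with a
  warning; clear indefiniteness is an error naming the matrix.
* **Marginals.** Pollutants log-normal, green/blue logit-normal on
  [0, 100]%, noise truncated normal on [30, 90] dB — plausible ranges,
  not fits to data.
* **Demographics.** Age is untruncated Normal(55.46, 7.37): truncating
  to the nominal 40–70 recruitment window would shrink the sample SD to
  ~6.9 and miss the documented dispersion, so the biomarker generator
  instead tolerates modest extrapolation outside that window.
* **Archetypes.** Five standardized exposure mean profiles (air
  pollution, green space, rural-urban fringe, noise, blue space) mixed
  with proportions (0.20, 0.25, 0.30, 0.125, 0.125) and spherical
  within-archetype scatter SD 0.5 — separations of 1.5–2 z units chosen
  once as a realistic "distinct but overlapping" regime.
* **Planted effects.** Outcomes follow
  \(y = \beta\sum_i w_i q_i + z^\top\gamma + \varepsilon\) with
  configurable simplex weights, so recovery is checkable against ground
  truth; frailty components are Bernoulli with age- and index-linked
  logits; biomarkers have age-linked means so computed PhenoAge
  correlates with age around 0.85–0.9.
* **Hygiene.** All ground truth lives in `truth_*` columns that
  `read_cohort()` strips by default; every stage draws from child seeds
  of one master seed, so a configuration reproduces a cohort byte for
  byte.

What the generator does **not** emulate: spatial autocorrelation and
geography, measurement error in exposure models, selection and attrition,
non-MCAR missingness, and real biomarker covariance beyond age trends.
Passing recovery tests therefore demonstrates that the estimators work
when their assumptions hold at realistic correlation strengths — not that
the published effect sizes would reproduce on restricted real data.

# Problem sizes and numerical choices

Analyses in the tests and reproduction script use desk-scale sizes chosen
as the package's own defaults: copula calibration at n = 20000, cohort
demographics at n = 10000, archetype recovery at n = 5000 over five
seeds, WQS weight recovery at n = 5000 with 100 bootstraps, type-I
measurement over 200 replicates at n = 400 with 10 bootstraps. Key
numerical conventions: type-7 quantiles everywhere; right-closed
quantile bins; optimizer tolerance `reltol = 1e-10` with 5 starts;
EM tolerance 1e−8 with a monotonicity guard; WSS/BSS identity asserted
at 1e−8; simplex renormalization drift bounded at 1e−12.

# Known limitations

WQS inference conditions on the estimated weights; repeated-holdout or
permutation-test variants are out of scope. The elbow rule cannot select
the endpoints of `k_range`. The latent-class model assumes conditional
independence of indicators given class. Brain age is accepted as a
precomputed column only — the gradient-boosted model that produces it is
out of scope. The quantile count q is a modeling choice; sensitivity to
it should be reported alongside any substantive claim.

# A minimal worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n = 5000, seed = 1)
cohort <- simulate_cohort(cfg)

fit <- wqs(phenoage ~ age + sex, cohort,
           exposures = exposure_names(), n_boot = 100, seed = 1)
summary(fit)

som_fit <- som_subpop(cohort, exposures = exposure_names(), seed = 1)
print(som_fit)
compare_subpopulations(som_fit$assignment, cohort$phenoage, cohort,
                       covariates = c("age", "sex"))

scan <- single_exposure_scan(cohort, exposure_names(),
                             c("phenoage", "brain_volume_z"))
head(scan[order(scan$adjusted_p), ])
```
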