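---
title: "Methods: epimutation burdens, clock residuals and cohort pooling in epidrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epimutation burdens, clock residuals and cohort pooling in epidrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

`epidrift` analyses two families of DNA-methylation aging biomarkers across
multiple cohorts and pools the results. This vignette records the models,
the numerical choices, and the reasoning behind the design decisions that
were genuinely open, so that a maintainer can tell what is principled, what
is convention, and what is an interpretation.

## Stochastic epigenetic mutations

For each CpG the cross-sample distribution of beta values defines quartiles
Q1 and Q3 and fences `Q1 − 3·IQR` and `Q3 + 3·IQR`; a *stochastic
epigenetic mutation* (SEM) is a value strictly beyond a fence. The strict
inequality matters only on ties but is the natural reading of "lower
than"/"greater than", and `compute_fences()`/`call_sems()` implement it
that way. The per-sample burden is the count of SEM cells over the fenced
probes, modelled as `log(burden + 1)`.

Numerical choices:

* **Quantile convention.** Sample quartiles use Hyndman–Fan type 7
  (linear interpolation), the default in the major statistical ecosystems;
  type 2 is available via `quantile_type` because epimutation studies do
  not standardize this. On large cohorts the choice is immaterial; on
  small panels it shifts fences by at most one interpolation step.
* **Log transform.** `log(burden + 1)` rather than `log(burden)`, because
  small synthetic panels (and real individuals on sparse probe subsets)
  can have zero burdens. `log_transform = "log"` maps zeros to `NA`
  instead, for users who prefer the strict log scale.
* **Degenerate probes.** A constant probe has IQR 0 and collapsed fences;
  equal values are then *not* SEMs (strictness again). Probes with fewer
  than `min_samples = 8` non-missing values are excluded and reported, not
  an error: real arrays lose cells to detection-p filtering.
* **Fence scope.** Fences are computed within cohort, mirroring the
  per-cohort analysis design; whether the original consortium computed
  them per cohort or pooled is not documented, and a pooled run is
  achieved simply by passing a combined matrix.

The white-blood-cell-adjusted variant regresses, per CpG, beta on the
estimated leukocyte fractions (intercept included, last fraction dropped
since fractions sum to one) and re-runs the fence/call procedure on the
residuals. The residual matrix is no longer bounded in [0, 1]; the caller
only assumes an ordering, so this is sound.

## Clocks and age acceleration

A clock is `intercept + Σ w_j β_j` over its CpGs, optionally followed by
the inverse log-linear transform used by pan-tissue clocks trained on
transformed age: with adult age `A` (default 20 years), predictor `y < 0`
maps to `(1+A)·e^y − 1`, else `(1+A)·y + A`. Coefficient files are runtime
inputs and never vendored: published coefficient tables are licensed
artifacts, and the tests instead use the generator's true clock, for which
exactness is provable. Probes absent from the matrix (within the
`min_coverage = 0.95` allowance) are dropped from the sum; missing cells of
present probes are imputed with the probe mean or rejected, per
`missing_policy`.

Age acceleration is `aa = dnam_age − age`; the extrinsic residual `eaa`
regresses `aa` on age within cohort (so `mean(eaa) = 0` and
`cor(eaa, age) = 0` to machine precision — both asserted in the tests);
the intrinsic `ieaa` additionally residualizes on the WBC fractions.
Residualization within cohort (rather than pooled) matches the
meta-analytic design in which every downstream model is per-cohort; a
pooled residualization would leak cohort mean differences into the
outcome.

## Per-cohort exposure models

Each of the five risk factors is categorical with three levels and a fixed
reference (education High, smoking Never, obesity NormalWeight, alcohol
Abstainer, physical activity High). Model M1 adjusts for age, sex and any
cohort-specific covariates; M2 adds the other four factors' dummies (the
mutually adjusted specification). Estimates carry classical homoskedastic
standard errors and normal Wald 95% intervals (`±1.959964·se`); HC1
sandwich errors are available via `se_type` but are not the default since
the consortium convention reports plain intervals. Categories absent from
a cohort lose their dummy with a warning rather than failing the whole
grid. Exposure-by-age and exposure-by-sex product terms extend M1
(`fit_interaction()`, moderator centered), and sex-stratified fits
(`fit_sex_stratified()`) complement the pooled product-term test.

## Random-effects pooling

Cohort estimates are pooled under `β_i ~ N(μ, v_i + τ²)` with τ² estimated
by REML: the profile log-likelihood
`−½Σlog(v_i+τ²) − ½log(Σw_i) − ½Σw_i(β_i−β̂)²`, `w_i = 1/(v_i+τ²)`, is
maximized over `[0, τ²_max]` with `τ²_max = 10·max(v_i)·k`, by bounded
one-dimensional search (`optimize`, tolerance 1e-10), with the boundary
τ² = 0 checked explicitly because a boundary maximum is common when
heterogeneity is weak. Internally the problem is standardized by `max(v)`
before optimizing, which conditions the search and makes the estimator
*exactly* equivariant under rescaling of the outcome — this is what makes
rescale-then-pool and pool-then-rescale commute to floating-point
precision when all cohorts share the scaling constants. Heterogeneity is
reported as Cochran's Q (fixed-effect weights) and
`I² = max(0, (Q−(k−1))/Q)·100`. The DerSimonian–Laird moment estimator is
included as a closed-form comparator (`dl_pool()`), and the test suite
additionally cross-checks REML against both an independent refined
grid search over the profile likelihood and the `metafor` package.
Confidence intervals are plain normal Wald intervals; the Knapp–Hartung
small-sample adjustment is available via `knha = TRUE` but off by default,
matching the convention of reporting unadjusted 95% CIs.

## Cohen's-d rescaling of SEM effects

Effects on `log(burden+1)` are standardized per cohort by the outcome's
standard deviation (`d = β/σ_outcome`) and re-expressed in years through
the standard deviation of the same cohort's clock age acceleration
(`β_years = d·σ_AA`). The defining supplementary material of the two-step
procedure is not publicly archived, so this is the canonical reading of a
Cohen's-d bridge between scales, applied per cohort *before* pooling; both
the sigma source (per-cohort vs pooled) and the reference measure are
arguments, and neither choice is claimed to be the original consortium's.
Standard errors are scaled by the same factor, treating the sigmas as
known constants — a documented simplification that understates the
uncertainty slightly when cohorts are small.

## Region enrichment

SEM loci are probes with at least `min_recurrence` SEM calls (default 1 —
no recurrence threshold is documented for the original analysis, so the
floor is a parameter). The null distribution resamples `|loci|` probe
identities uniformly without replacement from the array universe: probes
are a fixed design, so identity resampling preserves probe density, the
key confounder that genomic coordinate shuffling would break. The p-value
uses the add-one rule `(b+1)/(n_perm+1)` and is therefore never zero and
valid by construction; its type-I error and its agreement with exhaustive
hypergeometric enumeration on a tiny universe are asserted in the tests.
Note that at consortium depth nearly every SEM-prone probe eventually
carries one call, so a recurrence floor of 1 saturates the locus set and
the test correctly reports no enrichment; sparse designs (fewer samples,
lower rate) or a higher floor make placement bias visible.

## The synthetic generator

`simulate_cohorts()` produces, from one seed, multi-cohort data with the
statistical structure the analysis assumes:

* **Clock CpGs** are linear in transformed age `a_i = age_i + δ_i`:
  `β_ij = μ_j + s_j·a_i (+ noise, clipped to [0,1])`, slopes
  `|s_j| ∈ [0.002, 0.004]` per year with random sign (a 40-year age span
  then moves beta by 0.08–0.16, the magnitude of strong clock CpGs). The
  emitted true clock has weights `w_j = 1/(m·s_j)` and intercept
  `−(1/m)Σμ_j/s_j`, so on clip-free, noise-free data it returns `a_i`
  exactly — the tests assert 1e-9 years. The intercepts μ_j are drawn
  inside the feasible band that keeps noise-free betas strictly inside
  (0, 1) for any age within a 5-standard-deviation δ margin, so clipping
  cannot silently break that identity.
* **Latent age acceleration** is
  `δ_i = Σ effects(exposures_i) + u_c + N(0, delta_sd²)` with exposure
  effects in years (defaults 0.3/0.6 for Medium/Low education, smaller
  for the other factors — the magnitude scale of reported lifestyle
  effects), a cohort random intercept (`between_cohort_sd`, default 0.5
  y), and individual noise `delta_sd = 4` y, a typical residual SD of
  blood age-acceleration measures. The spread of δ, not the exposure
  effects, dominates the outcome variance — as in real cohorts.
* **SEM-prone CpGs** have tight Beta backgrounds (concentration 300,
  means in [0.25, 0.75]) and per-sample planted epimutation counts
  `K_i ~ Poisson(λ0·exp(r·age_i + Σ log-effects))` (defaults λ0 = 2,
  r = 0.03/yr). Planted cells are pushed deterministically to the far
  extreme (0.01 or 0.99) rather than drawn from a heavy tail, so planted
  events are recoverable ground truth and caller recall is exactly
  testable. Probe choice is uniform, or weighted by `enrichment_fold`
  inside the designated region set (default: the "open_chromatin" tiling,
  fold 3, mirroring the qualitative finding that epimutations concentrate
  in particular chromatin contexts).
* **Cell composition** comes from a Dirichlet over six leukocyte
  fractions; WBC-sensitive CpGs load on the centered granulocyte
  fraction, inducing the confounding that the IEAA and WBC-adjusted SEM
  variants are designed to remove. Exposure–education confounding is
  opt-in through `confounding_matrix`, which is how the
  mutual-adjustment attenuation pattern (M2 shrinking a confounded M1
  estimate) is induced and tested.
* **Genome.** Probes tile a synthetic two-chromosome genome at 1 kb
  spacing, and the three region sets are deterministic tilings (every 4th
  probe = "open_chromatin", 20% tilings for "polycomb_repressed" and
  "shore"), so expected overlaps are computable by hand.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic 450K/EPIC probe spacing and chromatin
annotation, co-methylation and LD structure among neighbouring probes,
array batch and normalization artifacts, non-uniform age distributions,
missingness mechanisms tied to signal intensity, and clocks whose CpGs
respond nonlinearly near the boundaries. The generator validates the
*statistics*, not the biology.

## Problem sizes and reproducibility

The test and acceptance workloads are scaled so the full suite runs in
about a minute: the default study is 6 cohorts × 300 samples on a
640-probe panel; parameter-recovery loops use 50 replicates; REML
calibration uses 18 cohorts × 1000 replicates; enrichment calibration uses
200 simulations × 500 permutations. Two sizing choices deserve a note:

* The exponential-age-slope recovery regresses `log(burden+1)` on age, and
  `E[log(K+1)]` for a Poisson count underestimates `log λ` by roughly
  `1/(2λ)`; at small burdens this curvature bias exceeds the sampling
  error of the slope. The recovery check therefore runs on a panel sized
  so burdens are large (5000 SEM-prone probes, λ0 = 20, burdens ≈ 60–190),
  where the log-linear approximation is informative about the true rate
  slope. This is a property of the estimand, not of the implementation.
* The end-to-end recovery and attenuation checks shrink the probe panel
  (the clock outcome does not need SEM probes) to keep 50 full replicates
  cheap without changing the quantities under test.

All randomness flows from explicit seeds: the generator from
`config$seed`, the pipeline's enrichment stage from a derived substream,
and every permutation batch from per-set derived seeds, so identical
configurations reproduce every numeric output bit-identically (asserted in
the tests). The run manifest records the seed, a config hash, per-stage
timings and row counts.

## Known limitations

* Sigma constants in the Cohen's-d rescaling are treated as known;
  intervals on rescaled effects are accordingly slightly narrow.
* Plain Wald intervals at small k (< ~5 cohorts) undercover under strong
  heterogeneity; use `knha = TRUE` in that regime.
* The WBC adjustment and IEAA assume linear cell-composition effects on
  beta; strongly nonlinear composition effects would leave residual
  confounding.
* `burden` counts raw calls over available probes; individuals with many
  missing cells have a mildly deflated burden, and no denominator
  correction is applied (the original procedure documents none).
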