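---
title: "Mixed-model methylome-wide association: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model methylome-wide association: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methMWAS` analyses blood methylation beta-value matrices against a binary
disease phenotype. This vignette is the package's account of the models it
fits, the parameters that matter, what the synthetic-cohort generator does
and does not emulate, and the numerical and design choices made where the
design was genuinely open.

## The models

**Variance captured by all probes.** With `W` the n × m matrix of probe
values standardized probe-wise to mean 0 and variance 1, the package fits

y = Cβ + Wu + e,  var(y) = WW′σ²_u + Iσ²_e = Aσ²_o + Iσ²_e,

where `A = WW′/m` is the omics relationship matrix and σ²_o = m·σ²_u. The
probe-captured fraction is ρ² = σ²_o/(σ²_o + σ²_e). A binary phenotype is
analysed as 0/1 on the observed scale with this linear mixed model — no
liability transformation is applied to the estimate, which is the standard
convention for this quantity. Components are estimated by REML.

**Per-probe association.** The single-component scan fits each probe as a
fixed effect while it remains part of the genome-wide random effect
(y = w_i·b_i + Cβ + Wu + e). The multi-component variant splits probes into
two random effects by their p-value in a preliminary least-squares scan and,
for each target, removes every probe on the same chromosome strictly within
50 kb of the target from both random components before testing the target as
a fixed effect. The window guards against shared local signal (co-methylation
with the target) absorbing the effect under test; the two components let
strongly associated probes — including confounder-driven ones — carry their
own, larger effect-size variance.

**Downstream.** Cohort-level results are pooled by fixed-effect
inverse-variance weighting assuming independent cohorts; heterogeneity Q is
reported but not modelled. The summary-data MR module estimates
b_xy = b_zy/b_zx at the top cis-QTL and tests, via the HEIDI statistic,
whether Wald ratios at correlated cis SNPs are mutually consistent — the
signature of a single shared causal variant — against the linkage
alternative. Classification uses the BLUP solutions
û = (σ²_o/m)·W′V⁻¹(y − Cβ̂) to score an external cohort, evaluated by
Nagelkerke R² and AUC.

## Key parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `detectRateMin`, `detectP` | 0.95, 0.01 | fractions | classical array probe-detection rule |
| `minDetectedProbes` | 0.927 | fraction of probes | the classical absolute call-rate cutoff (450,000 of 485,512 probes) generalized to a fraction so matrices of any size can use it |
| `sdMin` | 0.02 | beta SD | removes uninformative flat probes |
| `thresholdP` (partition) | 0.01 | p-value | the initial-scan cutoff separating the two random-effect groups; the canonical value is not fixed by the method, so it is exposed and logged |
| `windowBp` | 50000 | bp, strict `<` | local-exclusion window of the multi-component scan |
| `pInstrument` | 5e-8 | p-value | genome-wide instrument threshold for MR |
| `snpPMax`, `ldPrune` | 1.6e-3, (0.05, 0.9) | p; r² bounds | HEIDI SNP-inclusion conventions of the originating method; configurable because data sets differ in LD richness |
| `minOverlap` (scoring) | 0.5 | fraction | refuse to score a cohort sharing fewer than half of the training probes |

## The synthetic-cohort generator

The generator is the package's stand-in for protected cohort data and
defines the study conditions of every calibration experiment. Per sample,
beta values arise as a cell-type-proportion-weighted mixture of per-type
probe signatures (proportions Dirichlet-distributed with typical whole-blood
means: ~55% neutrophils, ~15% CD4 T cells, …); slide/row/column batch
effects (SD 0.1) and measurement noise (SD 0.3) are added on the logit
scale, so values remain in [0,1] while effects stay additive. Probes sit on
22 autosomes with exponential spacing (mean 30 kb — chosen so a 50 kb window
holds a realistic handful of neighbours at desk scale, where full array
density would be impractical). Case status comes from a liability threshold:
liability = scaled causal-probe contributions + covariate effects + normal
residual, thresholded at the case-fraction quantile.

**Observed vs liability scale.** The mixed model reports variance fractions
on the observed 0/1 scale, while the generator's `liabilityVarianceExplained`
is a liability-scale quantity. For many small effects the two are linked by
ρ²_obs = h²_liab·z²/(p(1−p)) (z the normal density at the threshold,
p the case fraction); `liabilityVarianceForObserved()` inverts this so
experiments can be stated on the observed scale. Recovery of a target
ρ²_obs = 0.3 at n = 500, m = 2000 is verified in the acceptance suite.

**Composition shifts.** When the case Dirichlet differs from the control
one, case proportions (and their methylation) are re-drawn after status
assignment. This plants a clean composition confounder but attenuates the
causal-probe/liability link for those samples, so shifted configurations are
used for calibration and robustness experiments, not effect recovery.
`celltypeInformativeFraction` controls how concentrated the composition
signal is across probes (1 = every probe carries some cell-type difference;
small values emulate strongly cell-type-specific CpG subsets).

**What is not emulated.** Raw intensities and dye bias (QC layers such as
detection p-values are accepted as inputs, not generated by default);
sex-chromosome probes; related individuals; population structure; fine-scale
co-methylation blocks (probe correlation arises only through shared
cell-type, batch and liability structure). Passing tests therefore
demonstrate correctness of the estimators under the stated generative model,
not performance on any real cohort.

All randomness flows from one integer seed through named substreams, so
adding a component never perturbs the draws of another, and two calls with
the same configuration but different `cohortSeed` produce independent
cohorts sharing one causal architecture — the discovery/replication design
used by the classifier experiments.

## Numerical choices

- **Standardization** uses the population (1/n) variance so that
  diag(WW′/m) averages exactly 1 — the scale convention that makes the
  variance-component parameterization testable. Missing betas are
  mean-imputed before scaling and counted.
- **REML** uses average-information updates with step halving, an EM
  fallback when the AI step fails to improve the restricted likelihood, and
  an active-set rule that freezes components sitting on their lower bound
  (10⁻⁶ × phenotypic variance, flagged as clamped) with an outward
  gradient. Convergence is declared when the log-likelihood moves by less
  than 10⁻⁸; a grid-search evaluation of the same objective serves as an
  independent oracle in the tests. Starting values split the
  covariate-adjusted phenotypic variance evenly across components.
- The ρ² standard error is a delta-method transform of the inverse AI
  matrix; the p-value for ρ² is a 0.5·χ²₀ + 0.5·χ²₁ mixture
  likelihood-ratio test against σ²_o = 0 — the package's own convention for
  a boundary parameter, labelled as such.
- **Scans** are two-step: variance components estimated once under the
  windowless model, then held fixed for per-probe generalized least squares
  (Cholesky whitening for the single-component scan; exact Woodbury
  downdates of the covariance for each target's 50 kb exclusion in the
  multi-component scan). A per-probe refit is statistically equivalent to
  first order and computationally prohibitive; the limiting equivalence of
  both scans to ordinary least squares when the components vanish is
  asserted at 10⁻⁶.
- **Probe partition boundaries:** threshold 1 (or more) puts every probe in
  group 1, threshold 0 puts every probe in group 2; an empty first group
  collapses the model to a single component with a warning.
- **Sample-signal outliers** are flagged against a median/MAD centre and
  scale rather than mean/SD, so a gross outlier cannot mask itself.
- **HEIDI** evaluates the tail of the quadratic form in correlated normals
  by Imhof-type numerical inversion of the eigenvalue-weighted χ² sum, with
  a Monte-Carlo fallback; the two routes are required to agree within 10%
  in the tests. Wald-ratio covariances use the delta method with LD-implied
  within-study correlations; exposure and outcome studies are treated as
  independent.
- **Tie-breaks:** equal instrument p-values resolve to the smaller base-pair
  position (or SNP id when positions are absent); correlation pruning breaks
  p-value ties by probe id; the empirical sign null uses the +1 correction
  and counts `null ≥ observed`, so it can never return 0.
- **Degenerate inputs** are explicit errors: constant probes at
  standardization, single-level batch factors, outcomes without variation,
  zero-SD scores, non-positive doses, empty QC output.

## Open design points, resolved

- **Filter-then-residualize order.** Probe/sample filters run before batch
  residualization; the order is fixed and documented because the reverse
  order changes which probes survive the variability filter.
- **Quantile normalization** against control probes is deliberately replaced
  by explicit batch residualization on slide/row/column indicators — a
  documented fidelity gap: residualization removes additive batch effects
  exactly but not intensity-dependent ones.
- **Six cell types for dose correlations.** Dose–composition correlations
  default to the seven blood types minus eosinophils (the rarest, and the
  type conventionally dropped from covariate sets to avoid compositional
  collinearity); the tested set is a parameter.
- **Per-type logistic models.** Composition differences are tested one cell
  type at a time (intercept + sex + age + that type), matching how per-type
  p-values are conventionally reported; joint modelling is possible by
  passing several columns as covariates.
- **Score scaling order.** Profile scores are z-scaled within the target
  cohort before covariate-adjusted evaluation.
- **Deconvolution constraints.** Nonnegativity is enforced in the solve;
  sum-to-one is applied by post-normalization rather than as a hard
  constraint, matching common practice for reference-based deconvolution.
- **Meta-analysis tolerance.** The worked pooled effects are checked against
  two-decimal published-style inputs; because those inputs are themselves
  rounded, pooled values are compared at the propagated-rounding bound
  (~0.01) rather than at machine precision.

## Problem sizes

The calibration experiments use n = 300, m = 1000 for null-scan inflation
(20 replicates), n = 500, m = 2000 for variance-fraction recovery
(10 seeds), 200 replicates for HEIDI type-I error and 100 for linkage
power, and n = 400 per cohort for the classifier transfer pair. These sizes
were chosen as the smallest at which the asymptotic behaviour under test is
expected to hold cleanly (λ's sampling SD scales as m^−1/2; ρ²'s SE as
roughly n⁻¹); the same experiments scale up unchanged.

## Limitations

Estimators are validated under the generator's assumptions; real arrays add
intensity-dependent artefacts, co-methylation blocks and relatedness that
the generator does not produce. ρ² on the observed scale mixes cause and
consequence of disease — nothing here distinguishes them, and the MR module
only interrogates *genetic* mediation at a single locus. The classifier
measures case–control discrimination in a diagnosed sample; it is not a
pre-diagnostic risk predictor. HEIDI's delta-method covariance is a
first-order approximation that degrades with weak instruments; the
SNP-inclusion threshold guards against this but cannot remove it.
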