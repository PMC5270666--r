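---
title: "Methods: the latent dementia phenotype and the serum-protein mediation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the latent dementia phenotype and the serum-protein mediation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Dementia is, by definition, cognitive impairment that disables.  The latent
variable delta operationalizes that definition: it is the fraction of general
cognitive performance that is shared with functional status.  `deltamed`
builds delta as an orthogonal bifactor model over five indicators — Logical
Memory II, Visual Reproduction I, COWA, Digit Span, and summed IADL
(reverse-scored so higher always means better function):

* every indicator loads on **delta**;
* the four cognitive indicators additionally load on **g'**, the residual of
  general intelligence after delta is removed;
* IADL loads on delta *only* — this exclusion is what ties delta to
  disability and makes the decomposition identified;
* both latent variances are fixed at 1 and the factors are orthogonal, so
  the factor-score weights are scale-free.

With five indicators the model has 14 free parameters against 15 distinct
covariance moments (df = 1).  That single degree of freedom makes the
delta/g' split empirically fragile: when the two loading vectors on the
cognitive indicators are close to proportional, the likelihood can drift to
a degenerate solution in which delta collapses onto the IADL-specific
dimension.  The estimation engine guards against this with box constraints
on residual variances (below), but users fitting their own indicator sets
should check `factor_determinacy()` and the `$warnings` field of the fit.

Age's effect on the phenotype is decomposed per biomarker with a
three-path model.  The package deliberately keeps the path labels of the
delta literature, **which are not the conventional mediation labels**:

| label    | meaning                               | conventional name |
|----------|---------------------------------------|-------------------|
| `path_a` | age -> phenotype, direct (adjusted)   | c'                |
| `path_b` | biomarker -> phenotype                | b                 |
| `path_c` | age -> biomarker                      | a                 |

The indirect effect is `path_c * path_b`, tested by the delta-method Sobel
statistic, and the mediated share is reported as
`100 |cb| / (|cb| + |a|)` — unsigned, so that *attenuating* mediators
(indirect effect sharing the direct effect's adverse sign) and
*accentuating* ones (opposing it) both report positive shares.  The signed
MacKinnon proportion `cb / (a + cb)` is emitted as a diagnostic column.
Biomarkers enter one at a time; multivariate mediation and interactions are
out of scope.

Every biomarker is classified by two Bonferroni-gated decisions
(p < 0.001, strict): class 1 if both `path_c` and `path_b` pass (candidate
mediator), class 2 if only `path_c` (age-related only), class 3 if only
`path_b` (phenotype-related only), class 4 otherwise.

## Composite scoring and its one non-obvious choice

Factor scores use the regression method, `W = Sigma^-1 Lambda Phi`.  For an
orthogonal bifactor with all-positive loadings this method has a known
wrinkle: the two score columns are *not* uncorrelated (the population
score correlation here is about 0.3), and the g' score absorbs a
delta-correlated component.  Because g' is defined as delta's residual in
general intelligence, `composite_scores()` therefore orthogonalizes the g'
composite against the delta composite by default — the empirical
realization of "g' is what is left of g after delta".  This makes the two
score columns exactly uncorrelated and removes essentially all of the g'
score's delta contamination, which is what produces the characteristic
validation contrast: delta discriminates dementia cases from controls at
AUC > 0.9 while g' sits at chance.

Two consequences are worth knowing:

* Scores are *attenuated* stand-ins for the latents.  Paths into the delta
  composite (`path_a`, `path_b`) are scaled by the score's validity
  (roughly the squared determinacy, about 0.77 under the default
  generator).  The mediated share is a ratio of two such paths, so the
  scaling cancels and the share is recovered without bias.
* The delta composite retains a small g' cross-loading (about 0.25).  If
  g' itself carries an age path, that leaks into the fitted direct path
  `path_a` and biases the mediated share downward by several points.  The
  package's percent-recovery analyses therefore use generating
  configurations with the g'-age path set to zero; with the default weak
  path (-0.11) the bias is a property of regression-method scoring, not of
  the arithmetic.

Scoring is complete-case: a subject missing any indicator is scored
missing.  This keeps composites deterministic and mirrors restricting ROC
analyses to complete cases.

## Biomarker preprocessing

The conditioning chain per biomarker column, in fixed order:

1. **Outlier trimming**: values beyond 3.0 SD of the column mean are set
   missing.  The pass is single — z-scores are computed once from the
   input, not iterated — because iterated trimming changes counts and is
   a different procedure.
2. **Log-normalization**: if |skewness| > 1.0 the column is natural-log
   transformed (non-positive values are first shifted by `1 - min`, and
   the shift is recorded).
3. **Standardization** to mean 0, SD 1.
4. **Batch residualization** on batch dummy variables (OLS residuals),
   then re-standardization.  Pre-residualizing rather than adding batch
   dummies inside every SEM keeps all per-protein models structurally
   identical.

Applying the chain twice is an identity for the transform steps (no second
log trigger, residualization of residuals is the identity, standardization
of standardized data is the identity); only the outlier pass can touch
additional points when the processed scale still has |z| > 3 tails, which
is why the trimming is deliberately single-pass and reported per column.
Note one side effect measured during development: trimming on the *raw*
(skewed) scale deletes genuine high values of the latent biomarker signal
and attenuates both `path_c` and `path_b` by roughly 5% on lognormal
columns — faithful to the published procedure, but users comparing shares
across differently-skewed panels should be aware of it.

## Estimation engine

`sem_fit()` estimates RAM-form models (`Sigma = F (I-A)^-1 S (I-A)^-T F'`)
by maximum likelihood:

* **ML** minimizes `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` on
  complete cases, with the sample covariance computed with divisor `N`
  and the test statistic `chi^2 = (N-1) F_min`.  The divisor-N convention
  is what makes FIML and ML coincide exactly on complete data.
* **FIML** maximizes the casewise likelihood accumulated over missingness
  patterns, with a saturated mean structure; `chi^2 = 2(ll_sat - ll_model)`
  against the saturated model fitted by EM.
* Optimization is L-BFGS-B with analytic gradients (ML), followed by
  damped Newton polishing on the coordinates away from their bounds;
  convergence requires a projected gradient norm below `1e-5`.  On
  non-convergence up to five deterministically jittered restarts run, and
  the result is flagged — never silently accepted.
* Observed-variable residual variances are bounded below at
  `-0.05 * S_vv`.  Mildly negative (Heywood) estimates remain reportable
  and are recorded in `$warnings`; the bound only excludes the unbounded
  ridge on which weakly identified bifactor samples otherwise diverge.
  Parameters pinned at the bound are flagged.
* Standard errors come from the inverse observed information (finite
  differences of the analytic gradient).
* Start values are deterministic: per-equation OLS for observed-variable
  regressions, tiered magnitudes (0.7/0.35 of the indicator SD) for
  loadings so multi-factor starts are asymmetric, half the sample variance
  for residuals.

Fit indices follow the usual formulas — CMIN/DF, CFI against the
independence model, RMSEA — with NA sentinels for saturated models, and
`chi_square_difference()` implements the nested-model test (delta df = 0
with identical fits returns p = 1 rather than an error).  Residual
covariances are admitted only when declared in a spec; no automated
forward selection is performed.

Multi-group fitting minimizes `sum_g (N_g - 1) F_g` with equality
constraints expressed by shared parameter labels; the split-half
generalizability check constrains `path_a`, `path_b`, `path_c` jointly
across random halves and tests the fit degradation.  (Whether to constrain
paths jointly or one at a time was genuinely open; jointly is the default
because it matches testing "the mediation model generalizes" as one
hypothesis, and the API accepts any label subset.)

## The synthetic-cohort generator

There is no public deposition of the motivating cohort, so the generator
is the package's evidence base: it draws subjects with exactly the
structure the analysis assumes, plus the generating truth.  Defaults, and
why:

* **n = 3000 subjects**, age ~ Normal(71, 9.5), indicator means/SDs,
  covariate marginals (APOE 39% carriers, education 13.2 y, 36% of the
  ethnicity group, 39% male, GDS 5.6) echoing the demographic table of a
  large dementia cohort.
* **Loadings** delta (.75, .45, .65, .35, .80) and g' (.40, .65, .45, .70, 0).
  Chosen at design time for two properties: delta determinacy 0.88
  (comfortably above the 0.80 acceptance floor), and strongly
  non-proportional loading ratios on the cognitive indicators — with
  near-proportional ratios the bifactor split is empirically
  under-identified and roughly a quarter of n = 3000 samples hit the
  collapse boundary; with these, none of 30 did.
* **Direct age path** a = -0.12 (standardized), a weak **g'-age path**
  -0.11, and small covariate effects on delta.  The implied total age
  effect on delta is about -0.46 — deliberately strong, because the
  default panel carries 20 simultaneous mediators.
* **Biomarker panel** of 100: 20 class-1 mediators (|c| = 0.35,
  |b| = 0.12; 14 attenuating with c > 0, b < 0 and 6 accentuating with
  c < 0, b < 0, i.e. proteins that decline with age yet accentuate its
  adverse effect), 40 class-2, 18 class-3, 22 class-4 — the taxonomy
  shape of a real screen.  |b| = 0.12 is the operational meaning of
  "strong effect" here: after score attenuation and complete-case loss it
  gives per-path power ~0.95 at the 0.001 gate, so a well-calibrated
  screen should recover >= 80% of true mediators.  Each default mediator's
  true mediated share is 100·0.042/(0.042+0.12) ≈ 26%.
* **Nuisance structure**: 5 assay batches with additive shifts
  (SD 0.3), every other biomarker reported on a lognormal scale, 0.5%
  gross outliers (5–8 SD), 5% missing cells (MCAR by default; an
  age-dependent option exists).  Age and diagnosis are never masked, and
  age is the only never-adjusted exogenous variable, which keeps the
  mediation estimand clean.
* **Diagnosis** is assigned by tertile cuts on delta (worst third "AD",
  best "NC"), and CDR sum-of-boxes is a noisy monotone decreasing
  transform of delta, truncated to [0, 18] in half-point steps.  Diagnosis
  is only used for ROC validation, so the generative rule is a declared
  convention, not an inference.

What the generator does *not* emulate: longitudinal visit structure beyond
the implicit two-visit layout (visit-1 biomarkers, visit-2 cognition),
ethnicity-specific loading differences, non-normal latent distributions,
and informative (MNAR) missingness.  Passing tests on these cohorts
therefore show the *pipeline arithmetic* is right under the model's own
assumptions; they cannot show the model is right for any particular real
cohort.

With 20 simultaneous mediators screened one at a time, each per-biomarker
model folds the other 19 indirect paths into its direct path, so the
estimated per-biomarker share on the default panel is mechanically smaller
(~9%) than the single-mediator truth formula (~26%).  Recovery of the
share formula itself is checked on single-mediator configurations, where
the two coincide.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at n = 3000 (screens, recovery
replicates; 100 replicates per recovery level in the tests, 30 in the
acceptance script), n = 5000 for the phenotype-contrast checks, 500 null
biomarker tests for gate calibration, and 200 replicates for the
chi-square-difference calibration — sizes chosen so every Monte-Carlo
tolerance is several times its standard error.

## Known limitations

* Regression-method scores are attenuated and cross-contaminated;
  conclusions about *path magnitudes* (not shares, not classifications)
  on the composite scale should multiply out the validity.
* The per-protein models assume linear, homoscedastic, Gaussian structure;
  robust and ordinal estimators are out of scope.
* The split-half step tests equality of the three mediation paths only;
  full measurement-invariance ladders are not implemented.
* FIML gradients are numeric, so FIML fits of large specifications are
  markedly slower than ML.
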