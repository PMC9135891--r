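---
title: "Methods: simulated twin cohorts and bivariate Cholesky models of puberty timing and BMI"
author: "pubertwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated twin cohorts and bivariate Cholesky models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubertwin)
```

## The scientific problem

Earlier puberty is associated with higher adult body mass index (BMI), but
childhood adiposity predicts both. The classical twin design separates the
sources of such an association: monozygotic (MZ) co-twins share all of
their segregating genetic variation, dizygotic (DZ) co-twins on average
half of the additive part, and both share their rearing environment. A
trait's variance can therefore be decomposed into additive genetic (A,
cross-twin correlation 1.0 in MZ / 0.5 in DZ), dominance (D, 1.0 / 0.25),
shared environmental (C, 1.0 / 1.0) and unique environmental (E,
uncorrelated) components; C and D are not jointly identifiable in twins
reared together, so models are ACE, ADE or AE.

For two traits the bivariate Cholesky decomposition writes each component's
2×2 covariance block as \(X = L_X L_X^\top\) with \(L_X\) lower
triangular, which keeps every block positive semidefinite by construction.
The quantities of scientific interest are derived from the blocks:

- the genetic correlation \(r_A = A_{12}/\sqrt{A_{11}A_{22}}\) (and its
  E analogue \(r_E\)), whose square is the fraction of one trait's genetic
  variance shared with the other;
- the decomposition of the phenotypic correlation
  \(r = \sum_X X_{12}/\sqrt{V_{11}V_{22}}\) into signed per-component
  contributions, reported as percentages of \(r\) that close to 100 (a
  negative percentage marks a component covariation opposing the direction
  of the overall correlation).

Longitudinal claims ("does earlier puberty predict adult BMI beyond
childhood BMI?") are addressed by standardized regressions of post-puberty
BMI on a puberty index with baseline BMI as a covariate, and genetic
liability is probed by regressing puberty indices on polygenic scores of
obesity indices with genetic principal components as covariates. Because
twins come in pairs, all regression inference uses cluster-robust
(sandwich) standard errors with pairs as clusters.

Individual-level twin-cohort data of this kind are access restricted, so
the package pairs every estimator with a synthetic-cohort generator that
reproduces the statistical structure the estimators assume. All operating
characteristics quoted by the test suite are properties of this generator,
not of any real cohort.

## The synthetic cohort generator

`generate_cohort()` draws, for each same-sex twin pair, latent A, C (or D)
and E component vectors per trait with the cross-twin sharing coefficients
above, sums them into standardized phenotypes, and then decorates them on
the raw scale. Each component is drawn through the same block-assembly
routine that the likelihood code uses for the expected pair covariance;
drawing components separately (rather than one stacked phenotype vector)
keeps the additive-genetic latents available, which the polygenic-score
simulator needs and which makes exact MZ sharing literal: the MZ draw is
copied, not correlated-at-1.

The default trait panel (`trait_defaults()`) mirrors a Finnish adolescent
twin cohort followed from age 12 to 35: Pubertal Development Scale (PDS)
scores at 12 and 14 (1–4 mean-item scale), retrospective pubertal age (PA,
years, reported at 17), and BMI at eight waves. Means and SDs are
sex-specific (e.g. male BMI at 12: 17.7 ± 2.55; female PA: 12.8 ± 1.18).
Variance components default to moderate-to-high heritability with shared
environment fading after mid-adolescence. The default cross-trait
correlation structure is a two-factor construction (a puberty factor and an
adiposity factor, correlated 0.40) that guarantees positive semidefinite
component correlation matrices while matching published magnitudes:
within-puberty genetic correlations near 0.5, puberty–adolescent-BMI
genetic correlations of 0.2–0.3 (negative for PA, since later puberty goes
with lower adolescent BMI). The anchoring magnitudes are tabulated in
`cohort_target_correlations()`. One simplification: the young-adult BMI
wave is modeled as a single trait (`bmi24`) even though reporting ages
straddle 22–24 in the cohorts being emulated, and a single `bmi17` wave
serves both sub-cohorts.

Raw-scale decoration, in order:

1. **Skew tilt.** BMI-type traits pass through
   `apply_skew()`: standardize, apply \(z \mapsto (e^{\lambda z}-1)/\lambda\),
   rescale to the original mean and SD. The map is monotone, reduces to the
   identity at \(\lambda = 0\), and for normal input has the skewness of a
   log-normal with \(\sigma = \lambda\). The default \(\lambda = 0.45\)
   gives sample skewness near 1.5, inside the 1.11–2.36 band typical of
   raw adolescent BMI, and the log transform used in preprocessing
   substantially reduces it — mirroring the standard analysis pipeline.
   The tilt is applied to the pooled standardized values, so it slightly
   attenuates Pearson twin correlations on the raw scale; tests of
   correlation structure therefore use skew-free traits, and the model
   pipeline works on log-BMI where the attenuation is largely undone.
2. **Location/scale and age.** Values are scaled to sex-specific means and
   SDs, and a per-pair survey-age jitter (uniform ±0.5 years around the
   nominal wave age, identical for co-twins) enters through a trait-specific
   raw-scale slope. Co-twins share their survey age by design; the cohorts
   emulated here surveyed both twins together, and wave-level age
   differences exist only *between* pairs — which is exactly what the
   age residualization in preprocessing removes.
3. **PA censoring.** Latent pubertal ages above 17 years are recoded to 17
   and flagged (`censor_pa()`), emulating respondents who had not yet
   reached menarche/voice break at the retrospective survey.
4. **Attrition.** Each trait is masked missing-completely-at-random with a
   wave-specific probability; published attrition counts give the
   magnitudes, but no dropout mechanism is modeled.
5. **Polygenic scores.** Each configured score is
   \(\alpha \tilde A + \sqrt{1-\alpha^2}\, G\), where \(\tilde A\) is the
   target trait's unit-variance additive latent and \(G\) an independent
   genome-determined noise latent (copied within MZ pairs, correlated 0.5
   within DZ pairs), with \(\alpha = \sqrt{r^2 / a^2}\) so the squared
   correlation with the target trait equals the configured `r2` (which
   therefore cannot exceed the trait's heritability). Scores are latent:
   no SNPs or LD are simulated. Principal components are independent
   standard normals — null population structure — with an optional
   single-PC confound switch for testing the adjustment.

Cohorts are byte-identical given the seed; the TSV writer stores a sidecar
JSON with the config hash so runs are self-describing.

What the generator does *not* emulate: non-random dropout, ordinal
item-level PDS responses (PDS is simulated on the mean-score scale),
sex-limitation of genetic effects, opposite-sex pairs (excluded by design,
matching the same-sex restriction of the analyses), and real population
stratification. Passing tests therefore certify the estimators under the
model's own assumptions, not robustness to their violation.

## Preprocessing

`preprocess_cohort()` applies the standard preparation: natural log of BMI
(the transform precedes adjustment), then within-sex ordinary
least-squares residualization of every trait on its survey-wave age, with
the residuals z-standardized per stratum. Standardization puts all traits
on a common scale, so twin-model variances are comparable and regression
coefficients read as SD-per-SD; the skewness estimator is the adjusted
Fisher–Pearson form with the \(\sqrt{n(n-1)}/(n-2)\) correction used by
most statistics software. Censored PA values enter residualization as-is
(at 17 years), replicating the conventional treatment of PA as a
continuous variable; `fit_*` likelihoods likewise treat PA as observed.
Fractional ages are accepted throughout.

## Full-information likelihood and its optimization

For a pair with observed phenotype subvector \(y_o\), the contribution is
the multivariate-normal log-density under the model-implied mean and the
pair covariance \(\Sigma_z = \begin{pmatrix} V & K_z \\ K_z & V
\end{pmatrix}\), marginalizing missing entries by row/column deletion
(`pair_loglik()`). Internally the fitter groups pairs by zygosity ×
missingness pattern and evaluates the likelihood from per-group sufficient
statistics (count, mean, centered scatter), making each evaluation
independent of the number of pairs; the analytic gradient uses
\(\partial\,\mathrm{nll} = \tfrac12 \mathrm{tr}(W\, \partial\Sigma)\) with
\(W = n\Sigma^{-1} - \Sigma^{-1}(S + n dd^\top)\Sigma^{-1}\). The grouped
objective is tested to equal the per-pair sum, and the gradient to match
finite differences.

Numerical choices:

- **Parameterization.** Cholesky loadings keep every component block PSD,
  so the implied pair covariance is positive definite whenever the E block
  is nonsingular; no constraints are needed. Trait means are estimated
  jointly (two extra parameters) even though inputs are typically
  pre-standardized.
- **Starting points.** Up to five deterministic starts: a moment start
  from the observed within- and cross-twin covariances (Falconer-style
  component estimates, eigenvalue-clamped to PD), the same start with A
  halved, and even variance splits with cross-trait correlations 0 and
  ±0.3. The best converged solution wins; ties go to the smaller gradient
  norm. Simulation loops may use `n_starts = 1` (the moment start), which
  the calibration tests exercise at scale.
- **Confidence intervals.** Delta method from the observed-information
  covariance, applied on the Fisher-z scale for correlations and
  back-transformed, which respects the [−1, 1] range. Profile-likelihood
  intervals are not implemented; the delta intervals are the ones whose
  90–98% simulation coverage the test suite verifies. Solutions with a
  component correlation within 0.02 of ±1 are flagged as boundary
  solutions rather than rejected.
- **Model comparison.** `compare_models()` computes the likelihood-ratio
  statistic with chi-square df equal to the parameter-count difference —
  the naive convention common in this literature. Because dropping C tests
  variance components on their boundary, this is conservative; an
  equal-mixture option (`boundary = "mixture"`) is provided. LRT values
  down to −10⁻³ (optimizer tolerance noise on log-likelihoods of order
  10⁴) are clamped to zero; larger inversions raise an error suggesting
  more starts.
- **Missing data.** All pairs with any observed phenotype contribute
  (full-information ML); `complete_pairs_only = TRUE` reproduces a
  complete-pairs analysis. Fits require at least 30 pairs per zygosity by
  default (`min_pairs`).
- **Model ladder.** The reporting pipeline fits ACE as the starting model
  and decomposes under AE, retaining the ACE–AE comparison with a
  Bonferroni-flagged sheet (default 24 tests, threshold 0.002). ADE is
  available on request; ACDE is not identifiable and not offered.

## Cluster-robust regressions

Point estimates are OLS. The covariance is the clustered sandwich
estimator with the Stata-style small-sample factor
\(\frac{G}{G-1}\cdot\frac{N-1}{N-k}\) and t inference on \(G-1\) degrees
of freedom (G = number of pairs) — the Williams-type correction. With
every observation its own cluster this reduces exactly to HC1; the test
suite pins both identities against a brute-force matrix oracle. In
`standardized_association()` only the predictor and outcome are
z-standardized (within the analyzed stratum); adjusters — baseline BMI,
principal components — enter on their original scale, so the headline
coefficient is SD-per-SD while adjustment is unaffected by scaling.
Models are complete-case; no imputation is performed.

## Problem sizes used by the verification suite

The simulation checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted: intraclass correlations at
20,000 + 20,000 pairs (±0.02), genetic-correlation recovery at
5,000 + 5,000 pairs (±0.04–0.05), CI coverage and LRT calibration over 200
replicates at 1,000–2,000 pairs per zygosity, and regression-path recovery
at 1,000 + 1,000 pairs (±0.03). The sufficient-statistic likelihood makes
these loops cheap: a bivariate AE fit takes tens of milliseconds at these
sizes.

## Known limitations

- PA censoring is ignored in the likelihood (a sensitivity flag can drop
  censored values); a proper Tobit-style likelihood is future work.
- Only Wald-type (delta-method) intervals are reported.
- The generator's MCAR attrition cannot probe missing-not-at-random
  sensitivity, and its latent polygenic scores cannot probe LD or
  stratification artifacts.
- No sex-limitation models: male and female fits are stratified, never
  jointly constrained.
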