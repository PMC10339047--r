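---
title: "Methods: Mendelian randomization and survival analysis of circulating metabolic measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization and survival analysis of circulating metabolic measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

## The scientific problem

Circulating metabolic measures — lipoprotein subfractions, fatty-acid
ratios, amino acids and the like — predict incident non-alcoholic fatty
liver disease (NAFLD) in prospective cohorts, but observational hazard
ratios conflate causation with confounding and reverse causation.
`metabomr` implements the combined design used to separate these: a
prospective observational arm (Cox proportional-hazards models of an
incident diagnosis-code phenotype) and a two-sample Mendelian
randomization (MR) arm in which genetic variants serve as instruments
for lifelong differences in each metabolic measure. An explicit triage
combines the two arms' evidence into a per-exposure causal call.

Every stage is exercised on synthetic data with known ground truth. The
package therefore ships first-class simulators for GWAS summary
statistics and survival cohorts whose defaults encode the study
conditions the pipeline targets.

## Two-sample MR model

For variant $j$, let $\hat\beta_{X,j}$ (SE $\sigma_{X,j}$) be its
association with the exposure (per SD, from a rank-inverse-normalized
GWAS) and $\hat\beta_{Y,j}$ (SE $\sigma_{Y,j}$) its association with the
outcome (log-odds for the binary disease). Under the instrumental-variable
assumptions each Wald ratio $\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$
estimates the causal effect $\theta$.

The primary estimator is inverse-variance-weighted (IVW) meta-analysis
with multiplicative random effects and an under-dispersion correction:
with weights $w_j = \hat\beta_{X,j}^2/\sigma_{Y,j}^2$,

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j}, \qquad
Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2, \qquad
\hat\phi = \max\!\left(1, \frac{Q}{k-1}\right),$$

and $\mathrm{se}(\hat\theta) = \hat\phi^{1/2} (\sum_j w_j)^{-1/2}$. The
floor at 1 means heterogeneity can widen the interval but apparent
under-dispersion never narrows it below the fixed-effect SE. Cochran's
$Q$ is reported against $\chi^2_{k-1}$.

Four robust estimators probe the exclusion-restriction assumption:

* **MR-Egger** — weighted regression of $\hat\beta_{Y,j}$ on
  $\hat\beta_{X,j}$ *with* an intercept, after orienting each variant so
  $\hat\beta_{X,j} \ge 0$. The intercept estimates the average
  directional pleiotropic effect; its test is the pleiotropy diagnostic
  used by the triage. Residual scale is floored at 1 exactly as in IVW.
* **Weighted median** — the 50% point of the inverse-variance-weighted
  empirical distribution of the ratios (cumulative midpoint positions
  $s_j = \sum_{i\le j} w_i - w_j/2$, linear interpolation at 0.5);
  consistent while valid instruments carry a majority of the weight. SE
  by seeded parametric bootstrap (default 1000 resamples).
* **Contamination mixture** — each ratio is modelled as valid
  ($N(\theta, \mathrm{se}_j^2)$) or invalid
  ($N(0, \mathrm{se}_j^2 + \psi^2)$), each variant taking the larger
  component likelihood; the profile over a $\theta$ grid gives the
  estimate, and the 95% confidence set is the region within
  $\chi^2_1(0.95)/2$ of the maximum — possibly a union of disjoint
  intervals, which is reported as such. Defaults: $\psi$ = 1.5 times the
  SD of the ratios; grid centred on the IVW estimate, half-width six IVW
  SEs (doubled until the maximum is interior), step one tenth of an SE.
  Two numerical choices matter here and are deliberate: the valid
  component uses the *second-order* delta-method ratio SE
  $\sqrt{\sigma_Y^2/\beta_X^2 + \beta_Y^2\sigma_X^2/\beta_X^4}$, because
  the profile treats that SE as the entire uncertainty and the
  exposure-side term is not negligible at metabolite-GWAS precision; and
  confidence bounds are extended half a grid step beyond the inside
  region, since the true cutoff crossing lies between grid points.
  Without these, nominal 95% intervals measurably undercover.
* **MR-PRESSO** — the observed weighted residual sum of squares about
  leave-one-out IVW predictions is compared with a parametric null
  (default 1000 simulations); the global p-value is empirical with floor
  $1/(n_{\mathrm{sim}}+1)$, per-variant outlier p-values are
  Bonferroni-adjusted, and when outliers are flagged the reported
  estimate is the IVW on the remaining variants. The distortion test is
  not implemented.

Binary-outcome estimates are reported as odds ratios per SD,
$\mathrm{OR} = e^{\hat\theta}$.

### Instruments

Candidates are variants with $p < 5\times10^{-8}$ (strict), clumped
greedily within 1 Mb windows at LD $r^2 < 0.01$; ties in $p$ break by
(chromosome, position, identifier) so clumping is order-invariant. A
named preset excludes the glucokinase-regulator region (chromosome 2,
27,219,709–28,246,554, widened 500 kb each side), a locus with primary
hepatic effects on many metabolites. Instruments missing from the
outcome study are replaced by their best proxy at $r^2 > 0.8$ (strict);
a proxy inherits the original variant's exposure record and its outcome
effect is aligned through the sign of the LD correlation. Harmonization
aligns effect alleles across studies, resolving swapped and
complementary-strand notation; palindromic variants are resolved by
allele-frequency concordance and dropped when either minor-allele
frequency exceeds 0.42 (a conventional limit; the frequency carries no
orientation information near 0.5). Instrument strength is summarized by
per-variant $F_j = (\hat\beta_{X,j}/\sigma_{X,j})^2$ and variance
explained $r_j^2 = t_j^2/(t_j^2 + n - 2)$.

### Directionality

Steiger filtering removes variants that explain significantly more
outcome than exposure variance (Fisher-transformed correlations, one-sided
z-test at $\alpha = 0.05$); for a binary outcome the log-odds t-statistic
is used directly, an acknowledged approximation. Reverse MR runs the full
univariable pipeline with continuous liver fat as exposure and the
metabolite as outcome — a binary diagnosis makes a poor MR exposure, the
underlying continuous trait does not.

## Multivariable MR

To ask whether a metabolite acts on disease independently of adiposity,
the same instruments (plus the covariate's harmonized effects) enter a
weighted regression of $\hat\beta_{Y}$ on the matrix of exposure
effects without intercept (MVMR-IVW; SEs scaled by
$\max(1,\sqrt{Q/(k-p)})$), an intercept variant oriented on the primary
exposure (MVMR-Egger), a weighted $L_1$ regression through the origin
solved by iteratively reweighted least squares (MVMR-median; bootstrap
SEs), and MVMR-Lasso: per-variant intercepts $\alpha_j$ penalized by
$\lambda\sum_j|\alpha_j|$, solved by coordinate descent (tolerance
$10^{-8}$) along a descending log-spaced $\lambda$ grid. The selected
$\lambda$ is the largest whose zero-intercept ("valid") subset passes
Cochran's $Q$ at the 95% $\chi^2_{k_{\mathrm{valid}}-p}$ quantile; the
reported estimate is the MVMR-IVW on that subset. Because the valid
subset only shrinks as $\lambda$ decreases, this is the maximal set of
instruments consistent with homogeneity — the natural reading of a
heterogeneity stopping rule.

Conditional instrument strength for exposure $e$ regresses its effects
on the other exposures' (weights $1/\sigma_{X,e,j}^2$) and reports
$F_e = Q_{x,e}/(k-p)$, the residual weighted sum of squares per spare
degree of freedom. Cross-exposure GWAS error covariances are set to zero
— a documented limitation when exposures share one sample.

## Observational arm

The incident phenotype is the first occurrence of a target liver code
(K74.0, K74.2, K75.8, K76.0, K76.9); any other K74/K75/K76 code removes
the participant entirely (liver disease of another etiology), and target
codes dated at or before enrollment remove the participant from the
incident analysis. Cox models use the partial likelihood with the Efron
tie correction (Breslow available), follow-up years as the time scale
with enrollment as origin, and report hazard ratios per SD for
standardized metabolites, adjusted for age, sex, smoking, alcohol,
deprivation, ethnicity, waist circumference and metabolic-syndrome
medication. Kaplan-Meier curves use the product-limit estimator.
Quintiles cut at the 20/40/60/80 empirical percentiles with ties to the
lower group. Metabolic dyslipidemia uses the NCEP-ATPIII cut-offs:
high triglycerides at $\ge 1.7$ mmol/L (boundary inclusive, the
"$\ge$ 150 mg/dL" convention), low HDL-cholesterol below 1.0 (men) or
1.3 (women) mmol/L, strict.

## Multiplicity and triage

Metabolic measures are strongly correlated, so the number of independent
tests is taken as the smallest number of principal components of the
phenotypic correlation matrix explaining 90% of the variance; the
corrected threshold is $0.05/m$ (displayed half-up to four decimals, so
$0.05/8$ prints as 0.0063). K-means on the rows of the correlation
matrix (default $k = 3$, 25 restarts, seeded) summarizes the cluster
structure, reporting each cluster's minimum pairwise correlation.

An exposure is called a **causal candidate** only if *all* of: primary
IVW $p$ below the corrected threshold; strictly more than half of the
available robust estimators significant at 0.05; all estimates sharing
the IVW's sign; Egger intercept $p > 0.05$; MVMR robustness (MVMR-IVW
significant with the same sign, MVMR-median and MVMR-Lasso significant,
MVMR-Egger intercept non-significant); reverse-MR $p \ge 0.05$; and
Steiger filtering applied. One deliberate reading: a *non-significant*
Egger intercept is the pass condition — a significant intercept is
evidence of directional pleiotropy, and the criterion is stated
inconsistently in prose descriptions of such pipelines; treating
$p > 0.05$ as the pass is the only internally consistent choice.
Triage flags are returned individually so a verdict can always be
audited.

## Synthetic data: what it emulates, and what it does not

`simulate_two_sample_gwas()` draws effect-allele frequencies
$p_j \sim U(0.05, 0.95)$, true effects $b_j$ scaled so
$\sum_j 2p_j(1-p_j)b_j^2$ equals the configured heritability, and
standard errors $1/\sqrt{2p(1-p)n}$ — the standardized-trait
approximation appropriate for rank-inverse-normalized GWAS. Exposure and
outcome estimates are independent draws (two-sample independence), with
$\hat\beta_{Y,j} \sim N(\theta b_j + \alpha_j, \sigma_{Y,j}^2)$ and
direct effects $\alpha_j$ nonzero for a configured fraction of invalid
variants. LD, when requested, is compound-symmetric within blocks and
zero between — the simplest structure that gives clumping real work.

Default study sizes mirror the targeted designs: metabolite GWAS
$n = 115{,}000$; waist circumference $n = 462{,}166$; liver fat
$n = 32{,}860$; and for the binary disease outcome an **effective**
sample size of 33,462, i.e. $4/(1/8434 + 1/770{,}180)$ — log-odds
standard errors scale with the case-control balance, not the total
count, and using the total would make outcome noise unrealistically
small relative to exposure noise. Heritability defaults (4% over 80
candidate variants) put single-variant F-statistics near 58, matching
instrument panels whose F-statistics all exceed 54.

`simulate_cohort()` builds the metabolite panel from block latent
factors (within-block pairwise correlation = squared loading, default
0.8, giving observed minima near 0.78–0.79), covariates with plausible
population distributions, Weibull proportional-hazards event times with
configurable per-SD log hazard ratios, administrative censoring at 12.6
years, and diagnosis records that include back-dated (prevalent) and
non-target liver codes so the phenotype filter is genuinely exercised.

Not emulated: realistic genome-wide LD, population stratification,
sample overlap between exposure and outcome GWAS, winner's-curse-free
instrument discovery in an external sample, missing covariate data, and
competing risks. Passing tests therefore demonstrate internal
correctness and statistical calibration under the stated generative
model, not robustness to these real-data complications.

### Orientation and directional pleiotropy

With effect signs in their natural (sign-random) orientation, a
directional set of direct effects $\alpha_j > 0$ produces
*sign-symmetric* contamination of the Wald ratios (the ratio divides by
$b_j$ of random sign). The simulator's `exposure_increasing` flag
orients all true effects positive — the convention under which
directional pleiotropy actually biases IVW upward and the Egger
intercept estimates the mean direct effect. Recovery tests use whichever
orientation matches the claim under test, and Egger-intercept recovery
additionally restricts to genome-wide-significant instruments, since a
variant whose observed sign can flip contributes its pleiotropy with a
random sign.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to give informative Monte-Carlo precision while staying
quick: calibration suites use 1000–2000 replicates of 30–60 variants
(binomial SE on a 5% rate at 2000 replicates is about 0.5 percentage
points); recovery suites use 200–1000 replicates; the end-to-end
benchmark runs 20 exposures (five causal at log-odds effects
$\pm0.3, \pm0.5, 0.4$ per SD, five nulls contaminated with 30% invalid
instruments at mean direct effect 0.08) through the complete pipeline;
cohort analyses use 5,000–20,000 subjects. The weighted-median and
MVMR-median bootstraps and the MR-PRESSO simulations are seeded
everywhere, and all generators restore the caller's RNG state.

Degenerate inputs fail loudly rather than silently: too few instruments
for an estimator's preconditions, collinear MVMR designs, a
contamination-mixture maximum on the grid boundary, empty instrument
sets after thresholding, all-dropped harmonization, non-convergent or
separated Cox fits, and fewer than five distinct values for quintiles
all raise errors with specific messages.

## Known limitations

* Conditional F-statistics ignore cross-exposure sampling covariance;
  with exposures measured in one sample they are optimistic.
* Steiger's test on a binary outcome approximates variance explained
  from the log-odds t-statistic.
* The MR-PRESSO distortion test and the correlated-instrument IVW are
  out of scope, as are multi-allelic variants and indels.
* The weighted median retains a finite-sample percentile shift when all
  instruments are oriented exposure-increasing and contamination is
  one-sided; the triage relies on the estimator battery, not any single
  robust method, for exactly this reason.
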