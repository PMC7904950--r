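---
title: "Methods: polygenic scores, the plasma proteome, and bidirectional causal inference for BMI"
author: "proteogps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores, the plasma proteome, and bidirectional causal inference for BMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`proteogps` implements an analysis chain that links blood plasma protein
levels to body mass index (BMI) through genetic drivers:

1. a **genome-wide polygenic score (GPS)** is computed from imputed dosages
   and a weight table, with allele harmonization and optional cis-window
   exclusion;
2. a **protein-wide association scan** regresses each (log2, z-scored)
   protein on BMI or on the GPS with covariate adjustment, Bonferroni
   control, replication assessment and subsampling-based replication power;
3. a **tail-effect analysis** asks whether the score-protein slope is
   amplified in the extremes of the score distribution;
4. **bidirectional Mendelian randomization (MR)** estimates causal effects
   in both directions (BMI-to-protein and protein-to-BMI) with one-sample
   two-stage least squares (2SLS) and two-sample summary-statistic
   estimators (Wald ratio, inverse-variance weighting, MR-Egger);
5. a **biweight midcorrelation screen** relates expression levels to
   quantitative traits robustly.

Real cohort data of this kind (genotypes plus aptamer-based proteomics) are
access-restricted, so the package ships a first-class synthetic-cohort
generator with known causal structure. Every stage is validated against that
ground truth; the limits of what such validation shows about real data are
discussed at the end.

# The synthetic cohort

## Genotypes

Dosages are drawn per variant as Binomial(2, maf) under Hardy-Weinberg
equilibrium, independently across variants. Linkage disequilibrium is
induced only inside declared blocks (needed to exercise LD clumping): block
members copy the lead variant's haplotype alleles with probability
`sqrt(r2)`, which gives an expected squared dosage correlation of `r2` with
the lead. Genome-wide LD, recombination maps, population structure and
imputation uncertainty are deliberately not modelled: the downstream
analysis never uses LD except pairwise at clumping time.

## BMI and the score link

With `S` the standardized true score (weighted dosage sum over the score
variants, weights drawn standard normal),

```
BMI = mu + beta_gps * L(S) + beta_age * (age - 60) + beta_sex * sex + N(0, noise_sd)
```

where the link `L` is a hinge: identity for `|s|` below the
`amplification_q` quantile of `|S|`, slope multiplied by `amplification_k`
beyond it. `amplification_k = 1` gives a strictly linear link. The hinge is
the simplest mechanism that concentrates extra slope in the extremes of the
score distribution, which is the qualitative phenomenon the tail analysis
measures.

Defaults (all chosen once, from the study conditions the pipeline emulates):

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_samples` | 996 | samples | proteomics cohort size the pipeline targets |
| `mu_bmi` | 27.2 | kg/m2 | adult European population mean |
| `beta_gps` | 2.2 | kg/m2 per score SD | score explains about 30% of BMI variance under the linear link (reported GPS-BMI R2 ~ 0.3); in the full generative model with feedback and confounding the realized share is ~0.2 |
| `noise_sd_bmi` | 3.25 | kg/m2 | total BMI SD ~ 4-4.7 kg/m2, typical of adult cohorts |
| `beta_age`, `beta_sex` | 0.04, 0.5 | kg/m2 per yr; kg/m2 | weak covariate effects |
| `amplification_k` | 4 | -- | tail effects "almost quadrupled" relative to the full sample |
| `amplification_q` | 0.92 | quantile of abs(S) | places the hinge just inside the 5% tails; see the tail-regression section for why the hinge must not coincide with the 5% cut |
| `log2_offset` | 10 | log2 units | emitted protein matrix is positive, `2^(P+10)`, so the log2 preprocessing step has real work to do |

`gps_slope_for_r2()` inverts the full variance decomposition (covariates,
residual noise, protein feedback, confounder loadings) to find the slope
for a target variance share under the linear link; it is validated
empirically to within 0.02 of the target at n = 10000.

## Protein regimes

Each protein carries a regime tag and effect sizes (`alpha`: protein-SD per
BMI-SD; `theta`: kg/m2 per protein-SD; `delta`: protein-SD per SD of its
cis genotype, the standardized sum of its cis-variant dosages):

* `bmi_to_protein`: `P = alpha * z(BMI) + delta * G_cis + e`
* `protein_to_bmi`: `P0 = delta * G_cis + e`, then `BMI <- BMI + theta * P0`
* `bidirectional`: generated sequentially -- `P0` feeds BMI, the final
  protein is `P0 + alpha * z(BMI)`. The sequential construction keeps the
  model acyclic so the ground truth stays well defined.
* `confounded_null`: a latent `U ~ N(0,1)` loads on both BMI
  (`confound_bmi = 2.0` kg/m2) and the protein (`confound_protein = 0.5`
  SD); there is no causal edge in either direction.

Default effect sizes: `alpha = 0.25` (about 0.06 per kg/m2 at a BMI SD of
4, inside the range reported for strong BMI-protein associations),
`theta = 1.2`, `delta = 0.35` (cis R2 ~ 12%, a typical strong cis-pQTL).
`theta` and `delta` are a power calibration: the protein-to-BMI edge must be
detectable through its cis instruments at n = 5000 under a per-test
threshold of 3.29e-4 (the Bonferroni level for 152 tests) with margin --
the condition the direction-recovery validation is defined by. The naive
calculation using only the score and noise variances understates the BMI
variance (feedback and confounding add ~8 kg2/m4) and was corrected to the
full decomposition; with these values reverse-direction recovery is ~99%.

There is no published generative magnitude for protein noise; `e` has SD 1
on the log2 scale so that `alpha`, `delta` are approximately standardized
effects. The mapping to any real cohort's variance structure is
unverifiable and not claimed.

# Scoring

The raw score is `sum_v w_v * d*_{s,v}` with `d* = dosage` for rows whose
effect allele matches the dosage-counted allele and `2 - dosage` for rows
matching the other allele. Palindromic variants (A/T, C/G) are excluded
as strand-ambiguous; unmatched rows are dropped and counted, never fatal.
Standardization uses the sample SD (n-1), which makes
`standardize(c(1,2,3)) == c(-1,0,1)` exact. The cis-exclusion window
(default 100 Mb) is anchored on the gene interval boundaries, same
chromosome only; whether such windows should be boundary- or TSS-anchored
is not standardized in the field, so the window is a parameter. Indels and
multi-allelic variants are outside the contract and rejected by the
readers. Missing dosages do not occur on the synthetic path; the readers
reject out-of-range values rather than imputing.

# Association scans

Each protein column is log2-transformed and z-scored, then regressed on
`[1, exposure, covariates]` by OLS; the exposure coefficient is reported
with a two-sided p-value from the t distribution with n - p degrees of
freedom (at cohort-scale n the difference from the normal is negligible,
but the contract is fixed). Exposure and covariates are z-scored by default
so scan coefficients are in SD-per-SD units; `standardize_exposure = FALSE`
keeps BMI in kg/m2. Replication requires both Bonferroni significance in
the replication table and directional concordance -- significance with the
wrong sign is `discordant`, concordance without significance is
`concordant_only`.

## Replication power (p95)

For each association, 1000 subsamples of 356 individuals are drawn without
replacement, the model is refit, and the 50th smallest p-value (the
`ceiling(0.05 * reps)`-th order statistic; ties kept as-is in the sorted
multiset) is reported as p95 -- the p-value achievable with 95% probability
at the replication sample size.

A calibration subtlety: when the subsample is a large fraction of the
parent cohort (356 of 996), the subsample p-values are strongly dependent
-- conditional on the data, the subsample z-statistics are approximately
`N(sqrt(f) * z_full, 1 - f)` with `f = n_sub / n`. For a truly null protein
the p95 then has mean ~ 0.08 and SD ~ 0.04 across datasets, not the ~0.05
one would expect from the 5th percentile of independent uniforms. The
order-statistic calibration (p95 ~ 0.05 for a null protein) therefore only
holds when the parent cohort dwarfs the subsample; the package's validation
evaluates it at n = 10000 with n_sub = 356, where the measured mean is
0.047 (SD 0.011), and averages over independent datasets. For real use the
p95 is a per-dataset descriptive quantity, exactly as defined above.

# Tail-effect analysis

Samples are stratified by score percentiles: `lower` holds the
`ceiling(n*p/100)` smallest scores, `upper` the same count of largest
scores, ties broken by sample order (stable sort); an index that would land
in both strata is kept in `lower`, so the strata are always disjoint and
partition the sample at p = 50. Decile summaries use the rank rule
`floor(10*r/n) + 1` (decile sizes differ by at most one; at n = 996 they
are 99 or 100) with normal-approximation 95% confidence intervals.

## Why the tail regression allows per-tail intercepts

The signature quantity is `ratio = beta_tail / beta_full`, the tail-fit
slope over the full-sample slope. There is a sharp constraint on the naive
version of this statistic: if the tail fit pools both tails with a *single*
intercept, then for any odd monotone link `L` and Gaussian score,

```
ratio = (E[s L(s) 1_T] / E[s L(s)]) * (E[s^2] / E[s^2 1_T])  <=  1 / E[s^2 1_T]  ~ 2.28
```

for the 5% tails (`T = {|s| > 1.645}`, `E[s^2 1_T] = 0.439`). No generative
mechanism whatsoever can push the pooled single-intercept ratio above ~2.3,
yet amplification factors of 3-7 are exactly what extreme-score analyses
report. The resolution is that a single shared intercept forces the fit to
absorb the *between*-tail contrast into the slope denominator; the local
slope in the extremes is what the amplification factor means. The default
fit therefore keeps one common slope but allows a separate intercept per
stratum (an upper-tail indicator). Under the hinge link this recovers

```
ratio ~ k / (1 + (k - 1) * (1 - q))
```

which is 3.08 at `k = 4, q = 0.9` and ~3.2 at the default `q = 0.92`. The
default `q = 0.92` places the hinge strictly inside the 5% tails: if the
hinge coincides exactly with the 5% cut (`q = 0.9`), sampling noise in the
two empirical cutoffs mis-assigns boundary samples and biases the tail
slope downward. With a linear link (`k = 1`) the within-stratum slope is
unbiased for the full-sample slope at *every* percentile, so the ratio is
centred at 1 -- the cleaner form of the usual p = 50 identity. The literal
single-intercept pooled fit remains available as
`stratum_intercept = FALSE`; it satisfies the exact identity
`ratio(p = 50) = 1` and is the right choice when the quantity of interest
is the pooled two-tail slope itself rather than the local amplification.

Classification of BMI-associated proteins is three-way and exhaustive:
`gps_associated` (score association below the strict scan threshold), else
`tail_associated` (tail fit p < 0.05 and |ratio| > 3), else `bmi_only`.
Signed ratios are reported; the absolute value is used only in
classification.

# Mendelian randomization

## Instrument selection and harmonization

Instruments require `p < 1e-8` and F-statistic `(beta/se)^2 > 10`, no
confounder association at `p < 1e-8` (applied to both directions), and
greedy LD clumping at `r^2 <= 0.001`: SNPs are visited in ascending
p-value order and accepted only if sufficiently uncorrelated (dosage
correlation from the supplied reference panel) with every accepted SNP
within the window. The clumping window defaults to 10 Mb -- a window value
accompanying `r^2 = 0.001` is conventional but not standardized, so it is a
parameter. Exposure and outcome summary statistics are aligned on the
exposure's effect allele; palindromic SNPs are dropped, swapped-allele
outcome betas are negated, irreconcilable pairs are dropped with a reason.
An empty instrument set is a typed `no_instruments` outcome, not an error,
and propagates as a literal marker into the report.

## Estimators

* **Wald ratio**: `by/bx`, first-order delta-method SE `sy/|bx|` (the
  second-order term adding exposure uncertainty is available via
  `second_order = TRUE`).
* **IVW** (fixed-effect): weighted regression of outcome on exposure betas
  through the origin with weights `1/sy^2`; Cochran's Q on k - 1 df; with
  one SNP it reduces exactly to the Wald ratio. A multiplicative
  random-effects variant (SE inflated by `sqrt(Q/(k-1))` when > 1) is
  behind `random_effects = TRUE`, since both conventions circulate.
* **MR-Egger**: SNPs re-oriented so `bx >= 0`, weighted regression with a
  free intercept; the intercept is the directional-pleiotropy estimate with
  its own test. Constraining the intercept to zero reproduces IVW exactly
  (an algebraic identity of weighted least squares).
* **2SLS**: fitted exposures from the first stage enter the second stage;
  the SE is the classical 2SLS variance with residuals recomputed from the
  actual exposure, t reference on n - p df (whether real analyses used
  normal or robust SEs is typically unstated; the classical choice is
  documented and fixed). The first-stage F for the instrument block is
  recorded and a warning raised below 10.

IVW and Egger report fixed-effect (sigma = 1) standard errors under the
stated weights: when the weights are correct this gives nominal coverage
(validated: 95% CI coverage 92-98% and Egger intercept type-I error
0.03-0.08 over 500 no-pleiotropy simulations with 20 instruments).

## The bidirectional report

Per protein, four cells: 1SMR (2SLS) and 2SMR (IVW) in each direction.
Forward 1SMR instruments BMI with the polygenic score; reverse 1SMR uses at
most the two strongest cis instruments of the protein (ranked by
first-stage association), mirroring the one-or-two-suitable-instruments
situation typical of cis-pQTL analyses. Cells without inputs carry
`not_available`; without usable instruments, `no_instruments`. Direction
calls (`forward`, `reverse`, `both`, `none`) use a per-test Bonferroni
threshold. On 5000-sample synthetic cohorts the report recovers the
generative direction in >= 99% of replicates for the directed regimes and
flags the confounded-null regime in ~0%, while naive OLS on the same
confounded-null proteins is biased ~0.17 SD-per-SD away from zero --
the de-confounding property that motivates MR.

# Biweight midcorrelation screen

`bicor` uses the canonical definition: deviations from the median scaled by
nine times the *unscaled* MAD (no 1.4826 consistency factor), Tukey
biweights `(1-u^2)^2` truncated at `|u| = 1`, correlation of the weighted
deviations. Zero-MAD inputs fall back to Pearson with a warning, matching
reference behaviour. Screen p-values use the t approximation
`t = r sqrt((n-2)/(1-r^2))`, two-sided (one- vs two-sided is unstated in
typical reports; two-sided is the conservative fixed choice). Retention is
the joint rule `|r| > 0.1 AND p < 0.05`, with `*`/`**`/`***` tiers at
0.05/0.01/0.001.

# Numerical choices and degenerate inputs

* Sample SD (n-1) everywhere; exact small-sample contracts follow from it.
* Zero-variance columns raise errors naming the offending column; the scan
  rejects rank-deficient designs listing the collinear columns.
* All OLS paths share one QR-based fitter; `(X'X)^-1` is recovered in
  original column order even when the QR pivots.
* Ties in score ranks are broken by sample order (stable sort); ties in
  p-values are kept as-is in order statistics.
* Exit behaviour of readers: schema violations and out-of-range dosages
  report the offending row/column and fail before any compute.

# Validation problem sizes

The test suite validates: estimator-vs-oracle equality at 1e-10 on 50
random instances per estimator; direction recovery and de-confounding on
200 cohorts of n = 5000; the tail signature on 200 cohorts of n = 10000 per
link (50 score variants and one protein per regime in these runs -- the
analysis is invariant to the variant count, which only sets the score's
granularity); IVW/Egger calibration on 500 summary-statistic simulations;
and p95 calibration at n = 10000 averaged over 5 independent datasets.

# Limitations

The generator validates the *statistical machinery*, not biology: passing
tests show the estimators recover known effects under the generative
assumptions (HWE, linear effects, Gaussian noise, a hinge nonlinearity,
independent covariates). They do not show robustness to assay artifacts,
batch effects, genome-wide LD, population stratification, non-Gaussian
protein distributions, or pleiotropy structures other than the constant
directional term simulated for the Egger test. Real analyses should treat
the MR outputs with the usual caution: instrument validity is an assumption,
and the confounder-exclusion and clumping steps only remove the violations
they can see.
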