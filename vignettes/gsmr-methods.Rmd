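---
title: "Multi-instrument Mendelian randomization by generalized least squares: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instrument Mendelian randomization by generalized least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmrkit)
```

## The estimation problem

Observational associations between a modifiable exposure $x$ (say, BMI in
SD units) and a disease outcome $y$ cannot separate causation from
confounding or reverse causation. Mendelian randomization (MR) uses
genetic variants as instrumental variables: alleles are fixed at
conception, so a SNP $z$ that affects $y$ only through $x$ identifies the
causal effect $b_{xy}$. With GWAS summary statistics from two
non-overlapping samples — per-allele effects $\hat b_{zx}$ (SD units) and
$\hat b_{zy}$ (logOR for disease) with standard errors — each instrument
yields a ratio estimate

$$\hat b_{xy(i)} = \hat b_{zy(i)} / \hat b_{zx(i)},$$

and under a shared causal model every valid instrument estimates the same
$b_{xy}$. `gsmrkit` combines the $m$ per-SNP ratios by generalized least
squares (GLS), propagating the sampling error of **both** GWAS and the
linkage disequilibrium (LD) among instruments:

$$\hat{\mathbf b}_{xy} \sim N(\mathbf 1\, b_{xy},\, \mathbf V), \qquad
\hat b_{xy} = (\mathbf 1' \mathbf V^{-1} \mathbf 1)^{-1}
\mathbf 1' \mathbf V^{-1} \hat{\mathbf b}_{xy}, \qquad
\mathrm{var}(\hat b_{xy}) = (\mathbf 1' \mathbf V^{-1} \mathbf 1)^{-1},$$

tested by $T = \hat b_{xy}^2/\mathrm{var}(\hat b_{xy}) \sim \chi^2_1$.
The diagonal of $\mathbf V$ is the delta-method ratio variance

$$\mathrm{var}(\hat b_{xy(i)}) = b_{xy(i)}^2 \left[
\frac{\mathrm{var}(\hat b_{zx(i)})}{b_{zx(i)}^2} +
\frac{\mathrm{var}(\hat b_{zy(i)})}{b_{zy(i)}^2} -
\frac{\mathrm{var}^2(\hat b_{zx(i)})}{b_{zx(i)}^4} \right],$$

and the off-diagonal entries couple SNP pairs through their LD correlation
$r$ (estimated from a reference genotype panel):

$$\mathrm{cov}(\hat b_{xy(i)}, \hat b_{xy(j)}) \approx
\frac{r\,\sqrt{\mathrm{var}(\hat b_{zy(i)})\mathrm{var}(\hat b_{zy(j)})}}{b_{zx(i)} b_{zx(j)}}
+ b_{xy(i)} b_{xy(j)} \left[
\frac{r\,\sqrt{\mathrm{var}(\hat b_{zx(i)})\mathrm{var}(\hat b_{zx(j)})}}{b_{zx(i)} b_{zx(j)}}
- \frac{\mathrm{var}(\hat b_{zx(i)})\mathrm{var}(\hat b_{zx(j)})}{b_{zx(i)}^2 b_{zx(j)}^2} \right].$$

Setting $i = j$, $r = 1$ recovers the diagonal exactly; the suite verifies
this identity over random parameter draws. True effects inside $\mathbf V$
are replaced by their per-SNP estimates (plug-in) — the only thing
computable from summary data; the consequences are discussed under
limitations.

Because the logOR is free of case-control ascertainment bias, a binary
outcome's $\hat b_{xy}$ is interpretable as the population logOR per SD of
exposure; `logor_to_or()` and `aggregate_effect()`
($\log \mathrm{OR} = \sum_i x_i \log \mathrm{OR}_i$) convert to the OR
scale.

## Assumptions

* **Relevance, enforced**: only instruments with exposure $P \le 5\times
  10^{-8}$ after clumping are used; `gsmr()` refuses (by default) to run
  with fewer than 10 of them. This is not bureaucratic caution: the
  delta-method variance above is a Taylor approximation in
  $\mathrm{se}(\hat b_{zx})/|\hat b_{zx}|$ and can even go negative for
  weak instruments.
* **Exchangeability / no confounding**: alleles are randomized at meiosis;
  instrument selection is exposure-only, never outcome-informed.
* **Exclusion restriction, tested not assumed**: pleiotropic instruments
  (direct SNP-outcome effects) violate it; the HEIDI-outlier filter below
  removes the detectable ones. Instruments that survive may still carry
  small pleiotropic effects — the Egger intercept (`estimate_egger()`) is
  a useful companion diagnostic.
* **Two-sample design**: exposure and outcome GWAS errors are independent.

## HEIDI-outlier filtering

Under the causal model all instruments share one $b_{xy}$, so an
instrument whose ratio deviates is a pleiotropy suspect. For each SNP $i$,

$$d_i = \hat b_{xy(i)} - \hat b_{xy(\mathrm{top})}, \qquad
T_i = d_i^2 / \mathrm{var}(\hat d_i) \sim \chi^2_1,$$

with $\mathrm{var}(\hat d_i)$ assembled from the two ratio variances and
their covariance (same structural formula as $\mathbf V$'s off-diagonal).
SNPs with $P < 0.01$ are removed in a single pass
(`--heidi-iterate` repeats until stable). The *target* is not the top
exposure hit — an extreme exposure association is itself an outlier
candidate — but the strongest exposure association within the **third
quintile** of the $\hat b_{xy}$ ranking, operationalized as the rank band
$(0.4m, 0.6m]$; when that band contains no integer rank (m of 3, say) the
median rank is used, and $p_{zx}$ ties break by distance from the median
$\hat b_{xy}$, then SNP id.

A property worth understanding before interpreting HEIDI output: with the
target chosen by this rule, the $\mathrm{var}(\hat d_i)$ formula *adds the
target's full marginal variance*, but the quintile constraint pins the
realized target close to the consensus ratio, so the formula systematically
overstates $\mathrm{var}(\hat d_i)$ and the test is **conservative**. The
test suite demonstrates both halves: with a randomly chosen target
(no selection) the HEIDI p-values are exactly uniform under a causal null,
while under the quintile rule the removal rate at threshold 0.01 falls well
below the nominal 1% (the acceptance suite measures ~0.1-0.2% at its
simulation scale). Conservatism costs a little power, never type-I error,
and filtering is pure subset selection — retained SNPs' effects are never
modified.

## Conditional analysis (mtCOJO)

To ask whether a risk factor's effect on disease survives adjustment for
other risk factors, the target trait's per-SNP effects are conditioned on
the *genetic values* of $t$ covariate traits using only summary data:

$$\hat b_{zy}\,|\,\hat{\mathbf b}_{xy} = \hat b_{zy} -
\hat{\mathbf b}_{zx}' \hat{\mathbf b}_{xy},$$

where the joint covariate effects come from the marginal (GSMR) estimates
via $\mathbf b_{xy} = \mathbf D^{-1/2} \mathbf R_x^{-1} \mathbf D^{1/2}
\boldsymbol\beta_{xy}$, with $\mathbf R_x$ the genetic-correlation matrix
and $\mathbf D$ the diagonal of covariate SNP-heritabilities. The adjusted
sampling variance is

$$\mathrm{var}(\hat b_{zy}|\hat{\mathbf b}_{xy}) = \mathrm{var}(\hat b_{zy})
+ \hat{\mathbf b}_{xy}' \mathbf V_{zx} \hat{\mathbf b}_{xy}
- 2\, \hat{\mathbf b}_{xy}' \mathrm{cov}(\hat b_{zy}, \hat{\mathbf b}_{zx}),$$

where sampling covariances between traits measured on (partially)
overlapping samples are $c \cdot se_a \cdot se_b$ with $c = \rho\, r_p$
(overlap fraction times phenotypic correlation), supplied in practice as
bivariate LD-score-regression intercepts. Heritabilities, genetic
correlations and intercepts are **configuration inputs** (YAML); LDSC
estimation itself is out of scope here. With no overlap the variance
*inflates* ($+\,\mathbf b'\mathbf V\mathbf b$); with target and covariates
on one sample it deflates ($-$); both special cases are unit-tested. The
adjusted dataset is a valid `.ma` file and feeds straight back into
`gsmr()` — "conditional GSMR".

Covariates are assumed in SD units (the derivation standardizes them). SNPs
missing from any covariate are skipped by default (`missing_action =
"zero"` keeps them unadjusted for the missing covariates); a warning fires
when any $|r_g| > 0.9$, since near-duplicate covariates (systolic and
diastolic blood pressure, say) invite over-correction.

## The synthetic-data generator

The simulator exists so that every pipeline stage is testable without any
external download, and its defaults are the conditions under which the
package's statistical claims are verified: $m = 100$ instruments, MAF
drawn per LD block from $U(0.05, 0.5)$, instruments jointly explaining
$h^2_x = 5\%$ of exposure variance (per-SNP effects $\propto N(0,1)$, so
instrument strength is realistically heterogeneous), causal effect
$b_{xy} = 0.3$, $n = 50{,}000$ per sample, two disjoint samples.

Two generation paths:

* **Individual-level** (`simulate_genotypes()` + `simulate_traits()` +
  `gwas_scan()`): haplotypes within an LD block copy a block "master"
  allele with probability $\sqrt r$, giving Hardy-Weinberg genotypes with
  *exact* exchangeable within-block allele correlation $r$ (blocks share
  one MAF to keep this exact — a deliberate simplification). The exposure
  is genetic value plus noise rescaled to the target heritability;
  quantitative outcomes add the causal and pleiotropic paths plus unit
  noise; binary outcomes are drawn from a logistic model with the
  intercept calibrated to the target prevalence by root-finding (so the
  $b_{xy} \approx \mathrm{logOR}$ check is exact in design), with a
  liability-threshold variant behind `liability = TRUE`.
* **Direct sampling** (`sim_truth()` + `sample_sumstats_direct()`): effect
  estimates drawn from their asymptotic distribution
  $N(\mathbf R \mathbf u,\, \mathbf S \mathbf R \mathbf S)$ on the
  standardized-genotype scale, $\mathbf S = \mathrm{diag}(1/\sqrt n)$ —
  orders of magnitude faster, used for replicate-heavy calibration
  studies.

What the generator does **not** emulate: realistic allele-frequency
spectra and coalescent LD (blocks are exchangeable, real LD decays),
population stratification, assortative mating, imputation noise,
sample-overlap between exposure and outcome GWAS, and genuine
genome-scale SNP counts. Passing tests therefore demonstrate the
estimator's statistical behavior under its own model assumptions, not
robustness to the full messiness of real GWAS.

All randomness flows from a single integer seed; identical seeds give
byte-identical output.

## Numerical and policy choices

* **Stable ratio variance**: the diagonal of $\mathbf V$ is evaluated as
  $se_{zy}^2/b_{zx}^2 + b_{xy}^2(se_{zx}^2/b_{zx}^2 - se_{zx}^4/b_{zx}^4)$,
  algebraically identical to the factorized form but finite at
  $b_{zy} = 0$; the equality is unit-tested.
* **Solving, not inverting**: GLS uses a Cholesky solve of $\mathbf V$.
  Non-invertibility (instruments in high LD) is operationalized as a
  condition number above $10^8$ of $\mathrm{cov2cor}(\mathbf V)$ — the
  correlation structure, because per-SNP ratio variances legitimately span
  orders of magnitude with heterogeneous instrument strength and would
  dominate a raw-$\mathbf V$ condition number. The error names the most
  correlated instrument pair.
* **Clumping**: greedy by ascending $P$, removing neighbours within $\pm$1
  Mb of the index SNP at $r^2 \ge 0.05$ (the $\pm$window reading of "1 Mb
  window"); ties in $P$ break by position then SNP id, making output
  deterministic. Verified against a brute-force oracle on random instances.
* **Allele harmonization**: outcome effects are sign-flipped onto the
  exposure's effect allele, handling swapped and complementary-strand
  codings; palindromic (A/T, C/G) SNPs are aligned by allele frequency
  when informative ($\min(\mathrm{eaf}, 1-\mathrm{eaf}) \le 0.4$) and
  dropped otherwise (kept as coded under `keep_palindromic = TRUE`).
  Aligned frequency differences above 0.2 trigger a strand-error warning.
  These policies are package choices — community convention, not mandated
  by the estimator.
* **LD from a panel**: Pearson correlation of allele counts on
  pairwise-complete individuals (no imputation of missing genotypes),
  columns oriented to the harmonized effect alleles; monomorphic SNPs are
  a named error. PLINK bed/bim/fam is read natively; plain-text matrices
  serve as fixtures.
* **Indeterminate HEIDI variances** ($\mathrm{var}(\hat d) \le 0$, possible
  only for weak instruments) retain the SNP — conservative for filtering,
  since the full $\mathbf V$ still enters the GLS afterwards.
* **p-values** are upper-tail $\chi^2_1$ survival probabilities, reported
  in scientific notation without flooring.

## Known limitations

* **Plug-in GLS attenuation.** Replacing true effects by estimates inside
  $\mathbf V$ makes the GLS weights share sampling noise with the ratios:
  a SNP whose $|\hat b_{zx}|$ fluctuates high gets both an attenuated ratio
  and extra weight. At the default simulation conditions (mean per-SNP
  NCP ~ 50) the suite resolves a systematic attenuation of roughly 3%
  relative at $b_{xy} = 0.3$, shrinking as instruments strengthen; at
  $b_{xy} \le 0.1$ it is below Monte-Carlo resolution. Genome-wide
  significance filtering is the guardrail, not a cure.
* **HEIDI conservatism** under the quintile target rule, as analyzed
  above: expect the realized removal rate of valid instruments to sit well
  below the nominal threshold.
* **Weak-instrument invalidity.** The delta-method variances are
  meaningless for instruments with $|\hat b_{zx}|/se \lesssim 2$; the
  package refuses rather than warns only at the `min_instruments` level,
  so callers overriding `force = TRUE` should know what they are doing.
* Linear, age- and sex-homogeneous effects only; composite exposures
  (educational attainment, say) identify the effect of their genetic
  component.

## Problem sizes used by the test and acceptance suites

Calibration and recovery studies run on the direct-sampling path with
$m$ of 30-100 instruments and $n = 50{,}000$ per sample: 2,000 replicates
for null calibration, 240 per scenario for parameter recovery, 500 for the
HEIDI removal-rate study. The binary-outcome check simulates 40,000
individuals at $m = 30$ once. These sizes keep the full suite under a few
minutes on one CPU while leaving Monte-Carlo error well below the effects
being measured.
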