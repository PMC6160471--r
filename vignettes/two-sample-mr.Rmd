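---
title: "Two-sample Mendelian randomization with lipidmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with lipidmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

## The causal model

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for a modifiable exposure. For variant $j$, let
$\gamma_j$ be its true effect on the exposure (in SD units) and
$\Gamma_j$ its true effect on a binary outcome (log-odds). Under the
instrumental-variable assumptions — the variant is associated with the
exposure, shares no confounder with the outcome, and affects the
outcome only through the exposure — the structural model is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\theta$ is the causal log-odds per SD of exposure and
$\alpha_j$ is the horizontal-pleiotropy effect, zero for a valid
instrument. We observe noisy estimates
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ from an exposure GWAS
and $\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$ from an
independent outcome GWAS. Everything in the package operates on these
summary statistics; no individual-level data are used.

The estimators differ in what they assume about $\alpha_j$:

- **IVW** assumes $\alpha_j = 0$ for all $j$. It is the
  inverse-variance-weighted average of the per-variant ratios
  $\hat\beta_{Yj}/\hat\beta_{Xj}$, equivalently the zero-intercept
  weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with
  weights $\sigma_{Yj}^{-2}$.
- **MR-Egger** allows directional pleiotropy that is independent of
  instrument strength (the InSIDE condition): the regression intercept
  estimates the mean of $\alpha_j$ and the slope remains a consistent
  estimate of $\theta$. The intercept test is the package's test for
  unbalanced pleiotropy. The price is substantially lower precision,
  which is why a null Egger estimate with a tight IVW signal calls for
  caution rather than celebration.
- **Weighted median** tolerates arbitrary $\alpha_j$ on variants
  carrying up to half the total weight. Note that its finite-sample
  behaviour under contamination depends on the sampling noise of the
  valid ratios: one-sided invalid instruments shift the estimate by a
  quantile of the *valid ratio distribution*, which shrinks with the
  per-variant standard errors, not with $J$ alone. The package's tests
  therefore check the breakdown property at small per-variant noise.

## Harmonization

Exposure and outcome tables are joined on rsid and both effects are
expressed for the exposure-increasing allele. The rules, in order of
precedence:

1. variants absent from the outcome table are excluded (no
   proxy-variant search is attempted — an unavailable variant is simply
   logged, which also covers the occasional consortium variant that has
   no usable proxy);
2. outcome alleles must match the exposure pair directly or after a
   swap (beta negated, frequency complemented); anything else is
   flagged as a multi-allelic conflict. Indels are matched by exact
   string or swap only — no strand-flip inference;
3. palindromic variants (A/T, C/G) are kept only when both studies
   report effect-allele frequencies on the same side of 0.5 and the
   minor-allele frequency is at most `maf_ambiguity_limit` (default
   0.42, the conventional cut) in both; otherwise strand orientation is
   genuinely ambiguous and the variant is dropped;
4. a cross-study effect-allele-frequency gap above `freq_tolerance`
   (default 0.20) flags a probable allele-labelling inconsistency.

Both thresholds are configurable because the field has no universal
values; 0.42 and 0.20 are deliberately permissive defaults that drop
only clearly unresolvable variants. Every input variant lands in
exactly one of retained/excluded, and the harmonization log reconciles
the counts.

## Instrument selection

For a multi-lipid panel the *comprehensive* instrument for one lipid is
every variant with $p < 5\times10^{-8}$ for that lipid; the
*restrictive* instrument removes variants with $p < 10^{-3}$ for either
of the other two lipids, trading power for specificity when lipid
fractions share loci. For cis drug-target regions, candidates are
ranked by ascending p-value and accepted greedily while their squared
correlation with every accepted variant stays below `r2_max`
(default 0.4). P-value ties are broken by rsid so repeated runs give
identical sets. The gene window (default ±100 kb) is carried as
metadata only: candidate lists are inputs, and the package does not
recompute them from coordinates.

Moderate residual correlation among the pruned cis variants is modelled
explicitly: the correlated IVW/Egger estimators use generalized least
squares with covariance $\Omega_{jk} = \sigma_{Yj}\sigma_{Yk}\rho_{jk}$
built from the *signed* LD correlations. The sign convention matters —
$\rho$ refers to a specific allele coding, so when harmonization flips
a variant to its exposure-increasing allele the pipeline flips the
corresponding rows and columns of the LD matrix.

## Heterogeneity and outlier diagnostics

**Q′.** First-order Cochran statistics treat the exposure effects as
known (the NOME assumption). The Q′ statistic instead minimizes

$$Q(b) = \sum_j \frac{(\hat\beta_{Yj} - b\,\hat\beta_{Xj})^2}
                     {\sigma_{Yj}^2 + b^2\sigma_{Xj}^2}$$

over $b$, propagating uncertainty in both numerator and denominator of
the ratio, and refers the minimum to $\chi^2_{J-1}$. The minimization
is a bounded one-dimensional search bracketed at ten times the IVW
estimate around it (widened once, then declared non-convergent) with
tolerance $10^{-10}$; the objective is smooth and unimodal in practice,
so this is ample.

**MR-PRESSO.** The global test measures the weighted residual sum of
squares of each variant around leave-one-out IVW regression lines and
compares it with parametric simulations under the no-pleiotropy null;
the per-variant outlier test compares each variant's observed residual
distance with its own simulated distribution. Empirical p-values use an
add-one correction, so the smallest attainable p is $1/(n_{sim}+1)$ —
with the default $n_{sim} = 1000$, significance at 0.05 is always
attainable and p-values are never zero. The workflow is: global test;
if $p < 0.05$, flag outliers at per-variant $p < 0.05$ and re-estimate
IVW without them; retest heterogeneity. The per-variant threshold is
deliberately unadjusted for multiplicity (a Bonferroni-style threshold
can be passed explicitly); with 20–40 instruments this costs a few
false flags per hundred analyses but catches moderate outliers that a
corrected threshold would miss. The MR-PRESSO distortion test is not
implemented. One caveat the test suite documents: in data containing a
strong outlier, the leave-one-out slopes for the *other* variants are
themselves contaminated, so the false-positive rate among valid
variants in outlier-bearing data runs slightly above nominal; the
calibration check is therefore performed under the clean null.

## Power

For a case-control outcome with $N$ samples and case fraction $K$, the
approximate standard error of the causal log-odds is
$1/\sqrt{N K (1-K) r^2}$, with $r^2$ the exposure variance explained by
the instrument, giving the usual two-sided normal power. The inverse
problem (minimum detectable OR at target power) is solved by bisection
on the log-odds scale to $10^{-6}$. These are asymptotic
approximations: they match empirical IVW rejection rates to within a
few percent when instrument strength is high, and the match is part of
the acceptance checks. Note that $r^2$ must describe the instrument
actually used; with it unknown, power statements should be treated as
indicative.

## The synthetic-data generator

The generator emulates the two-sample summary-statistic setting at the
scale of the large lipid and breast-cancer consortium meta-analyses
(defaults: 188,577 exposure samples; 122,977 cases and 105,974
controls), which makes synthetic standard errors and instrument
strengths realistic for this class of study:

- allele frequencies uniform on (0.05, 0.95);
- true exposure effects $\gamma_j \sim N(0.08, 0.03^2)$, clipped below
  at 0.01 to keep the lipid-increasing orientation meaningful — 0.08
  per SD is typical of genome-wide-significant lipid loci at this
  sample size;
- standard errors from the standard GWAS approximations
  $\sigma_{Xj} = 1/\sqrt{2p_j(1-p_j)n}$ and, for case-control outcomes,
  the effective sample size $n_{cases}n_{controls}/(n_{cases}+n_{controls})$;
- pleiotropy laws: none, balanced ($N(0, s^2)$), directional
  ($N(\mu, s^2)$, defaults $\mu = 0.05$, $s = 0.01$), or a few spiked
  outliers expressed in units of the variant's outcome standard error;
- multi-lipid panels with planted variant classes (lipid-specific,
  pairwise-shared, shared by all three) mixed through a 3×3 loading
  matrix, so selection logic is checkable against known truth;
- cis LD blocks with autoregressive correlation
  $\rho_{jk} = r^{|j-k|}$, positive-definite by construction, with
  betas drawn jointly under the matching covariance.

One global seed drives everything through deterministic per-table
sub-seeds, so regenerating one table never perturbs another; within a
table, changing the variant count redraws that table. What the
generator does **not** emulate: realistic allele-frequency spectra,
genome-wide LD structure, winner's curse in instrument discovery,
sample overlap between the two studies, and population stratification.
Passing tests on synthetic data therefore validate the estimators and
plumbing under the stated model, not robustness to those additional
features of real consortium data.

## Numerical choices

- IVW defaults to multiplicative random effects,
  $\phi = \max(1, \sqrt{Q/(J-1)})$, matching the convention of the
  standard MR software; $\phi$ is always reported so fixed-effect
  results are recoverable, and a fixed-effect mode is selectable.
- All confidence intervals use the normal 1.96 quantile regardless of
  $J$, for cross-method consistency.
- Weighted-median weights are inverse first-order ratio variances;
  bootstrap default 1000 replicates; the RNG seed is a required
  argument everywhere randomness enters, and estimators restore the
  caller's RNG state.
- $\Omega$ is ridge-conditioned by $10^{-10}\times$ its mean diagonal
  before Cholesky factorization; solutions go through the
  factorization, never an explicit inverse (the explicit-inverse path
  exists only as an independent test oracle). The ridge bounds the
  agreement between correlated and plain estimators at identity LD to
  about $10^{-10}$ relative error, which the tests acknowledge with an
  $10^{-8}$ tolerance.
- Degenerate inputs fail loudly: empty instrument sets, a single
  variant passed to Egger, non-positive-definite $\Omega$ (the error
  advises stronger pruning), all-variant outlier flags.

## Pipeline decision rule

The full-study drivers mark (never filter) result cells that a
practitioner would consider credible: same direction of effect across
IVW/Egger/weighted-median, nominal IVW significance, Egger CI
overlapping the IVW CI (the "agreement in magnitude" reading), Egger
intercept $p > 0.05$ and heterogeneity $p > 0.05$. "Agreement in
magnitude" has no canonical quantitative form; CI overlap is the
package's operationalization, chosen because it scales with each
method's own precision. Errors are isolated per analysis cell — a
degenerate set for one lipid-outcome pair (for example a four-variant
restrictive triglyceride instrument) cannot abort the rest of the run.

## Problem sizes used in validation

The test and acceptance suites run 1000-replicate recovery and
calibration studies at $J = 44$ and $J = 20$, 200-replicate
pleiotropy-recovery studies, 100-replicate MR-PRESSO power studies with
$n_{sim} = 1000$, and a 185-variant full-pipeline study with planted
restrictive counts of 44/28/4 — sizes chosen to hold Monte-Carlo error
comfortably inside the asserted bands while keeping a full run in the
tens of seconds on one core.
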