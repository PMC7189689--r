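---
title: "Inferring XCI methylation patterns and sex-specific methylation aging on the X chromosome"
author: "methylXCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring XCI methylation patterns and sex-specific methylation aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylXCI)
```

## The problem

DNA methylation on the X chromosome is shaped by X-chromosome inactivation
(XCI): in female somatic cells one X is epigenetically silenced, and
silencing is maintained in part by dense promoter methylation on the
inactive X. A CpG subject to XCI is therefore roughly hemi-methylated in
females (one methylated, one unmethylated allele, beta near 0.5) but
unmethylated in males, while a CpG escaping XCI is lowly methylated in
both sexes. This sex structure is why X-linked CpGs are routinely dropped
from epigenome-wide studies of aging: a joint analysis of the sexes
confounds XCI with every other signal.

methylXCI implements a sex-stratified analysis of 450K-array beta values
for this setting: within-sex normalization, inference of XCI-related
methylation patterns from two independent twin cohorts, per-sex
age-association modelling, and replication/validation statistics across
cohorts — together with a twin-cohort simulator that generates data with
exactly the structure the models assume, plus the ground truth needed for
parameter-recovery tests.

## The models

**Sex differences.** For each CpG, the methylation M-value
($M = \log_2 \beta/(1-\beta)$) is regressed on sex with a random intercept
per twin pair:
$$M_{ij} = \beta_0 + \beta_1\,\mathrm{sex}_j + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \sigma_u^2),\ \varepsilon \sim N(0, \sigma_e^2),$$
with $\mathrm{sex}$ coded 0 for males and 1 for females, so $\beta_1 > 0$
means females are the more methylated. Because twins are like-sex, sex is
constant within a pair and the REML fit decomposes exactly: within-pair
contrasts estimate $\sigma_e^2$ and a between-pair regression of pair
means on sex carries all the information about $\beta_1$. `fitSexDifference`
exploits this to fit every CpG in closed form (falling back to a 1-D
profiled REML when per-probe missingness unbalances the pairs), which is
what makes a 10,000-replicate permutation test practical. The closed form
is verified against `lme4`/`lmerTest` in the test suite.

**Multiplicity for the sex test.** Significance is controlled by a
permutation family-wise error rate: sex labels are permuted across twin
pairs (preserving the male:female pair ratio), the full per-CpG test is
rerun, and each replicate's minimum p-value is recorded. A probe's FWER is
the fraction of replicate minima strictly below its observed p-value,
divided by $K$ with no +1 correction. Each probe is compared against the
pooled list of per-replicate minima (the minimum across all probes), which
is what makes the quantity a family-wise rate; the permutation reuses the
identical fitting path as the observed data, so the minima are
exchangeable with the observed statistic under the null.

**Pattern classification.** With per-cohort FWERs and per-sex mean betas
from two cohorts, each CpG gets the first matching label of: **A**
(female-hypermethylated in both cohorts; inferred subject to XCI), **D**
(male-hypermethylated in both), **ONE_COHORT** (significant in exactly
one cohort — either one; the class is deliberately symmetric),
**B** (no sex difference and all four per-sex, per-cohort means
below 0.25; escaping XCI), **C** (no sex difference and all four means
above 0.75), **REST** otherwise. The direction gates on A and D are
explicit because significance alone does not say which sex is the more
methylated; probes significant in both cohorts with discordant directions
fall to REST and are counted in a message. The beta cut-offs are applied
to all four per-sex-by-cohort means — the strictest reading of "in both
sexes, in both cohorts".

**Age association.** Separately per sex, each CpG's M-value is regressed
on age and the six blood cell-type proportions, with random intercepts
for array barcode (sentrix ID), array position and — in twin cohorts —
twin pair:
$$M = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{CD8T} + \dots +
\beta_7\,\mathrm{Gran} + (1\,|\,\mathrm{sentrixID}) +
(1\,|\,\mathrm{position}) + (1\,|\,\mathrm{pair}).$$
$\beta_1 > 0$ is an age-associated methylation gain (hypermethylation),
$\beta_1 < 0$ a loss. Fits use `lme4` REML; since the fixed design is
shared across CpGs, one model is built and every further probe is a
`refit()` with a new response. Significance per (cohort, sex) analysis is
a Benjamini–Hochberg FDR over all CpGs tested in that analysis.

**Replication and validation.** Significant sets from the two discovery
cohorts are intersected per class (both sexes / male-only / female-only)
and the overlap is tested with the upper-tail hypergeometric probability
$P(X \ge k)$ over the post-QC universe of $N$ CpGs, evaluated in log
space so magnitudes near $10^{-300}$ remain exact. The tail includes the
observed overlap ($\ge k$): that is the universal enrichment convention,
and a tail excluding $k$ would be guaranteed smaller than the reported
probability for the identical observation. Replicated CpGs are then
looked up in an independent third cohort whose own FDR must have been
computed over *all* its tested chromosome CpGs; a sex-independent
("both") CpG validates only if it passes in both sexes of the third
cohort (an either-sex rule is available via `bothRule`), and sign
consistency with both discovery cohorts is reported as a separate subset
because validation-by-FDR and direction agreement are logically distinct.

## Quality control and preprocessing choices

* QC order is blacklist → detection-p masking → missingness filter.
  Cross-reactive and polymorphic probes are consumed as annotation flags
  (deriving the blacklist is out of scope); calls with detection
  p > 0.01 become missing; probes with **more than** 5% missing calls are
  dropped (strict inequality: 1 masked call in 20 samples is retained,
  2 are dropped). QC is idempotent, and all downstream fits are
  complete-case per probe.
* `normalizeWithinSex` is a full quantile normalization applied within
  male and within female columns separately, so the bimodal male and
  trimodal female X-chromosome distributions are never forced onto a
  common shape. It is a deliberate simple stand-in for probe-subset
  normalizers; cohorts normalized upstream can skip it.
* `balanceSexes` equalizes the sexes by age-matching at twin-pair
  granularity: the larger sex's pair whose mean age is closest to the
  smaller sex's mean age is taken repeatedly until the counts match, with
  ties broken by lexicographically smaller pair id. Operating on whole
  pairs preserves the twin random-effect structure; singleton "pairs"
  (unrelated cohorts) reduce to sample-level selection.
* Chromosome selection is a plain filter on the probe annotation
  (`filterChromosome`), so an autosomal comparison chromosome is
  configuration, not special-cased code.

## The simulator and its defaults

`generateCohort` is the exact inverse of the fitted models: M-values are
assembled additively from a pattern-by-sex baseline, a per-pattern age
slope applied to age centred at the cohort mean, per-CpG random
intercepts for twin pair, sentrix ID and sentrix position, a per-CpG
cell-composition term over Dirichlet-distributed blood proportions, and
Gaussian residual noise; beta is the inverse logit. Noise lives on the M
scale (a logit-normal beta) precisely so that the generator and the
analysis models agree. Random intercepts are drawn per CpG and grouping
level — they are realizations of the mixed model's random effects, not
per-sample constants; a shared per-sample draw would correlate every
CpG's error with the same chance age–batch confounding and destroy the
null calibration the tests verify.

Defaults describe the three-cohort design of a two-discovery-plus-
validation twin study of older adults: cohort 1 with 113 like-sex pairs
per sex aged 56–79, cohort 2 with 36 pairs per sex aged 74–88, and a
validation cohort of 190 unrelated individuals per sex aged 78–91
(singleton pair ids). Pattern CpG counts default to one twentieth of the
published X-chromosome pattern sizes (A 215, B 32, C 147, D 8, REST 103,
505 CpGs in all) to keep recovery experiments fast while preserving the
class imbalance. Other defaults, chosen once as plausible for whole-blood
450K data: baseline betas A = 0.05/0.45 (male/female), B = 0.10,
C = 0.85, D = 0.65/0.35; age slopes −0.02 M/yr for pattern B and
+0.02 M/yr for pattern C (the qualitative direction reported for escaping
and constitutively methylated sites) and 0 elsewhere; residual SD 0.4 M;
pair intercept SD 0.3 M (a within-pair correlation near 0.35); batch SD
0.15 M over 8 chips; position SD defaults to half the batch SD over the
12 chip positions (neither variance is quantified anywhere, and position
effects are plausibly smaller than chip effects); cell-composition
coefficients N(0, 0.5²) per CpG against a granulocyte-dominant Dirichlet
(concentration 50); detection failures missing-completely-at-random at
rate 0.002. Ages are uniform on the cohort range and co-twins share age
exactly; 95% of pairs are monozygotic, matching the heavily-MZ make-up of
the twin cohorts this design mirrors. ONE_COHORT sites carry their sex
effect only in cohort 1's generating model (their mechanism is otherwise
unspecified); the two sexes share a residual SD by default, with
sex-specific variability left to the configuration.

What the simulator does **not** emulate: Infinium I/II probe chemistry
and color-channel effects, SNP-under-probe artefacts, cell-type-specific
or skewed XCI, non-uniform age distributions, and any dependence of
missingness on signal. Passing recovery tests therefore demonstrate that
the estimators recover the parameters of the assumed generating model —
not that real 450K data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Beta values are clipped to $[10^{-6}, 1-10^{-6}]$ before the logit so M
  stays finite; the inverse uses $1/(1+2^{-M})$ for stability at large
  $|M|$.
* In the balanced sex-difference fit, the pair-variance REML estimate is
  truncated at zero when the between-pair mean square falls below the
  within-pair bound, and the residual variance is then pooled across both
  strata; the test df follows the information actually used (pairs − 2,
  or the pooled df under truncation). Probes with no variance at any
  level are flagged and get a missing p-value.
* The age model drops grouping factors with a single level, flags a fit
  whose variance components all sit exactly on the zero boundary and
  replaces it with the identical OLS solution, and falls back to OLS with
  a flag when `lme4` fails outright. Wald t-tests use residual df
  (n − 7). Note that at a *true* zero variance, REML estimates stay
  positive with non-trivial probability in finite samples, so mixed and
  OLS p-values coincide exactly only for the collapsed fits and converge
  for the rest — the tests assert precisely this.
* The six cell proportions are compositional (they sum to 1), so
  granulocytes serve as the reference category; the age slope is
  invariant to this reparameterization.
* Pearson chi-squared statistics are computed from
  $\sum (O-E)^2/E$ directly, so a table with an empty row or column still
  yields a statistic with the nominal df and a warning, per the analysis
  contract (`chisq.test` is the cross-check in the tests).
* The hypergeometric tail is evaluated through `phyper(log.p = TRUE)`;
  zero-size sets give $k = 0$ and a tail of 1.
* One integer seed drives everything: per-cohort and per-purpose
  sub-seeds are split deterministically from it, so a study is
  bit-reproducible and two cohorts with different labels are independent.

## Problem sizes used by the tests and acceptance script

Recovery and calibration runs use the full default study for pattern
classification (505 CpGs; 452 + 144 discovery samples; permutation
K = 500), ten 60-sample cohorts of 100 null CpGs at K = 200 for FWER
control, 200 CpGs at 100 samples for age-slope recovery, and 500 pooled
null CpGs for the age model's type-I error; these sizes give Monte-Carlo
error comfortably inside the asserted bands while keeping a full run in
the low minutes on a single core.

## Known limitations

* The permutation FWER pools minima across probes; per-probe permutation
  distributions are a different (and far costlier) multiplicity scheme.
* Wald t inference for the age model is mildly anticonservative when the
  pair-level information is small relative to n; the empirical size at
  0.05 sits near 0.06 in the test conditions.
* `validateInThirdCohort` assumes the third cohort was analysed with the
  same model family; it does not re-harmonize effect scales across
  normalization schemes.
* The simulator's Dirichlet cell model draws composition independently of
  age and sex, so it cannot exercise confounding between aging and
  cell-composition drift.
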