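---
title: "Models, simulation design and numerical choices in methylMR"
author: "methylMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation design and numerical choices in methylMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylMR)
```

# Scope

methylMR implements the analytical chain that leads from a multi-cohort
epigenome-wide association study (EWAS) of body mass index to causal
classification of the associated CpGs: per-cohort association models,
sample-size-weighted meta-analysis and replication, a composite
methylation measure, methylation–expression–BMI triangulation, and
bidirectional plus two-step Mendelian randomization (MR). Everything is
exercised against a synthetic multi-cohort generator with a known causal
ground truth, so each stage is validated by parameter recovery rather
than by eyeballing. This vignette records the models, the generator's
assumptions, the parameters that matter, and the choices we made where
the design was genuinely open.

# The per-cohort EWAS model

The primary orientation (`style = "methOutcome"`) regresses
inverse-normal-transformed methylation on BMI:

$$\mathrm{INT}(\beta_j) = \gamma_0 + \gamma_1\,\mathrm{BMI}
  + \boldsymbol{\gamma}'\mathbf{c} + \boldsymbol{\delta}'\mathbf{s} + e$$

where $\mathbf{c}$ are age, sex and optionally smoking, and $\mathbf{s}$
are surrogate variables. The alternative orientation
(`style = "residualOutcome"`) carries forward a batch-adjusted
logit-scale residual as the outcome. Both report the BMI term, so
directions are comparable across cohorts even when coefficient scales
are not — which is exactly why the meta-analysis combines only
(p, direction, n).

Open choices and how we resolved them:

* **Inverse-normal transform.** Rank-based, $\Phi^{-1}((r-0.5)/n)$ with
  average ranks for ties. The offset convention is not standardised in
  the field; $(r-0.5)/n$ is the symmetric choice (a two-way tie maps to
  exactly 0) and is frozen in the tests.
* **Family relatedness.** Approximated by CR1 cluster-robust (sandwich)
  standard errors over `family_id`, with $G-1$ degrees of freedom,
  rather than a linear mixed model. The simulator generates unrelated
  samples, so the contract being bought here is "valid SEs under
  within-family correlation", which the sandwich provides; a full LMM
  (e.g. via lme4) is a straightforward extension point.
* **The batch-residual orientation.** Where the source design speaks of
  a logistic-link GLM residual for a bounded outcome, we logit-transform
  the beta values, regress on batch indicators, and carry the residuals
  forward. This preserves the intent (batch-adjusted bounded outcome on
  an unbounded scale) without inventing an unstated quasi-likelihood.
* **Missing data.** Complete-case per CpG; `n` is recorded per record.
* **Saturated fits.** A numerically perfect association drives the
  residual variance to ~0; the p-value is floored at
  `.Machine$double.xmin` so downstream log/quantile transforms stay
  finite.

## Surrogate variables

`estimateSurrogateVariables()` returns the top-$k$ left singular vectors
of the covariate-residualised, per-CpG-standardised M-value matrix.
Because the residualisation precedes the SVD, the scores are orthogonal
to the covariate space by construction (asserted to 1e-8 in tests). This
is deliberately the principal-component core of surrogate-variable
analysis, not the iteratively reweighted full algorithm: the simulated
confounding is linear-factor confounding, and the tests demonstrate the
property that matters — adding the factors strictly deflates the genomic
inflation of a confounded null EWAS. Note that $k$ must cover the
confounder dimension but not exceed it. In the reference world the
confounder dimension is exactly 3 — one batch contrast plus two cell
factors — and that is the pipeline default. Both directions of error
are real and observable here: with $k = 2$ the leading axes can latch
onto batch structure and leave the BMI-coupled cell factor unadjusted
(and because factor loadings are shared across cohorts, that residual
confounding *replicates*); with $k = 4$ the extra axis is typically the
aggregate BMI-signal direction spanned by the causal and reactive CpGs
themselves — the residualisation protects age and sex but not BMI — and
adjusting for it regresses out true signal. Iteratively reweighted
surrogate-variable estimation would soften this trade-off; the
principal-component core makes it explicit instead.

# Meta-analysis, inflation and replication

Per CpG, $z_i = \mathrm{sign}_i\,\Phi^{-1}(1-p_i/2)$ and
$z = \sum_i \sqrt{n_i}\,z_i / \sqrt{\sum_i n_i}$ — the METAL
sample-size scheme with $w_i = \sqrt{n_i}$ (the cited method's standard
convention; the weighting formula is not printed in the source design,
so the convention is frozen here and tested via the $\sqrt{k}$ scaling
identity). p-values below 1e-300 are clamped before quantile conversion
and |z| is capped at 38; both constants are documented in the code.

The genomic inflation factor is $\lambda =
\mathrm{median}(z^2)/0.4549364$. At $m = 2000$ tests the median itself
has sampling SD ≈ 0.05, so λ bands of ±0.1 are meaningful for a pooled
suite-level estimate but would be violated by individual small
replicates about once in three runs purely by sampling noise — the
acceptance suite therefore asserts the band on the pooled null z-set
while still checking per-replicate hit counts.

Replication: the gate is $\alpha$ divided by the number of CpGs taken
forward (recomputed at run time, never hard-coded), a CpG replicates
only if the replication meta-analysis passes that gate *with the
discovery direction*, and per-cohort pass flags are reported alongside.
A CpG absent from one replication cohort stays in the meta-analysis over
the cohorts that do carry it.

# The composite methylation measure

Greedy pruning scans CpGs in order of increasing discovery p-value and
retains a CpG iff its absolute Pearson correlation with *every* retained
CpG is below the threshold (default 0.7) — keeping the more significant
member of each correlated clique, as "nonredundant in order of
decreasing significance" implies. The score is
$\sum_j \beta_{ij} w_j$ with signed discovery effect sizes as weights,
standardised with the sample SD ($n-1$); the weight source is
configurable because the design applies "cohort-specific" effect sizes
without fixing the cohort — the pipeline uses the first discovery
cohort. Deciles are assigned by score rank with stable-order
tie-breaking (raw vs standardised scores have identical ranks, so the
distinction is moot); bin sizes differ by at most one. Odds ratios per
SD are Wald-based from age- and sex-adjusted logistic models of obesity
(BMI ≥ 30) and overweight (25–29.9) against BMI < 25; perfect separation
is flagged and the CI reported as unbounded rather than fabricated.

# Expression triangulation

For each replicated CpG with an annotated gene, expression is regressed
on methylation (age, sex, batch adjusted) and the partial R² of the
methylation term, $t^2/(t^2+\mathrm{df})$, is reported; the
expression–BMI leg mirrors the same covariate set (the minimal symmetric
assumption, since that model's covariates are not printed in the source
design). The three-way gate is a pure conjunction — CpG in the
replicated set, CpG–expression p below Bonferroni over tested pairs,
expression–BMI p below Bonferroni over unique genes — with all
thresholds derived from the counts at run time. No sign-consistency is
forced across the triangle: real tables of this kind contain mixed sign
patterns.

# Mendelian randomization

* **Instrument selection.** `scanCisMeqtl()` fits logit-scale
  methylation on each SNP dosage within ±500 kb (inclusive) and returns
  the lowest-p SNP; ties break to the smaller distance, then the
  lexicographically smaller ID, so results are deterministic.
* **Estimator.** Two-stage least squares with the standard variance
  correction (stage-2 residuals recomputed with the observed exposure).
  For a single instrument this equals the Wald ratio of the two reduced
  forms — asserted to 1e-8 on 1000 random datasets — and the stage-1 F
  equals the square of the stage-1 t. The delta-method Wald-ratio SE is
  also available with and without the NOME simplification.
* **Exposure scale.** Exposures are standardised to sample SD units
  before stage 2, so causal effects read "per SD of methylation
  (or expression)".
* **Weak instruments.** Flagged at F < 10, never dropped: the reference
  analysis reports its instrument strength (F ≈ 26 for the genetic risk
  score) rather than filtering on it.
* **Genetic risk score.** $\sum_s w_s d_{si}$, standardised. Up to 20%
  of weight SNPs may be missing (score renormalised by the available
  absolute-weight sum, with a warning); more is an error.
* **Two-step MR.** Step 1 is the association of the meQTL with the
  mediator gene's expression; step 2 instruments expression with an
  eQTL required to satisfy dosage r² < 0.2 against the meQTL ("largely
  independent" made concrete and configurable).
* **Conditional sensitivity.** Attenuation is
  $(|t| - |t_{\mathrm{adj}}|)/|t|$ on the EWAS statistic after adding
  the top meQTL dosage as a covariate. The metric is defined on |t|
  because the source design states percentages without a formula;
  negative values (precision gain from conditioning on a true meQTL,
  typically a few percent) are reported as-is, not clipped.

# The synthetic multi-cohort world

`simulateMultiCohort()` draws one shared generative law — annotation,
causal roles, true effect sizes, confounder loadings, MAFs, GRS
weights — and then independent per-cohort realisations, in causal
order: genotypes → causal/null methylation → expression of causal-linked
genes → BMI → reactive methylation → remaining expression. Methylation
lives on the natural-log logit scale (values stay in [0,1] after the
inverse transform, and genetic effects are near-linear in the 20–80%
methylation band where most CpGs sit); the clipping constant for the
logit is 1e-6.

The default configuration is the package's reference world, chosen once:

* **Cohort structure.** Five cohorts of 2000 samples (two discovery,
  three replication in `runPipeline()`), mirroring a
  discovery-plus-external-replication design at desk scale.
* **Demographics and BMI.** Ages 50–85, ~50% female, ~10% smokers;
  BMI intercept 28 with small demographic effects and residual SD 4,
  landing cohorts near 27–28 ± 4.5–5 kg/m² — the range reported for
  older-adult cohorts in this literature.
* **Causal architecture.** 200 CpGs: 5% causal for BMI at 1.0 kg/m² per
  SD methylation, 8% reactive at 0.03 SD per kg/m² (16 reactive CpGs of
  200, echoing the reported 16-of-83 downstream fraction), the rest
  null. Each non-null CpG has a cis-meQTL within 100 kb (fixed
  magnitude 0.5 logit units per allele, random sign) and a linked gene
  (methylation→expression −0.3 SD/SD, predominantly inverse as
  observed); decoy SNPs fill the ±500 kb windows so the top-SNP scan is
  non-trivial.
* **Polygenic instrument.** 97 GRS SNPs contributing 0.8 (kg/m²)² of
  BMI variance (~2.7% — the GIANT-scale fraction), which yields stage-1
  F in the tens at n ≈ 2000, bracketing the reported F = 26.
* **Confounding.** Two latent cell factors loading on a random 30% of
  CpGs plus per-cohort batch offsets (scale 0.4), with the first factor
  also shifting BMI by 0.5 kg/m² per SD — giving surrogate-variable
  estimation something real to remove.
* **Extra knobs.** `exprToBmiEffect` (default 0) closes the
  meth→expr→BMI mediation chain for two-step-MR recovery studies, and
  `cellBmiEffect` makes the confounder's path into BMI explicit. The
  *global null* used for calibration sets every effect **and**
  `confoundingSd` to zero: shared factor structure correlates tests
  across CpGs, and calibration checks (KS uniformity, λ bands, Bonferroni
  hit counts) presuppose independent tests.

What the generator does *not* emulate — and hence what a green test does
not establish: probe-level microarray artifacts (detection failures, dye
bias, cross-hybridisation), family/population structure (samples are
unrelated; the cluster-robust machinery is exercised on labels, not on
true relatedness), imputation uncertainty, linkage disequilibrium between
instruments and decoys (dosages are drawn independently), and non-linear
or interaction-driven confounding. Results on real cohort data depend on
preprocessing choices the package deliberately leaves out of scope.

# Degenerate inputs and numerical policy

* Cohorts need n ≥ covariates + 2; smaller n is refused with a message.
* Perfect collinearity is an error naming the offending columns.
* Zero-variance CpGs are excluded from pruning with a warning; a
  zero-variance score or constant instrument is an error.
* Monomorphic instrument SNPs raise undefined-instrument errors.
* All thresholds (discovery, replication, expression legs) are derived
  from α and counts at run time.
* Every stochastic result is a pure function of `SimConfig@seed`; the
  pipeline bundle is byte-reproducible, which the tests assert by
  hashing the written TSVs.

# Known limitations

Power at desk scale is intentionally modest: forward/reverse MR at
n = 2000 separates causal from reactive CpGs in aggregate (flag-rate
properties) but individual-CpG classification is noisy, exactly as in
the population-scale analyses this package mirrors. The reverse-MR
power example in the operation documentation requires a deliberately
strong GRS; with the GIANT-scale default the per-CpG power is low and
the package reports it honestly rather than inflating instrument
strength. Trans-tissue QTL lookups are represented as summary-statistic
inputs, not live queries; pleiotropy-robust multi-instrument estimators
(MR-Egger, weighted median) and LD-aware clumping are out of scope.
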