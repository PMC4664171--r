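---
title: "Mapping cis-meQTLs at osteoarthritis risk loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-meQTLs at osteoarthritis risk loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlscan)
library(dplyr)
```

## The scientific question

Most osteoarthritis (OA) susceptibility variants are non-coding, and the
working hypothesis is that they act by regulating gene expression, in some
cases through DNA methylation. A methylation quantitative trait locus
(meQTL) is a variant whose genotype correlates with methylation at a nearby
CpG site. `meqtlscan` implements a targeted cis-meQTL screen for a panel of
OA association signals in cartilage: for each index SNP it asks whether
methylation at any CpG within the surrounding region tracks the number of
risk alleles a patient carries, then replicates candidate hits with an
independent assay technology and asks whether the methylation signal
propagates to gene expression.

The unit of data is a cohort: a sample sheet (disease status OA/NOF, joint,
sex), a minor-allele dosage per sample per index SNP, and a matrix of
methylation beta-values (the methylated fraction at a CpG, in [0, 1]) over
the CpG probes of a 450k-style array.

## The model

### Analysis windows

Each locus is scanned inside a window centred on its index SNP. The window
starts at 1 Mb and is enlarged in 0.5 Mb steps until it contains the whole
LD block of the signal (all variants with r² > 0.8 with the index SNP),
because the causal variant could be anywhere in that block. On the built-in
16-locus OA panel this yields 1 Mb for 15 loci and 1.5 Mb for rs10948172,
whose ~667 kb block (chr6:44,683,049–45,349,877) is offset from the SNP.
Coordinates are hg19, 1-based, inclusive at both ends; probes exactly on a
boundary are inside. CpGs created or destroyed by a SNP ("polymorphic"
probes) are excluded before testing, and the number of probes that survive
inside the window is the multiplicity denominator *m* for that region.

### The dosage regression

For each CpG the methylation beta-value is modelled as a linear function of
minor-allele count:

$$\beta_i = b_0 + b_1 d_i + \varepsilon_i, \qquad d_i \in \{0, 1, 2\},$$

fitted by ordinary least squares with a two-sided t-test of $b_1 = 0$.
Beta-values are used directly (not M-values) and no covariates are
included: the contract is the simplest model consistent with per-SNP
targeted assays. Missing genotypes or beta-values are dropped pairwise per
locus × probe. Within each region the raw p-values are Benjamini–Hochberg
corrected with family size *m* (the full region probe count), and a CpG is
called significant at adjusted p < 0.05. The percent of methylation
variance explained by genotype is $100 R^2$ of the same univariate model.

Effect directions are reported per *risk* allele: risk dosage equals minor
dosage when the risk allele is the minor allele, and $2 - d$ otherwise, so
"lower" always means the OA-associated allele goes with less methylation
regardless of which allele is minor in the population.

### Stratified passes

The scan runs as a series of passes mirroring the study design — all
samples, OA only, NOF only, OA knee, OA hip, males, females — because many
OA association signals are joint- or sex-specific. Each pass is corrected
independently per region; the package does not reuse the all-samples
correction for stratified passes, since each pass is a separate family of
*m* tests. Strata that leave a locus untestable (no samples, fewer than 3
complete pairs, a monomorphic SNP) produce flagged rows rather than errors,
so a 16-locus run always completes.

### Replication

Replication uses pyrosequencing percent methylation measured in PCR
duplicates. A sample is excluded at a CpG when its duplicates differ by
more than 5 percentage points (strictly more: a difference of exactly 5 is
retained — the rule is read as an absolute percentage-point difference).
Surviving means are compared across genotype groups with a Kruskal–Wallis
test (tie-corrected, chi-squared approximation) and Bonferroni-corrected
over the *k* CpGs in the assay batch. A CpG replicates only if its
adjusted p is below 0.05 **and** the trend of the extreme genotype-group
means matches the discovery direction; trends within 0.5 percentage points
are called flat and never match (the tolerance is a package choice — the
value is small relative to replicate noise but protects against reading a
direction into numerical noise). Loci whose CpGs show disease-group
methylation differences (Kruskal–Wallis across OA knee / OA hip / NOF)
have their NOF samples excluded from replication, so a disease-group shift
cannot masquerade as a genotype effect.

### Expression integration

Relative expression is computed per sample and gene by the
$2^{-\Delta Ct}$ method, $\Delta Ct = Ct_\text{target} -
\overline{Ct}_\text{housekeeping}$ over the 18S/GAPDH/HPRT1 reference
roles. Outliers are removed by an iterative two-sided Grubbs test at
$\alpha = 0.05$ (the level, sidedness and iteration are package choices;
critical values come from the t-distribution form of the test). Expression
is then correlated with CpG methylation by Spearman rank correlation, and
tested across genotype groups with a Kruskal–Wallis test by default (a
Welch t-test on the two homozygous groups is available, since both tests
are conventional for this design).

## The synthetic cohort generator

Patient-level methylation and genotype data of the kind this pipeline
consumes are not redistributable, so the package ships a generator that
emulates the study conditions and is itself first-class, tested code.

* **Composition** — 99 discovery samples (63 OA knee, 17 OA hip, 19 NOF;
  NOF patients are femoral-neck-fracture controls free of OA) and a
  replication set of 40 OA + 5 NOF; sex is assigned 50/50 at random.
* **Loci** — the built-in 16-SNP panel with its per-region 450k probe
  counts (from 32 to 655 probes per region). Only the rs10948172 LD block
  has published bounds; the other 15 are synthetic ±100 kb placeholders
  that reproduce the "1 Mb suffices" geometry. Minor-allele frequencies
  are synthetic common-variant values (0.20–0.48); the four meQTL loci are
  given MAF ≥ 0.3 so power statements are interpretable.
* **Methylation** — generated on the logit scale:
  $\beta = \text{logit}^{-1}(b + e\,d_\text{risk} + o_\text{status} +
  o_\text{sex} + \sigma Z)$, then clamped a hair inside (0, 1). Additive
  generation on the beta scale could leave [0, 1]; the logit link cannot.
  Baselines $b$ are uniform on (−1.5, 1.5) (beta roughly 0.18–0.82, the
  informative mid-range of the array). Noise is $\sigma = 0.15$ logit
  units.
* **Planted effects** — $e = -0.4$ logit per risk allele at the nine
  catalogued meQTL CpGs (their real hg19 positions), so the risk allele
  lowers methylation at all four loci, as observed. NOF samples get a
  −0.3 logit offset at the GLT8D1/SUPT3H CpGs and males a −0.2 logit
  offset at three SUPT3H CpGs, emulating the reported group differences.
* **Truth ledger** — every planted effect is recorded both in logit units
  and as the *population OLS slope per minor allele* implied by the
  generative model, computed by numerical integration over the noise and
  offset mixture. Parameter-recovery tests compare estimates against this
  quantity, so "bias" is measured against the estimand the regression
  actually targets rather than a rough delta-method approximation.
* **Pyrosequencing** — duplicates are drawn around $100\beta$ with 2
  percentage points of replicate noise (4 in stress tests), truncated to
  [0, 100]; the fraction failing the >5-point rule then follows the
  closed-form Gaussian tail $P(|N(0, 2s^2)| > 5)$, which the tests verify.
* **Expression** — housekeeping Cts around fixed means (10/20/24 cycles)
  and a target Ct rising 2 cycles per unit of methylation beta by default,
  so relative expression falls with methylation.

A single root seed derives per-stage substreams, making every stage
reproducible independently; the full pipeline is bit-identical under a
repeated seed.

**What the generator does not emulate:** array probe chemistry and
normalisation artefacts, batch effects, cell-type heterogeneity,
LD-induced correlation between neighbouring CpGs (filler probes are
independent given genotype), genotyping error, and realistic effect-size
dilution — the planted −0.4 logit effect at σ = 0.15 noise gives variance
explained in the 60–80% range, larger than typical real meQTLs. Passing
tests therefore demonstrate correctness of the machinery (error control,
direction handling, power ordering, oracle agreement), not field-realistic
power estimates.

## Numerical and design choices

* **Closed-form vectorised OLS.** Regions hold up to 655 probes and the
  validation suites run hundreds of seeded cohorts, so per-probe `lm()`
  calls are replaced by centred-sums OLS over the probe matrix; tests
  cross-check it against `lm()` to 1e-10 and against permutation tests.
* **Degenerate inputs.** A constant response with polymorphic genotype
  returns slope 0 and p = 1 (a constant carries no evidence against the
  null); an exact fit with spread returns p = 0; monomorphic strata and
  fewer than 3 pairs are status-flagged. BH adjustment keeps `NA`s out of
  the family.
* **Standard tests are delegated** to `stats::p.adjust` (BH with the
  region family size), `stats::kruskal.test`, `stats::cor.test` and
  `stats::t.test`; the Grubbs filter is implemented in-package with
  t-based critical values. The test suite re-derives each of these against
  an independent oracle (hand-applied step-up, exhaustive/Monte-Carlo
  permutation, definitional G statistic) so no delegation is trusted
  blindly.
* **Rounding of distances.** Distances quoted per-CpG use floor (107 kb,
  82 kb, 25 kb); span-like quantities use nearest (the ~667 kb block).
  Both are exposed.
* **Validation problem sizes.** The suite uses 200 null cohorts
  (99 samples × 16 loci, ~3,100 probes each) for false-discovery control,
  200 single-locus cohorts for slope recovery and 100 for detection
  power, 20,000-shuffle permutation oracles, and 30,000 duplicate pairs
  for the QC-rate law — sizes at which the Monte-Carlo error of each
  check is far below its assertion margin while the whole suite stays
  interactive.

## Known limitations

* The scan is strictly cis and single-SNP: no trans effects, no
  conditional or multi-variant modelling, and no attempt to fine-map which
  LD-block variant drives a signal.
* No covariate adjustment (age, batch); the model mirrors the targeted
  design it implements.
* The stratified passes are correlated analyses of overlapping samples;
  no cross-pass multiplicity control is attempted beyond the per-region,
  per-pass BH correction.
* Real risk alleles are catalogued only for the four meQTL loci; the other
  twelve default to the minor allele, which affects only direction labels
  at those loci.

## A worked run

```{r run, eval = FALSE}
report <- run_pipeline(sim_config(), seed = 42)
report
#> <meqtl_report>
#>   seed 42 | package 0.1.0 | config 1550422a
#>   discovery: 4 of 16 loci with significant CpGs (adj. p < 0.05)
#>     ALDH1A2  rs3204689   1/91 CpGs,  ... lower methylation with risk allele, replicated
#>     GDF5     rs143383    1/270 CpGs, ... lower methylation with risk allele, replicated
#>     GLT8D1   rs6976      3/431 CpGs, ... lower methylation with risk allele, replicated
#>     SUPT3H   rs10948172  4/197 CpGs, ... lower methylation with risk allele, replicated
#>   replication: 9 of 9 tested CpGs replicated; 4 of 16 loci (25.0% of panel)
#>   expression: 4 gene-CpG pairs tested, 0 with Spearman p < 0.05
```

The discovery stage flags exactly the four loci with planted effects, each
with the planted number of CpGs (3/4/1/1), all in the "lower with risk
allele" direction; every assayed CpG replicates, and the expression stage —
whose default link is weak relative to n = 29 — finds no significant
methylation–expression correlation, matching the structure of the original
analysis.

```{r plots, eval = FALSE}
autoplot(report$scan, locus_id = "SUPT3H")          # region plot
cohort <- simulate_cohort(sim_config(seed = 42))
plot_genotype_methylation(cohort, "rs3204689", "cg12031962")
```
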