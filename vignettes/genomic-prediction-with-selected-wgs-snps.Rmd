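---
title: "Genomic prediction blending chip SNPs with selected whole-genome-sequence variants"
author: "wgsblend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction blending chip SNPs with selected WGS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsblend)
```

## The problem

Routine dairy-cattle genomic evaluation predicts breeding values from a
medium-density chip (about 54K SNPs). Custom chips increasingly add a few
thousand *selected* whole-genome-sequence (WGS) variants — markers chosen
because QTL mapping or functional annotation places them at or very near
causative mutations. `wgsblend` implements the statistical machinery needed
to ask whether such added variants improve prediction in a numerically small
breed, and whether any improvement is really carried by the selected
variants rather than by the mere increase in SNP density.

The package provides four model families and a validation framework, plus a
synthetic-population generator that reproduces the data structure these
analyses assume. Everything operates on deregressed proofs (DRP) as
pseudo-phenotypes with heterogeneous reliabilities.

## Phenotype model: deregressed proofs and residual weights

Each animal contributes one record per trait, a DRP with an effective record
contribution (ERC). With trait heritability $h^2$ and
$\lambda = (1-h^2)/h^2$, the DRP reliability is

$$ r^2_{\mathrm{DRP},i} = \frac{\mathrm{ERC}_i}{\mathrm{ERC}_i + \lambda}, $$

and every model uses a diagonal residual covariance $\mathbf{D}\sigma^2_e$
with $d_{ii} = (1-r^2_i)/r^2_i$, so low-reliability records are
down-weighted. `TraitSpec` stores $h^2$ and derives $\lambda$; `DRPRecords`
stores the records with their reliabilities and weights; records with
ERC $=0$ carry $r^2=0$ and are flagged unusable.

## Linear mixed models

All linear models have the form
$\mathbf{y} = \mathbf{1}\mu + \sum_c \mathbf{Z}\mathbf{a}_c + \mathbf{e}$
with $\mathbf{a}_c \sim N(0, \mathbf{K}_c \sigma^2_c)$ and
$\mathbf{e} \sim N(0, \mathbf{D}\sigma^2_e)$:

* **PBLUP** — $\mathbf{K}$ is the pedigree numerator relationship matrix
  $\mathbf{A}$, built by the tabular method after tracing the genotyped
  animals three generations back (`computeA`); truncation founders are
  treated as unrelated and non-inbred.
* **G1** — one genomic component; $\mathbf{G}$ by VanRaden's first method,
  $\mathbf{G} = \mathbf{M}\mathbf{M}^\top / (2\sum_j p_j(1-p_j))$ with
  $\mathbf{M}$ centred by twice the allele frequency observed in the
  analyzed animals (`computeGVanRaden`).
* **G2** — two genomic components with zero covariance: one from the chip
  SNPs ($\mathbf{G}_{54K}$) and one from the selected-WGS union
  ($\mathbf{G}_{WGS}$), each with its own variance.

No residual polygenic effect is included: the SNPs are assumed to capture
all genetic variation, which is the modelling choice the framework is built
to evaluate. $\mu$ is the only fixed effect.

`solveMME` computes $\hat\mu$ by generalized least squares and breeding
values by the BLUP identity
$\hat{\mathbf{a}}_c = \sigma^2_c \mathbf{K}_c \mathbf{Z}^\top
\mathbf{V}^{-1}(\mathbf{y} - \mathbf{1}\hat\mu)$. This form never inverts a
(possibly singular) $\mathbf{G}$ and predicts animals without records
through their relationships — exactly what validation requires, where the
validation animals sit in the matrices but contribute no records.

### REML

`remlEstimate` maximizes the restricted likelihood by average-information
iterations. When an AI step would leave the parameter space it is damped (a
component can shrink at most ten-fold per iteration, keeping it positive);
when the AI system is singular an EM-style step (Johnson–Thompson form) is
taken instead. Estimates are floored at $10^{-8}$, and convergence is
declared when the relative parameter change drops below `tol` *or* the
restricted log-likelihood plateaus (relative change below $10^{-9}$) — the
latter matters when a variance converges to the zero boundary, where the
parameter crawls but the likelihood is flat. One-component fits use an
exact eigendecomposition fast path (one $O(n^3)$ decomposition, then
$O(n)$ per iteration); multi-component fits use dense iterations.
Relationship matrices get a $10^{-8}$ diagonal jitter before factorization.

## The Bayesian four-distribution mixture (B1/B2)

SNP effects are modelled directly:
$\mathbf{y} = \mathbf{1}\mu + \sum_c \mathbf{X}_c \mathbf{g}_c +
\mathbf{e}$, with each component's effects drawn from a mixture of four
zero-mean normals whose variances are locked in the ratios
$1000\,\sigma^2_1 = 100\,\sigma^2_2 = 10\,\sigma^2_3 = \sigma^2_4$; only
$\sigma^2_4$ is free, per genetic component. Mixing proportions follow
$\pi \sim \mathrm{Dirichlet}(125, 25, 5, 1)$. B1 pools all SNPs into one
component; B2 keeps chip and selected-WGS components separate (zero
covariance), each with its own $(\pi, \sigma^2_4)$ — chosen per-component
rather than shared because the two panels are expected to carry very
different effect-size distributions.

Design notes, where the model family leaves room:

* The nominal initial proportions $(0.889, 0.1, 0.01, 0.001)$ are not the
  mean of $\mathrm{Dirichlet}(125,25,5,1)$ (which is about
  $(0.801, 0.160, 0.032, 0.006)$). The Dirichlet counts drive the sampling;
  the nominal vector is used as chain initialisation only.
* Unlike the classic spike-at-zero variant of this model family, class 1
  has a small but nonzero variance ($\sigma^2_4/1000$), exactly per the
  ratio constraint; no point mass is used.
* $\sigma^2_4$ (and $\sigma^2_e$) carry scaled inverse-chi-square priors
  with 4 degrees of freedom; the prior scales are set from an initial
  variance partition of the phenotypic variance (half genetic, half
  residual), so the prior is weak but proper on the data's scale.
* The single-site Gibbs sampler updates SNPs in a fixed order by default
  (reproducibility); random order is available by flag. Class likelihoods
  are computed in log space with max-subtraction. The sampler runs in C++
  on R's RNG, so `set.seed` gives byte-identical chains.
* Default chain: 50,000 iterations, 10,000 burn-in, thinning 20 (2,000
  saved samples). The examples and tests use much shorter chains; mixing on
  the small simulated panels is fast because each SNP's conditional is
  sampled exactly.

Breeding values are posterior-mean effects times centred genotypes
(`posteriorEBV`), with centering frequencies fixed at those used during
sampling.

## Validation framework

Over a set of validation animals (`reliability`, `biasSlope`, `stability`):

* **Reliability** — $\mathrm{cor}(\mathrm{EBV}, \mathrm{DRP})^2$ divided by
  the mean DRP reliability of the validation animals.
* **Bias** — the regression slope of DRP on EBV; 1 is unbiased, below 1
  means over-dispersed predictions.
* **Stability** — correlation between predictions from the reduced
  (reference-only) and full data for the same animals.

`bootstrapCompare` contrasts two scenarios by a *paired* bootstrap: each of
the (default 10,000) replicates resamples the validation animals once and
evaluates both scenarios on the same resample. The mean and standard
deviation of the replicate contrasts give a paired t statistic
(two-tailed, $n_{boot}-1$ df), with Bonferroni correction at
$\alpha/m$ within a comparison family. The shared-resample pairing is what
makes the test paired; the contrast SD is the bootstrap standard error.
Identical scenarios yield exactly zero contrasts and are flagged rather
than tested. Fewer than 100 replicates are refused unless forced.

`runScenarioGrid` executes a trait × reference-set × SNP-set × model grid
and builds the three comparison families (across SNP sets, across reference
sets, across models), with $m$ = the number of pairwise comparisons in the
family. Per-cell seeds are derived by stable hashing of the cell key, so
adding a scenario leaves the others' randomness untouched.

`snpThinningExperiment` is the density control: remove as many random chip
SNPs as the selected-WGS union adds (default five replicates), keep the
selected SNPs, refit, and compare at equal SNP counts.

## The synthetic-population generator

The generator defines the study conditions; it is not a tuning dial.

* **Pedigree** (`simulatePedigree`): discrete cohorts; each non-founder
  cohort is produced by a few sires with a fixed number of offspring —
  paternal half-sib families, the structure that drives the
  reference/validation split rules.
* **Genotypes** (`simulateGenotypes`): gene dropping. Founder haplotypes
  are drawn per SNP in linkage equilibrium at frequencies uniform on
  [0.05, 0.5]; descendants inherit recombined haplotypes (Poisson
  crossovers, default one per chromosome per meiosis). Linkage
  disequilibrium therefore arises from family co-segregation — the dominant
  LD source in a half-sib population — not from ancestral coalescent
  history. This is deliberate: it matches the family structure the split
  rules guard against and is simple to verify (Mendelian consistency,
  parent–offspring regression of one half).
* **Architectures** (`assignQTL`): polygenic, major-QTL, or a four-class
  mixture mirroring the Bayesian prior; effects are rescaled so the
  realized additive variance equals $h^2$ on a phenotypic scale of 1.
* **Panels** (`buildPanels`): evenly spaced non-causal chip SNPs; two
  selected-WGS panels drawn from SNPs at or near causal variants
  (`proximity` in SNP-index units, 0-based positions; no physical map — the
  models never use one), with an exact number of dual-labelled SNPs so
  union accounting is testable.
* **Phenotypes** (`simulateERC`, `simulateDRP`): ERC log-normal with
  sex-specific means (bulls 40, cows 2, log-sd 0.5) — values chosen once to
  reproduce the qualitative bull ≫ cow reliability ordering reported for
  progeny-tested populations; neither the exact ERC distributions nor their
  parameters are observable from published summaries. DRP noise variance is
  $\sigma^2_a d_i$, which makes
  $\mathrm{cor}(\mathrm{DRP},\mathrm{TBV})^2 = r^2_{\mathrm{DRP}}$ hold by
  construction. A `drp_set` switch regenerates DRP with inflated bull ERC
  to emulate evaluations in which bull proofs absorb genotyped-cow
  information.
* **Imputation** (`injectImputationErrors`): imputation itself is out of
  scope; only its error process matters downstream. Genotypes are replaced
  with per-SNP probability by Hardy–Weinberg draws, and the per-SNP
  correlation and concordance against the originals feed QC.
* **QC** (`qcFilter`): retain MAF ≥ 0.01 (inclusive boundary) and both
  imputation metrics strictly above 0.8. A SNP with no genotypic variation
  counts as MAF 0 regardless of its nominal frequency. The filter is
  idempotent.
* **Split** (`splitReferenceValidation`): validation = young females plus
  their recent female paternal half-sibs, minus oversized families (cap
  500, kept in the reference) and low-reliability records ($r^2 \le 0.2$);
  the reference excludes the validation animals' recent maternal half-sibs,
  their progeny, and those progeny's sibs (full and half — the narrower
  reading would leave a leakage channel, so both are excluded).

What the generator does *not* emulate: ancestral (population-level) LD,
selection and assortative mating across generations, a physical map, real
chip ascertainment, or the two-step family/population imputation procedure.
Consequently, passing tests show that the estimators and comparisons behave
correctly under family LD and the stated error models — they do not certify
absolute reliability levels on real cattle data, which depend on LD
structure and reference sizes the generator does not reproduce.

## Worked example

```{r example, eval = FALSE}
ped <- simulatePedigree(nFounders = 120, nGenerations = 4,
                        siresPerGen = 6, offspringPerSire = 30, seed = 401)
panel <- qcFilter(simulateGenotypes(ped, nChromosomes = 2,
                                    snpsPerChromosome = 450,
                                    seed = 431))$panel
trait <- TraitSpec("milk", h2 = 0.390)
qtl <- assignQTL(panel, trait, "major_qtl", nQtl = 45, seed = 461,
                 majorFrac = 0.35, nMajor = 2)
panel <- buildPanels(panel, qtl, nChip = 600, nDfs = 25, nFra = 25,
                     nOverlap = 5, proximity = 0, seed = 491)
erc <- simulateERC(pedigreeTable(ped)$sex, seed = 521)
drp <- simulateDRP(trueBreedingValues(qtl), trait, erc, seed = 551)
split <- splitReferenceValidation(ped, drp, birthCutoff = 4,
                                  halfsibWindowStart = 3)

chip <- panelSnpIds(panel, "CHIP")
both <- union(chip, panelSnpIds(panel, "WGS"))
g1chip <- fitModel("G1", drp, panel, snpSubset = chip,
                   referenceIds = referenceIds(split))
g1both <- fitModel("G1", drp, panel, snpSubset = both,
                   referenceIds = referenceIds(split))
reliability(g1chip$ebv, drp, validationIds(split))
reliability(g1both$ebv, drp, validationIds(split))
```

## Problem sizes and numerical choices

The shipped tests and the reproduction script run entirely on simulated
data at desk scale, chosen as the smallest sizes at which the checked
properties are stable: oracle equivalences on 5–30 animals; REML recovery
at n = 1000 founders with up to 2000 SNPs over 20 seeds; the bootstrap
contracts at n = 2000 validation animals with 10,000 replicates; and the
qualitative direction checks on populations of 660 animals (about 450
reference, 90 validation after the split rules), 900 SNPs and 45 causal
variants, over 10 simulation seeds with 4,000-iteration chains. Direction
checks are asserted by one-sided bootstrap over the per-seed differences,
not per single run.

Known limitations: no multi-trait or single-step (H-matrix) models, no
dominance or epistasis, no VanRaden method 2, no annotation-informed
mixture classes, and no convergence diagnostics beyond determinism and the
oracle cross-checks; real (incomplete) genotype files are only supported
via mean imputation with a warning.
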