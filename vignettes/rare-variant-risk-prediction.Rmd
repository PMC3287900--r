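---
title: "Assessing the added predictive value of rare variants with collapsing and SVM risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the added predictive value of rare variants with collapsing and SVM risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Common susceptibility variants found by association studies have added
little discriminative power to risk models built on classical risk factors.
Rare variants, which can carry larger functional effects, might do better —
but individually they are too infrequent to estimate reliably, so their
information has to be aggregated. `rarepred` implements a complete,
reproducible pipeline for asking a precise version of this question in a
case-control cohort: *does adding gene-level collapsed rare variants to a
risk model that already contains screened common variants and environmental
covariates improve validation AUC, and by how much?*

## The procedure

Given genotypes for unrelated individuals (minor-allele dosages 0/1/2), a
per-SNP gene map with nonsynonymous flags, covariates (age, sex, smoking)
and one or more binary trait replicates:

1. **MAF partition.** Sample minor allele frequencies are computed on the
   training individuals only and SNPs are split at the conventional 5%
   boundary: *rare* (0 < MAF < 0.05), *common* (MAF ≥ 0.05; the boundary
   value counts as common), monomorphic SNPs are untestable and dropped.
2. **Common-variant screen.** Each common SNP is tested with Fisher's exact
   test on the 2×2 table of minor/major allele counts in cases vs.
   controls (two alleles per individual); SNPs with two-sided `p` strictly
   below the chosen threshold survive.
3. **Rare-variant collapsing.** Within each gene, two candidate burden sets
   are formed — all rare SNPs, and nonsynonymous rare SNPs — and collapsed
   into presence/absence carrier indicators (1 if the individual carries a
   minor allele at any member SNP). Each non-constant indicator is tested by
   a 1-df likelihood-ratio test in a logistic model adjusting for age, sex
   and smoking. If both sets of a gene pass the threshold, the one with the
   smaller AIC (`2k − 2 lnL`) is kept; a gene contributes at most one
   feature.
4. **Risk models.** Two soft-margin linear SVMs (penalty `C = 1`, the
   LIBSVM/e1071 default) are trained on the standardized feature matrix:
   one on common dosages + covariates, one additionally containing the
   rare-burden indicators. Decision values `w'x + b` rank predicted risk.
5. **Evaluation.** Validation AUC is the exact Mann–Whitney estimator
   (ties take half credit). The two models are compared
   replicate-by-replicate: paired differences, a t-based 95% CI, and a
   two-sided paired t-test.

Two experimental designs are provided. In the *replicate-train* design
(`run_experiment1`), selection and training use all individuals under the
labels of one trait replicate; the fixed decision scores are then evaluated
against every other replicate's independently re-simulated labels. In the
*random-split* design (`run_experiment2`), each trait replicate is divided
into a seeded random training subset (sizes 300–600 by default) and a
held-out validation subset, and *everything* — MAF partition, both screens,
burden membership, feature scaling, SVM weights — is recomputed on the
training subset alone.

## The synthetic cohort generator

The pipeline was designed for mini-exome style workshop data (697 unrelated
individuals, thousands of gene-grouped SNPs, hundreds of re-simulated trait
replicates on fixed genotypes) whose distribution is restricted; the
generator reproduces that *structure* so every stage can be exercised and
validated without any download:

- **Genotypes.** Each of `n_genes` genes receives `1 + Poisson(mean − 1)`
  SNPs (default mean 7.6, matching roughly 24,500 SNPs over 3,205 genes at
  full scale; the package default of 200 genes keeps desk runs fast).
  A SNP is rare with probability `prop_rare = 0.75`. Rare-stratum
  population frequencies are drawn log-uniformly (density ∝ 1/x) on
  [5×10⁻⁴, 0.05]: sequence data is dominated by very rare alleles, and a
  1/x spectrum — the neutral site-frequency shape — reproduces the key
  consequence that per-gene carrier frequencies spread over a wide range
  (a uniform rare spectrum would push almost every gene's carrier
  frequency above 20%, leaving no gene in the realistic 2–5% band).
  Common frequencies are uniform on [0.05, 0.5]. Genotypes are two
  independent allele draws per individual (Hardy–Weinberg, linkage
  equilibrium).
- **Covariates.** Age ~ Normal(50, 10²) truncated to [20, 90], sex ~
  Bernoulli(0.5), smoking ~ Bernoulli(0.3).
- **Phenotypes.** A population logistic model: log-odds are an intercept
  plus covariate terms, per-allele effects of causal common SNPs, and
  carrier effects of causal rare-burden genes. The intercept is calibrated
  by monotone root-finding so the cohort-mean case probability equals the
  target prevalence (default 0.30 — the workshop data's case proportion is
  not published, so this is a free parameter fixed once at a typical
  simulated-cohort value). Each replicate is an independent Bernoulli draw
  on the same genotypes, with a deterministic sub-seed per replicate so any
  replicate can be regenerated in isolation. Case counts therefore vary
  randomly across replicates; a fixed-count resampling mode is available
  as an option.
- **Causal architecture.** `causal_model()` picks 10 common causal SNPs
  (per-allele log-odds 0.4, drawn from the MAF band 0.1–0.4) and 20
  rare-burden causal genes (carrier log-odds 1.5, drawn from genes whose
  carrier frequency lies in 2–5%), plus modest covariate effects.

What the generator does *not* emulate: linkage disequilibrium between SNPs,
population stratification or relatedness, genotyping error, and any
family-based or quantitative-trait structure. Passing tests on this
generator therefore demonstrate the correctness and calibration of the
*procedure*, not the specific AUC levels attainable on any real cohort —
with LD, selected tag SNPs partially proxy unselected causals, which tends
to shrink the marginal value of added features.

## Numerical choices and edge cases

- **Fisher p-values** are computed by summing hypergeometric point
  probabilities over the whole support, counting tables whose probability
  is within a relative factor 1 + 10⁻⁷ of the observed one as ties (the
  same two-sided rule as `stats::fisher.test`, vectorized so that
  allele-count margins in the thousands remain fast). A degenerate margin
  returns p = 1 with a flag, and is never selected.
- **Logistic fits** use IRLS (relative deviance tolerance 10⁻¹⁰, ≤ 50
  iterations). Quasi-complete separation is flagged (`converged = FALSE`)
  when a coefficient passes 50 on the log-odds scale; the LRT p at the
  last iterate is still reported. The covariate-only null model is fitted
  once per gene scan. The LRT (not Wald) was chosen for the burden test:
  it is markedly better behaved when carriers are sparse.
- **AIC tie-break.** When a gene's two burden sets have exactly equal AIC
  (which happens whenever the two indicators coincide, e.g. all rare SNPs
  of the gene are nonsynonymous), the nonsynonymous set is kept — the more
  restrictive annotation.
- **Thresholding is strict** (`p < t`), so selection is nested across the
  threshold sweep by construction; a single scan is filtered per
  threshold.
- **SVM.** Labels map to ±1 with positive decision values meaning case
  (the sign convention is fixed explicitly from the solver's internal
  label order). Features are standardized by training-set mean/sd by
  default — the behaviour of the reference SVM tooling — with zero-variance
  columns left unscaled; validation matrices always reuse the training
  scaling. The solver stopping tolerance defaults to 10⁻⁵, which keeps
  KKT residuals around 10⁻⁵ on the pipeline's (often collinear) genomic
  feature matrices at millisecond cost; tightening it to 10⁻⁸ drives the
  duality gap below 10⁻⁶ on problems where exact optima are wanted (the
  package's oracle tests do exactly that). A radial kernel
  (`exp(−γ‖x−y‖²)`, γ = 1/#features) is available behind a flag for
  sensitivity analysis; the linear kernel is the supported analysis.
- **Missing genotypes** (absent in simulated data, permitted on input):
  SNPs over 5% missing are dropped at load with a warning; collapsing
  treats missing as non-carrier; remaining missing dosages are imputed to
  the training subset's rounded mean dosage at feature assembly.
- **Degenerate cells.** If no genetic feature survives a threshold, models
  are still trained on covariates alone so the with/without comparison
  stays paired. If the paired AUC differences have zero variance (e.g.
  identical models), the comparison is flagged degenerate and the t
  statistic is withheld rather than fabricated.
- **Replicate-train evaluation** computes AUC per validation replicate and
  averages (the only reading consistent with a paired t-test across
  replicates); pooled-score AUC is not used. The per-replicate AUCs reuse
  one fixed score vector because only the labels change across replicates.
- **Experiment 2 splits** are simple random by default (a
  case:control-stratified mode is a flag); a split missing a class on
  either side is redrawn deterministically and logged.

## Problem sizes

Desk-scale defaults were chosen so a full validation pass stays
interactive: 697 individuals × 200 genes (~1,500 SNPs), 50–100 trait
replicates, and 50 split replicates per experiment-2 cell. The full-scale
structure (3,205 genes, 200 replicates) is a configuration change, not a
code change.

## A worked run

```{r, eval = FALSE}
library(rarepred)

cfg <- sim_config(n_replicates = 100, seed = 1)
gen <- simulate_genotypes(cfg)
cov <- simulate_covariates(cfg)
mdl <- causal_model(gen$genotypes, gen$annotation, seed = 1)
mdl$intercept <- calibrate_intercept(mdl, gen$genotypes, gen$annotation,
                                     cov, 0.3)
ph <- simulate_phenotype_replicates(gen$genotypes, gen$annotation, cov,
                                    mdl, 100, derive_seed(1, 3))
ch <- cohort(gen$genotypes, gen$annotation, cov, ph)

run_experiment1(ch, experiment_config(thresholds = c(0.01, 0.001), seed = 1))
run_experiment2(ch, experiment_config(thresholds = 0.01,
                                      training_sizes = c(300, 600),
                                      seed = 1),
                replicates = 1:50)
```

`scripts/acceptance.R` packages this run (plus a null-cohort calibration)
end to end and writes the resulting AUCs, differences and paired-t
p-values as JSON.

## Known limitations

- The collapsing statistic is presence/absence only; weighted burden or
  variance-component (SKAT-type) tests are out of scope.
- The common-variant screen is unadjusted (Fisher's test admits no
  covariates); covariate adjustment enters through the rare-variant
  logistic stage and the SVM's covariate features.
- No multiple-testing correction is applied — thresholds are swept and
  reported per threshold, which is the object of study rather than a
  decision rule.
- AUC comparison across replicates uses normal-theory paired intervals;
  single-validation-set methods (DeLong) are not implemented.
- Multi-allelic VCF records must be split upstream; BGEN/PLINK formats are
  not read.
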