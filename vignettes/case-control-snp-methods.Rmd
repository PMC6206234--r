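---
title: "Methods: case-control SNP association, FPRP and haplotype EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP association, FPRP and haplotype EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsnp)
```

## Scope and data model

`ccsnp` analyzes unmatched case-control studies of a small panel of
biallelic SNPs. The unit objects are a `snp_def` (rsID, common and
variant allele in "X>Y" orientation, protective genotype set), a
`cohort` (panel plus a subject table with status, age in months, sex,
tumor site and per-SNP variant-allele doses), and a `genotype_counts`
triple per SNP. Genotypes are stored as doses 0/1/2 rather than allele
strings: the X>Y orientation fixes unambiguously which allele is
counted, which makes additive coding and protective-genotype scoring
deterministic. Missing genotypes (file sentinel `./.`) are dropped
per-analysis, never imputed; the combined protective-genotype score is
complete-case because a 0-5 score is undefined when any of the five
genotypes is absent.

The bundled study panel is the five-SNP *LMO1* set (rs110419 A>G,
rs4758051 G>A, rs10840002 A>G, rs204938 A>G, rs2168101 G>T), with every
variant-carrying genotype protective, and the published aggregate count
tables for 313 cases / 762 controls ship as plain-TSV package data.

## Single-locus association

All 2×2 contrasts use the cross-product odds ratio with the Woolf
standard error and a two-sided Wald test. The normal quantile is carried
at full precision (1.959964, not 1.96); this is what reproduces the
published two-decimal confidence bounds. Zero cells make a contrast
inestimable (rendered `/`) rather than raising an error; the
Haldane–Anscombe +0.5 correction is available behind a flag but is never
applied silently.

Two p-values coexist by design: the Wald p of each log-OR, and the
Pearson χ² of the underlying table (2 df for the 3×2 genotype
distribution, 1 df for collapsed models). Published tables report both,
in different columns, and the package exposes both (`p_value`,
`p_chi2`). No multiple-testing correction is applied anywhere — the
pipeline follows the FPRP route to noteworthiness instead of
Bonferroni/FDR.

The additive model is the exponentiated dose coefficient of a
maximum-likelihood logistic regression on the six grouped genotype
cells. `fit_logistic()` wraps binomial IRLS (`stats::glm.fit`) with
replicate weights, so grouped counts and row-expanded individual data
give identical estimates (asserted to 1e-9 in the tests, along with a
grid-plus-simplex likelihood-maximizer oracle). Convergence is tight
(epsilon 1e-12, 100 iterations) and apparent complete separation
(|coefficient| > 15) is an error, not a silent huge OR.

Adjusted estimates code age as continuous months and sex as a male
indicator. The source study does not state its coding; continuous age is
the default here, and the 18-month dichotomy is used only to define age
strata (≤18 vs >18 months). Site-of-origin strata compare each site's
cases against **all** controls, since controls carry no tumor site.

## Synthetic cohorts

The generator draws each subject's two haplotypes independently from a
configured frequency spectrum, which induces linkage disequilibrium
exactly through the joint haplotype frequencies (no recombination model
— the level of structure a published haplotype table can constrain) and
guarantees Hardy–Weinberg equilibrium at every locus in the source
population. Disease status is Bernoulli with

    logit P(case) = baseline + Σ_s effect(s, dose_s) + β_age·age + β_male·male,

and case-control sampling accumulates individuals by rejection until the
target group sizes are met exactly, mirroring the study design. A single
global RNG stream per run makes every output deterministic under the
seed.

Defaults are the study conditions: the 24-haplotype control-chromosome
frequency spectrum, 313 cases / 762 controls, dominant protective
effects of log(0.6) at the four associated SNPs and zero at rs204938,
baseline logit −2, truncated-normal age (mean 33.04, SD 30.30, range
0–132 months), P(male) = 0.5538, and multinomial tumor sites at the
published proportions (21.73 / 40.26 / 31.63 / 6.39%), assigned to cases
with no genetic dependence (the study gives no per-site effect
structure). Covariate effects default to zero, so adjusted and crude
estimates coincide up to noncollapsibility and Monte-Carlo noise —
which is itself a test.

What the generator does **not** emulate: population stratification and
admixture, genotyping error, relatedness, and any real age/sex
dependence of genotype. Passing calibration tests therefore shows the
estimators are correct under the stated model, not that the original
cohort is free of such artifacts.

Problem sizes in the test suite were chosen to keep the full run at a
few minutes on one CPU while leaving Monte-Carlo noise well inside each
asserted band: 200 replicates for null centering and effect recovery,
500 replicates of n = 2000+2000 for the adjusted-OR bias bound (<0.03
on the log scale), 1000 null replicates of 313/762 for the type-I-error
band [0.035, 0.065] at α = 0.05.

## FPRP

`fprp()` is the Wacholder posterior false-positive probability
α(1−π)/(α(1−π)+(1−β)π). Three numerical choices matter:

* **α is the observed p-value at full precision.** The published FPRP
  values are reproducible only this way: the rs110419 heterozygote cell
  (prior 0.25) is 0.009 with α = 0.00105 but drifts at the printed
  α = 0.001, and a published 0.200 cell needs α = 0.0456 rather than the
  printed 0.046.
* **Power** is the closed-form two-sided normal-test power to detect a
  hypothesized true OR₁ given the SE recovered from the reported CI,
  `se = (log hi − log lo)/(2·1.959964)`. The OR₁ policy defaults to the
  reciprocal pair 0.67/1.5 by direction of the estimate and is
  configurable, because source studies rarely state their OR₁.
* **Published power columns are inputs, not targets.** The study's
  printed power values (e.g. 0.361 where the internal model gives
  ≈0.29) are not reproducible from the stated parameters under any
  standard recipe, so `fprp_table()` accepts a supplied power column
  that overrides the internal model; the package does not claim to
  regenerate that column.

Degenerate priors are defined explicitly: π = 1 gives FPRP 0, π = 0
gives 1.

## Haplotype EM

The E-step support set for a genotype with *h* heterozygous loci is the
max(1, 2^(h−1)) unordered compatible pairs, enumerated exactly (checked
against brute-force enumeration of all ordered pairs). Pair posteriors
are proportional to θ_h1·θ_h2, doubled for heterozygous pairs; the
M-step divides expected chromosome counts by 2N. The log-likelihood is
asserted non-decreasing at every iteration; the stopping rule is a
log-likelihood change below 1e-9 (or 1000 iterations, with a warning —
never silent). Initialization is the deterministic product of
single-locus allele frequencies, with optional seeded Dirichlet restarts
taking the best likelihood; at one locus the EM fixed point is exactly
allele counting.

EM runs separately per group (cases; controls), matching group-specific
published counts; the source study does not state whether it pooled
first. Association uses unrounded expected counts by default; a
haplotype is inestimable when its count rounds to zero in either group
(the `/` rows of published tables), and haplotypes rounding below one
chromosome in both groups are suppressed from reports. Running the
contrasts on printed integer counts instead reproduces the published
crude ORs at two decimals (one extreme row, case/control 6/1, differs by
one print-rounding unit because the published counts are themselves
rounded EM expectations). Missing genotypes are handled by complete-case
exclusion, not E-step marginalization, keeping the support enumeration
exact.

Optional covariate-adjusted haplotype ORs regress case status on each
subject's posterior expected haplotype copies (dosages) from a pooled EM
fit plus age and sex. Dosage regression was chosen over most-likely
phase because it propagates phase uncertainty; per-copy dosage ORs
approximate, but do not exactly equal, a vs-reference contrast, which is
why the adjusted path is optional and the crude contrast is primary.

## Known limitations

* Wald/Woolf inference is asymptotic; very sparse haplotypes (counts of
  1–2 chromosomes) get wide, fragile CIs and exact methods would differ.
* The EM likelihood assumes random mating within each group; strong
  population structure would bias frequencies.
* Stratified estimates reuse the global adjustment covariates; strata
  are not matched designs.
* The demographic matching χ² reproduces published values only to ~3
  decimals; the original exact-test variant is unknown.
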