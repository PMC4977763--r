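---
title: "Mapping breed stereotypes: models and methods in breedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping breed stereotypes: models and methods in breedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

## The cross-breed stereotype design

Dog breeds are closed populations with strong, well-documented behavioral
tendencies. Instead of phenotyping individual dogs, the cross-breed design
assigns every genotyped dog the *breed-average* (stereotype) score of its
breed — here the nine C-BARQ classes: four aggression traits
(stranger-directed, dog-directed, owner-directed, dog rivalry) and five
fear/anxiety traits (stranger-oriented, dog-oriented, nonsocial fear,
separation-related anxiety, touch sensitivity). The phenotype is therefore
constant within breed, and all mapping information comes from between-breed
contrasts of allele frequency. That design has two consequences that shape
everything in this package:

* population structure *is* the signal carrier, so naive regression is
  catastrophically confounded and a mixed model with a genetic relatedness
  matrix is essential;
* loci that differentiate breeds strongly — selective sweeps — are exactly
  the loci the design can detect, so selection statistics and haplotype
  analysis are natural companions to the association scan.

## The linear mixed model

For one SNP the model is

$$ y = W\alpha + x\beta + u + \epsilon, \qquad
   u \sim N(0, \lambda \tau^{-1} K), \quad
   \epsilon \sim N(0, \tau^{-1} I), $$

with $W$ an intercept only, $x$ the mean-imputed minor-allele dosage, and
$K$ the **centered** genetic relatedness matrix
$K = \frac1m \sum_j (x_j-\bar x_j)(x_j-\bar x_j)^\top$. Each SNP is tested
by the likelihood-ratio statistic $2(\ell_1 - \ell_0)$ against $\chi^2_1$,
comparing the SNP model to the intercept-only null.

Numerical strategy, following the standard eigendecomposition trick: $K =
UDU^\top$ is computed once; rotating $y$, $x$ and the intercept by
$U^\top$ diagonalizes the covariance, so for any variance ratio $\lambda$
the fixed effects and $\tau$ are profiled out in closed form and the
likelihood costs $O(n)$. The 1-d profile likelihood is maximized over
$\log_{10}\lambda \in [-5, 5]$ by a 41-point grid followed by
golden-section refinement of every local grid optimum, with ties broken
toward smaller $\lambda$. Choices worth stating explicitly:

* **ML, not REML.** The test is a likelihood ratio between models with
  different fixed effects, which is only valid on ML likelihoods.
* **Mean-centering $y$** before rotation. The intercept absorbs the mean
  exactly, and centering avoids catastrophic cancellation when $\lambda$
  sits at the upper search bound — which is the *typical* situation here,
  because a breed-constant phenotype has essentially no within-breed
  residual and the profile likelihood plateaus in $\lambda$.
* **Degenerate SNPs** (monomorphic after imputation, or numerically
  collinear with the intercept) yield flagged records with $\beta = 0$,
  $p = 1$; a scan never aborts.
* The kernel is implemented in C++ (Rcpp) because the null calibration
  study fits two million single-SNP models.

The suite verifies the likelihood against an explicit
$(\lambda K + I)^{-1}$ GLS evaluation, the optimizer against a 0.01-step
grid, the collapse to OLS when $K = I$, and — on simulated breed-structured
nulls — that the empirical type-I error at $p < 0.05$ stays in
$[0.03, 0.07]$ while naive OLS exceeds 0.30.

Significance defaults to the inclusive rule $p \le 10^{-8}$ (the
convention for ~175k-SNP canine arrays; `significance_policy(1e-5)` suits
~45k-SNP panels). Phenotypes are used on their raw stereotype scale;
standardizing them changes nothing in the LRT because the model includes an
intercept and $\tau$ is profiled.

## Selection statistics

`pairwise_fst()` uses Hudson's two-population estimator with sample-size
correction, which is unbiased under unequal sample sizes; negative per-SNP
values are retained so genomewide moments stay unbiased. Genomewide
summaries use the ratio-of-averages form (`mean_pairwise_fst()`); averaging
per-SNP ratios is biased toward zero and is not used for calibration
checks.

The windowed statistics follow the published per-breed definitions:

* $d_i(b, w) = \sum_{j \ne b} \frac{\bar F^{bj}_{ST}(w) - \mu^{bj}}
  {\sigma^{bj}}$ — window-mean pairwise $F_{ST}$, standardized per pair by
  its genomewide window moments, summed over pairs involving breed $b$;
* $s_i(b, w)$ — the pairwise difference in *relative* window
  heterozygosity ($H_b(w)/\bar H_b$, with $H$ the window mean of
  $2p(1-p)$), standardized per pair and summed; strongly negative values
  mark reduced heterozygosity, the sweep footprint.

Windowing is a free design choice (the original tracks were published
precomputed): the default is 500 kb non-overlapping windows, last window
truncated, and regions are called per breed beyond the genomewide 99th
percentile (above for $d_i$, below for $s_i$), merging adjacent extreme
windows within a chromosome. Windows with no SNPs are missing and excluded
from all moments. Both statistics are invariant to allele-label flips and
to uniform scaling of heterozygosity, and each pair's standardized
deviations sum to zero over windows by construction — properties the suite
tests directly.

## Direct haplotype phasing and map intervals

At an association peak, within one breed, the dogs homozygous for one peak
allele need no statistical phasing. `phased_block()` keeps only such
subsets with **at least 4 dogs**, then extends from the peak SNP in both
directions, retaining each flanking SNP while its majority allele among
the homozygote subset has frequency **at least 0.95**, and stopping at the
first failure on each side. Readings that the published rule leaves open,
and how they are resolved here:

* "frequency of at least 0.95" is taken as the *per-SNP majority* allele
  within the subset (the natural consensus-haplotype reading); a
  fixed-founder-allele variant is available via `founder_allele = TRUE`;
* extension is strictly contiguous — one failing SNP terminates that side.
  An exhaustive enumeration oracle over all peak-containing intervals
  confirms on random fixtures that this greedy rule returns the maximal
  qualifying interval;
* missing genotypes leave the denominator; an all-missing SNP passes (no
  evidence against) and is counted in `n_all_missing`;
* allele labels `"A"`/`"B"` are positional (allele1/allele2), as allele
  letters on arrays are arbitrary.

The **maximum map interval** is the intersection of blocks across the
breeds that have one (breeds below the 4-homozygote floor simply drop
out). The **minimum map interval** additionally intersects the smallest
cross-breed overlap of $d_i$ or $s_i$ regions that contain the peak or abut
it within one window; if neither statistic produces a peak-covering
intersection the minimum equals the maximum — a locus can lack selection
evidence yet still be mapped by its haplotypes. Intervals are 1-based
inclusive bp, inherited from the PLINK MAP convention, and lengths are
reported in kb.

`pairwise_ld()` provides the companion matrices: composite $r^2$ from
genotype correlations and $|D'|$ from two-locus haplotype frequencies
estimated by EM over the double-heterozygote ambiguity.

## Breed-frequency prediction

`stepwise_fit()` regresses breed trait values on breed allele frequencies
of a small candidate marker panel with **no intercept**, adding at each
step the candidate with the smallest partial t-test p-value at or below
$\alpha = 0.05$, then removing any included marker whose p-value rises
above $\alpha$ (a single inclusion/exclusion cutoff; entry and stay can be
set separately). Exact ties are broken by candidate order; a visited-model
cycle guard terminates pathological entry/removal loops; an empty model
predicts the training mean and flags the fact.

Cell-level success for held-out breeds is a reporting convention rather
than a statistical necessity, so `success_matrix()` keeps it configurable:
the default accepts a prediction within half the across-breed SD of the
observed trait; a rank-window alternative (exact rank match at window 0)
admits an analytic chance rate of $1/k$ that the permutation machinery is
checked against. Chance is never assumed: `permutation_chance()` shuffles
observed values across breeds within each trait and reports the null mean
success rate and the permutation p-value $(1 + \#\{null \ge achieved\}) /
(n_{perm} + 1)$.

## What the simulator emulates — and what it does not

`simulate_breed_genotypes()` is a statistical stand-in for real array
cohorts, built so every analysis above has planted truth to recover:

* **Breed structure**: ancestral frequencies $\sim$ Uniform(0.05, 0.95)
  (avoiding rare-allele degeneracy), per-breed frequencies Balding-Nichols
  $\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ with default
  $F = 0.2$, genotypes Binomial(2, breed frequency). The realized
  genomewide ratio-of-averages $F_{ST}$ reproduces the configured $F$.
* **Sweeps**: at a causal locus the risk allele is a *derived* allele with
  low ancestral frequency (default 0.1) driven to near-fixation (default
  0.975) in the carrier breeds only — the classic sweep contrast of a
  variant common in selected breeds and rare elsewhere. All carrier-breed
  chromosomes inherit one founder haplotype across the flank (default
  1 Mb half-width) with a 2% per-SNP leak, so the 0.95 phasing rule meets
  realistic decay at block edges.
* **Stereotypes**: breed trait = $\sum_\ell w_\ell f_{b\ell}$ + Normal
  breed noise (default SD 0.1), clipped to a nonnegative range like
  questionnaire scores. The default fixture plants weight 1.0 on the raw
  frequency scale — a strongly sweep-driven stereotype, chosen so the
  planted locus carries most of the between-breed trait variance, as the
  design assumes of its mappable traits.
* **Bookkeeping**: uniform missingness (default 1%), dosages oriented to
  the cohort minor allele, X treated as autosomal diploid (array cohorts
  of unrecorded sex are conventionally analyzed as all-female), and full
  determinism: the same configuration and seed reproduce every byte.

Not emulated: linkage-disequilibrium decay and recombination maps,
coalescent noise, genotyping error, and ascertainment bias of array SNPs.
Passing tests therefore certify the *algorithms* against their stated
definitions and against planted truth under idealized population-genetic
structure; they do not certify calibration on real canine array data.

## Problem sizes and numerical conventions

The test suite runs its calibration studies at deliberately desk-scale
sizes, stated here as the package's reference conditions: the null
calibration aggregates 2,000 replicates of 12 breeds x 10 dogs x 1,000
SNPs; locus recovery and fine-mapping use 100 replicates of the canned
12-breed fixture (2,000 SNPs, one planted sweep); the phasing oracle runs
500 random small datasets; prediction power uses 20 replicates of the
24-breed two-locus fixture. `scripts/acceptance.R` recomputes the same
quantities at reduced replicate counts and records each with its problem
size. Other conventions: eigenvalues of $K$ are clamped at zero;
likelihood ties in $\lambda$ resolve to the smaller value; quantile-based
region thresholds are strict inequalities so a constant statistic surface
calls no regions; stepwise tie-breaks follow candidate order.

## Known limitations

* With a dozen breeds the effective sample size of any breed-constant
  phenotype is the number of breeds; weak planted effects are genuinely
  unrecoverable in this design, and the fixtures do not pretend otherwise.
* The $d_i$/$s_i$ implementations follow the verbal definitions of the
  published tracks; numerical agreement with any specific published values
  is not expected, since the original windowing and estimator details are
  not restated here.
* The success criterion for prediction is a configurable stand-in; no
  specific published cell-level rule is reproduced.
* PED/MAP parsing targets well-formed text files of the two supported
  dialects; binary PLINK and VCF inputs are out of scope.
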