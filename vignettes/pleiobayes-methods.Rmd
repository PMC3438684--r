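---
title: "Pleiotropic Bayesian model search and genetic risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropic Bayesian model search and genetic risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiobayes)
```

## The problem

A genome-wide association study (GWAS) with two dichotomous phenotypes
$D_a$ and $D_b$ (each coded 1 = unaffected, 2 = affected) may contain
*pleiotropic* loci: SNPs whose genotype distribution depends on both
traits at once.  A conventional single-trait scan models each SNP against
one phenotype and is blind to the joint structure; it loses power on
pleiotropic SNPs and cannot exploit a known secondary phenotype when
predicting the primary one.  `pleiobayes` implements a two-phase Bayesian
alternative:

1. **Phase I** scores every SNP under a small set of association models
   and inheritance codings, selects the best-supported model per SNP, and
   ranks the retained SNPs by their log Bayes factor against the null.
2. **Phase II** chooses how many top-ranked SNPs to carry into a
   classifier, by cross-validated AUC.

The ranked SNPs feed naive-Bayes-style classifiers that predict $D_a$
marginally (genotype only), conditionally (genotype plus known $D_b$), or
naively (a single-trait classifier trained without $D_b$), each as a
single classifier or an ensemble.

## The model space

A SNP $S$ takes the genotype values AA, AB, BB.  Four inheritance codings
map genotypes to categories: genotypic ($1=$AA, $2=$AB, $3=$BB), dominant
($1=$AA, $2=\{$AB$\mid$BB$\}$), recessive ($1=\{$AA$\mid$AB$\}$,
$2=$BB), and allelic, in which each genotype contributes its two alleles
as separate observations.  Four association models relate $S$ to the
phenotypes: the null $M_0$ (no dependence), the single-trait models $M_a$
and $M_b$, and the pleiotropic model $M_{ab}$ in which the genotype
distribution depends on the joint class
$(D_a, D_b) \in \{(1,1),(1,2),(2,1),(2,2)\}$ (always in that order).

Each model/coding pair defines a contingency table with $q$ phenotype
rows ($q = 1, 2, 2, 4$ for $M_0, M_a, M_b, M_{ab}$) and $c$ genotype
categories.  Rows are scored with a symmetric Dirichlet prior with
pseudo-count $\alpha$ per cell, giving the closed-form compound
(Dirichlet-multinomial) marginal likelihood

$$\ln p(S \mid D, M) = \sum_j \Big[ \ln\Gamma(c\alpha)
  - \ln\Gamma(n_{j\cdot} + c\alpha)
  + \sum_s \big( \ln\Gamma(n_{js} + \alpha) - \ln\Gamma(\alpha) \big)
  \Big].$$

**Prior pseudo-count.** We use $\alpha = 4/q$ for the model being scored
(so the null, with $q = 1$, gets $\alpha = 4$).  This makes the scoring
prior identical to the smoothing constant $a_v = 4/q$ used by the
prediction tables below, so one prior convention governs the whole
package.  $\alpha$ is configurable in `pleio_scan()`.

**Matched nulls.** A Bayes factor only makes sense between models of the
same data representation, so the null marginal likelihood is always
computed under the same inheritance coding as the alternative (an allelic
alternative is compared with an allelic-coded null).  The cross-coding
argmax in phase I then compares these per-coding Bayes factors directly.

## Phase I

For every SNP the 8 single-trait models ($M_a, M_b \times$ 4 codings) are
scored against their matched nulls and the largest $\ln BF$ wins; SNPs
with $\ln BF > 1$ (configurable) are retained.  For retained SNPs the
pleiotropic model is then evaluated *under the first-pass winning
coding*, with $q = 4$ rows, and selected only when its marginal
likelihood strictly exceeds the first-pass model's — ties keep the
simpler model.  The final ranking statistic is the Bayes factor of the
*assigned* model against the matched null, recomputed for $M_{ab}$
upgrades; ranking ties are broken by genomic order, so results are
deterministic.

Two design points were genuinely open and are decided as follows:

* The pleiotropic pass could have re-searched all four codings; we
  evaluate $M_{ab}$ only under the winning first-pass coding.  This is
  the cheapest reading of the two-pass structure and keeps the second
  pass a strict refinement of the first.
* The ranking Bayes factor for upgraded SNPs uses the $M_{ab}$-vs-null
  comparison rather than the first-pass value, matching the rule that
  ranked SNPs are compared through "their selected models".

Missing genotypes are dropped per SNP (complete cases); a SNP with no
observed genotypes is never retained.  The naive search is the same
machinery restricted to $M_a \times$ 4 codings with no second pass.

## Prediction

Classifiers always use the genotypic (3-category) coding, whatever coding
won the search, because it nests the others.  For the SNP at rank $i$
with assigned model $M_i^*$, the smoothed conditional probability table is

$$P(S_i = s \mid D = d, M_i^*) =
  \frac{n_{ijs} + a_v}{n_{ij\cdot} + 3 a_v}, \qquad a_v = 4/q,$$

whose rows sum to one exactly and never contain zeros, so posterior odds
are always finite.  With SNPs conditionally independent given the joint
class, the posterior over the four classes given a profile $\vec s$ and
the nested set $\Sigma_r$ is proportional to
$P(D = d)\prod_{i \le r} P(S_i = s_i \mid D = d, M_i^*)$; a SNP with a
single-trait model contributes the same factor to both values of the
other trait.  Products are accumulated in log space and normalized by
log-sum-exp, so long products cannot underflow.

The odds-form statistics for predicting $D_a = 2$ are the marginal ratio
(secondary trait summed out), the conditional ratio (known $d_b$), and
the naive two-class ratio; the ensemble variants average the *normalized*
class posteriors of the classifiers built on $\Sigma_1, \dots, \Sigma_r$
before taking the ratio.  The decision rule predicts class 2 when the
statistic strictly exceeds the threshold $T$, with $T = 1$ the Bayesian
rule.

**Class prior.** The default prior over the joint classes is uniform even
on unbalanced data.  The $T = 1$ rule is only the optimal 0-1-loss rule
under balanced priors, and the method's published behaviour on
unbalanced designs (sensible sensitivity at $T = 1$) is only reproduced
by a balanced prior; an empirical-prior option is provided for users who
want calibrated posteriors instead.

Subjects missing a genotype at a ranked SNP simply skip that factor —
no imputation.

## Phase II

The discovery set is split into stratified folds (default 10; LOOCV
available), stratifying on the joint phenotype class.  Phase I is re-run
from scratch on each training split — the held-out subjects touch neither
the search nor the smoothed tables, which a leakage test verifies — and
the held-out subjects are scored for every $r$ up to `r_max` (default
200).  Out-of-fold statistics are pooled across folds before computing
sensitivity, specificity and the Mann-Whitney AUC per $r$: pooling keeps
the AUC defined under LOOCV, where per-fold AUCs do not exist.  The
selected size $r^*$ is the smallest $r$ attaining the maximal AUC.  An
alternative decision threshold $T^*$ maximizes Youden's
$J = \text{sens} + \text{spec} - 1$ over the midpoints of consecutive
distinct pooled scores (plus below-minimum and above-maximum candidates,
smallest threshold on ties); internally the search runs on the log-odds
scale, where midpoints are geometric-mean midpoints of the odds.

## The simulator

`simulate_study()` emulates the evaluation design: a case-control GWAS
with two dichotomous phenotypes, exact per-class subject counts, and all
SNPs independent.  Null SNPs follow Hardy-Weinberg genotype frequencies
$(p^2, 2pq, q^2)$ with minor allele frequency drawn per SNP; causal SNPs
draw a MAF, a disease allele (A or B), an odds ratio uniform within the
scenario bounds, and an inheritance mode (dominant, recessive, or
additive).  Affected classes tilt the Hardy-Weinberg baseline by genotype
risk weights and renormalize: weight $OR$ on carriers (dominant) or risk
homozygotes (recessive), and $\sqrt{OR}^{x}$ with $x$ the disease-allele
count for the additive mode, so the homozygote-versus-homozygote odds
ratio equals the assigned $OR$.  Pleiotropic SNPs multiply the two
traits' weights in the doubly-affected class — additivity on the log-odds
scale.

Choices worth flagging:

* **MAF pool.** The original evaluation drew MAFs from a genotyping-array
  manifest that is not redistributable; the default pool is
  $\mathrm{Uniform}(0.05, 0.5)$, and `maf_pool` accepts a user-supplied
  list.
* **Scenario table repair.** The published Set-1 scenario table's name
  and sample-size columns contradict each other; the presets follow the
  scenario *names* (odd scenarios 1500 subjects, even 4000), the reading
  consistent with accuracy increasing in sample size within each effect
  level.
* **Balance.** "Balanced" scenarios use equal counts in all four joint
  classes, the simplest reading consistent with both margins being
  balanced.  The no-pleiotropy scenarios do not state a sample size; the
  presets default to 4000 discovery subjects.

What the simulator does *not* emulate: linkage disequilibrium (all SNPs
independent), rare variants (MAF $\le 0.05$), quantitative traits,
genotyping error and missingness.  Passing tests therefore demonstrate
correctness of the method under its own assumptions, not performance on
real genomes, where LD and confounding will matter.

## Numerical and scale choices

All likelihoods are natural logs; posterior normalization is by
log-sum-exp; the AUC uses average ranks (ties count one half).
Degenerate inputs are defined: an empty nested set returns the prior, a
scan with fewer than two subjects in a phenotype class warns and returns
an empty ranking, constant scores give a below-minimum Youden threshold.

The published evaluation used 500,150-SNP assays with 100 replicates per
scenario — several CPU-months.  The package's own reproduction
(`scripts/acceptance.R`) keeps every scenario parameter but reduces the
null SNP count to 20,000 and runs 20 replicates per scenario, sizes
chosen so the whole suite completes on a single desk CPU while leaving
the replicate means well within the published between-replicate spread;
the test suite uses 5,000 nulls and 6 replicates.  Fewer null SNPs mean
proportionally fewer chance false positives in the ranking tail, which
nudges selected-model accuracy up by roughly half a percentage point at
these sizes — visible but small against the published replicate SDs.

## Known limitations

Only two dichotomous phenotypes; no covariates; conditional independence
of SNPs given class (no LD modelling); the Dirichlet pseudo-count
convention, while internally consistent, is a package choice rather than
a published constant, and very different choices would shift Bayes
factors near the retention threshold.
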