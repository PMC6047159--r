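---
title: "Methods: maternal-genotype GWAS of breast-milk fatty-acid composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal-genotype GWAS of breast-milk fatty-acid composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkgwas)
```

## The problem

Breast-milk fatty-acid (FA) composition is a maternal phenotype, but in many
mother–infant cohort designs only the infants are genotyped.  Because a child
carries exactly one maternal allele at every autosomal locus, the infant's
genotype is informative about the mother's, and a genome-wide association
study (GWAS) of milk composition can be run against *imputed maternal
genotypes*, provided the imputation uncertainty is carried through the test
rather than collapsed to a best guess.  `milkgwas` implements that pipeline:

1. maternal genotype posteriors from infant genotypes (Mendelian
   transmission + Hardy–Weinberg equilibrium, HWE);
2. compositional phenotype preparation (26 assayed %wt/wt FA fractions plus
   7 derived summaries, variance-stabilising transforms);
3. an uncertainty-aware ("missing data") score test with covariate
   adjustment;
4. per-variant QC filters (allele frequency, IMPUTE-style info score, exact
   HWE test in infants);
5. fixed-effects inverse-variance meta-analysis across studies;
6. multiplicity correction across correlated phenotypes by the
   eigenvalue-based effective-test count;
7. conditional regional scans and locus grouping;
8. a synthetic dyad-cohort generator so every stage is testable without any
   cohort data.

## Maternal genotype posteriors

Let $p$ be the reference-allele frequency and count genotypes as the number
of reference alleles.  With the mother drawn from HWE, the father treated as
an unobserved random population member at the same $p$ (the only assumption
consistent with the premises; no assortative-mating option is provided), and
Mendelian transmission, conditioning on the infant count $c$ gives, in the
order $(\pi_0,\pi_1,\pi_2)$:

* $c=0$: $(1-p,\; p,\; 0)$
* $c=1$: $\bigl(\tfrac{1-p}{2},\; \tfrac12,\; \tfrac{p}{2}\bigr)$
* $c=2$: $(0,\; 1-p,\; p)$

A hard infant call forbids the Mendelian-inconsistent maternal homozygote,
and averaging the three posteriors over the infant's own HWE marginal
recovers the maternal HWE prior.  These closed forms are verified in the
test suite against a brute-force enumeration of all nine mother x father
genotype pairs.  When the infant genotype is itself probabilistic (imputed),
the maternal posterior is the convolution of the two uncertainty sources,
i.e. the mixture of the closed forms weighted by the infant triple.  A
missing infant genotype contributes no information and yields the maternal
HWE prior.  Monomorphic variants are dropped (the posterior is degenerate
and only polymorphic sites are analysed).

Reference-allele frequencies default to estimates from the infant cohort
($\hat p = \sum_i \mu_i / 2n$ with $\mu_i$ the posterior-mean count), as
published cohort frequencies are, and can be overridden per variant.

The amount of surviving genotype information is summarised by the
IMPUTE-style score $\mathrm{info} = 1 - \sum_i v_i / (2n\hat p(1-\hat p))$,
with $v_i$ the per-sample variance of the count; hard calls give 1, triples
at the HWE prior give 0.

## Compositional phenotypes

The 26 assayed fractions are %wt/wt of total identified FA and sum to 100
per mother (closure).  Seven derived phenotypes are simple class sums
(saturated SFA, cis-monounsaturated MUFA, omega-6 and omega-3
polyunsaturated PUFA6/PUFA3, trans TFA, total PUFA = PUFA6 + PUFA3) plus the
PUFA6/PUFA3 ratio — 33 phenotypes in all.  All fraction phenotypes are
natural-log transformed to stabilise variance, so a multiplicative
per-allele genetic effect is additive on the analysis scale; the ratio is
square-root transformed, and its effects are reported as
$2\sqrt{s_0}\,\hat\beta$, the change in the ratio per allele at a
standardisation point $s_0 = 12$ (a typical cohort mean).  Zero fractions
under log are excluded per phenotype (complete-case within phenotype), not
globally, preserving sample size for unaffected phenotypes.

Multiplicity across the correlated phenotypes is corrected with the
eigenvalue-based effective-test count (Li–Ji form): with eigenvalues
$\lambda_i$ of the phenotype correlation matrix,
$M_\mathrm{eff} = \sum_i [\,I(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)\,]$, clamped to $[1, K]$; the simpler variant
without the floor term is available for sensitivity analysis.  The
experiment-wise threshold is $\alpha_\mathrm{gw}/M_\mathrm{eff}$; with the
conventional $5\times10^{-8}$ and 12.0 effective phenotypes this is
$4.2\times10^{-9}$.  Which data entered the published correlation matrix
(raw vs transformed, pooled vs per-study) is not stated anywhere we could
re-derive it from; `phenotype_correlation()` therefore takes any phenotype
table, and we default to the pooled transformed phenotypes.  Tiny negative
eigenvalues of near-singular matrices are clamped to zero, and eigenvalues
a float-epsilon below an integer are guarded before the floor.

## The missing-data score test

For a transformed phenotype $y$ the null model is least squares on an
intercept plus covariates (maternal age, infant age at milk sample, infant
sex, and study site where it varies), with the maximum-likelihood variance
divisor $n$ (the score-test convention).  With per-sample posterior moments
$\mu_i$ and $v_i$ of the maternal count, null residuals $r_i$, leverages
$h_{ii}$, and residual projector $M$ (always applied through the QR factors):

$$U = \sum_i \mu_i r_i/\hat\sigma^2, \qquad
I_\mathrm{complete} = \bigl(\mu' M \mu + \textstyle\sum_i v_i(1-h_{ii})\bigr)/\hat\sigma^2,$$
$$I_\mathrm{missing} = \sum_i v_i r_i^2/\hat\sigma^4, \qquad
V = I_\mathrm{complete} - I_\mathrm{missing},$$

$S = U^2/V \sim \chi^2_1$ under the null; the one-step effect is
$\hat\beta = U/V$ with $\mathrm{SE} = V^{-1/2}$.  This is the
observed-information (complete-minus-missing) construction for a latent
three-class genotype: genotypes are never collapsed to an expected dosage.
When every triple is hard the statistic reduces *exactly* to the classical
OLS score test and $\hat\beta$ to the OLS slope — a reduction the suite
checks to $10^{-8}$ relative on random datasets.  Variants whose genotype
uncertainty drives $V \le 0$ are flagged untestable rather than reported.

Two properties are treated as the test's acceptance surface and verified by
simulation: null calibration (uniform p-values; empirical type-I error at
its nominal level) and the information ordering (soft genotypes never carry
more information than the underlying hard ones).

### Effect estimation away from the null

The one-step $\hat\beta = U/V$ is exact under hard genotypes, but with
heavily convolved maternal posteriors (roughly a quarter of the hard-call
information at a typical allele frequency) it acquires a small
away-from-zero bias and understates its sampling variance at moderate
effect sizes, because the curvature of the observed-data likelihood changes
between the null and the estimate.  For *reporting* effect sizes the
package therefore also provides `ml_effect()`: maximum likelihood in the
latent-genotype mixture model fitted by EM, with the standard error taken
from the numerically differentiated observed-data log-likelihood.  Under
hard genotypes EM reduces to OLS in one step.  In the lead-variant
simulation scenario (allele frequency 0.17, multiplicative effect 0.85 on
the arachidonic-acid fraction, 1142 dyads, mothers imputed from infants)
the ML estimate is unbiased and its 95% CIs cover the truth at close to
nominal rate, which is what the recovery checks assert; p-values always
come from the score statistic.

Effects on log phenotypes are reported exponentiated (multiplicative change
in the fraction per reference allele, e.g. 0.85), together with the
equivalent per-*major*-allele percent increase $(1/e^{\hat\beta}-1)\cdot
100$ (≈17% for 0.85) when the multiplicative effect is below 1.

### Conditional models

Conditional scans append either the transformed conditioning phenotype
(e.g. log AA) or the conditioning variant's posterior-mean maternal dosage
as a covariate.  A covariate column cannot carry a probability triple, so
dosage is the coherent choice for variant conditioning; conditioning a
phenotype on itself leaves zero residual variance and is flagged degenerate
rather than tested.

## Meta-analysis, filters, loci

Per-study effects on the common transformed scale are combined with
inverse-variance weights $w_k = \mathrm{SE}_k^{-2}$:
$\beta_\mathrm{meta} = \sum w_k\beta_k/\sum w_k$,
$\mathrm{SE}_\mathrm{meta} = (\sum w_k)^{-1/2}$, two-sided normal p, and a
per-study direction string ("--", "+-", ...).  Allele orientation must
match exactly across studies — silent strand flipping is the classic
meta-analysis bug, so there is no auto-flip.  The screening filter keeps
variants with MAF > 0.05 when present in both studies (MAF > 0.1 when in
only one), info = 1 in every contributing study, and infant exact-HWE
p > 1e-5; the permissive regional mode relaxes to info > 0.9 and
MAF > 0.05.  The HWE filter uses an exact conditional test on the
heterozygote count (the asymptotic test misbehaves exactly where the filter
matters, at rare-genotype configurations); whether the original screening
used an exact or asymptotic test is unstated, and the exact test is the
safer default.  Genomic-control inflation is computed and attached as a
diagnostic but never applied as a correction.

Significant variants are grouped into loci by transitive physical proximity
with a 500 kb merge window (no operational locus definition is published;
the window is exposed as an argument), each locus reporting its lead
(smallest-p) variant and member counts at the experiment-wise and
genome-wide thresholds in the "n/m" convention.  Results are ranked by
combined significance with position as the tie-break, which makes scan
output invariant to variant input order.

## The synthetic dyad generator

The generator inverts the inference model, so parameter recovery is a
meaningful end-to-end check:

* Mothers and fathers are i.i.d. HWE draws at each variant's configured
  reference-allele frequency; each infant receives one allele drawn
  uniformly from each parent.  Mendelian consistency is exhaustively
  checkable.
* FA profiles are multivariate log-normal: per-fraction moments are matched
  to a built-in cohort reference profile
  ($\sigma^2_{\log} = \log(1+\mathrm{CV}^2)$,
  $\mu_{\log} = \log(\mathrm{mean}) - \sigma^2_{\log}/2$), with defaults
  taken from the published Bangladeshi cohort summary tables
  (`fa_reference()`; the PROVIDE GWAS column of 532 mothers is the default,
  with the second PROVIDE column and the two CRYPTO site columns
  available).  The two-study scenarios in the tests use the PROVIDE and
  CRYPTO Mirpur profiles at the published post-QC sizes 532 and 610.
* Genetic effects multiply a target fraction by
  $\mathrm{factor}^{(\text{maternal count})}$ — the phenotype is maternal,
  so the effect acts on the mother's genotype and the infant is only the
  observation channel.  Covariate effects, when configured, add on the log
  scale; by default none are simulated, since no covariate effect sizes are
  published — covariates then exercise the adjustment machinery without
  changing the truth.
* The 26 fractions are then closed to sum exactly 100.  Closure slightly
  attenuates realised effects on large fractions; for trace fractions such
  as arachidonic acid (~0.5% of total) the attenuation is negligible, which
  the recovery tests confirm.  Note that a configured effect adds variance
  on top of the moment-matched marginal, so a strongly affected fraction's
  realised SD slightly exceeds its target.
* The latent correlation uses exchangeable within-class blocks
  ($\rho_w = 0.5$) and a negative SFA–PUFA coupling ($-0.3$), other blocks
  independent.  The published correlation structure is a heat map with no
  printed values, so these defaults are qualitative stand-ins, fully
  configurable, and positive semi-definiteness is verified numerically
  before sampling.
* Imputation uncertainty is emulated by `degrade_to_probabilistic()`: the
  true class keeps probability $c$ and the rest is split between the other
  classes in proportion to their (HWE) priors; $c = 1$ is exact, $c = 1/3$
  with uniform priors is fully uninformative, and the info score decreases
  monotonically in $c$.

What the generator does *not* emulate — and what passing tests therefore do
not establish for real data: linkage disequilibrium between variants
(variants are independent, so locus grouping and conditional analyses are
exercised on mediation rather than LD structure), genotyping or assay batch
effects, longitudinal changes across milk stages (one specimen per mother),
and real covariate–phenotype confounding.

## Numerical choices

* Triples renormalised on input; raw sums outside [0.98, 1.02] are
  rejected; missing is (0,0,0) and is excluded from per-variant statistics.
* GEN dialect: five leading columns (chrom, snpid, pos, refA, altA),
  probabilities written hom-ref, het, hom-alt with allele A = reference,
  6 significant digits (round-trips far below the 1e-6 container
  tolerance); 1-based, fully closed coordinates; no liftover.
* VCF: GT and GP fields only, through `vcfR`; GP arrives in P(0/0), P(0/1),
  P(1/1) order and is reversed into reference-count order.
* Null fits use a QR factorisation; rank deficiency is an error naming the
  collinear columns; $V \le 10^{-10}$ flags a variant untestable;
  $\hat\sigma^2 < 10^{-12}$ flags a null fit degenerate.
* EM: 200-iteration cap, 1e-9 parameter tolerance, log-probabilities
  floored at 1e-300; SE by `optimHess` on $(\beta, \alpha, \log\sigma^2)$.
* Reproducibility: a simulation config carries one integer seed;
  genotype and phenotype stages derive fixed sub-seeds from it, so a fixed
  config is bit-identical end to end.

## Problem sizes used by the checks

The test-suite simulations are sized to be decisive yet quick: null
calibration uses 20,000 independent variants at n = 1000 (Kolmogorov–
Smirnov uniformity at $\alpha$ = 0.01 and a 99% binomial interval around
the nominal 5% level); effect recovery uses 200 replicates of the
lead-variant scenario at the published combined size n = 1142; generator
moment checks use n = 5000; oracle comparisons (trio enumeration, OLS
reduction, HWE enumeration at n ≤ 20) are exhaustive or near-exhaustive.

## Known limitations

* The score information uses the null-model $\hat\sigma^2$; away from the
  null the one-step effect is mildly biased (hence `ml_effect()` for
  reporting).
* No X-chromosome special-casing, no multi-allelic sites, no paternal or
  sibling genotypes, no phasing, no kinship/mixed-model adjustment, no
  principal-component covariates in the screening model, and no LD-aware
  clumping — matching the scope of the analysis the package reimplements.
* The published effective-phenotype count (12.0) cannot be re-derived
  without the original cohort correlation matrix; the package computes
  $M_\mathrm{eff}$ from whatever phenotype table it is given and treats
  12.0 as an input when reproducing the published threshold.
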