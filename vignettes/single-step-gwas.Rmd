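---
title: "Single-step GBLUP GWAS: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GBLUP GWAS: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssGWAS)
```

## The problem

Livestock populations record phenotypes on very many animals but genotype
only a fraction of them. Single-step GBLUP (ssGBLUP) fits one animal model

$$ y = Xb + Za + e, \qquad a \sim N(0,\ \sigma^2_a H), \quad
   e \sim N(0,\ \sigma^2_e I) $$

in which the additive-genetic covariance $H$ merges pedigree expectations
(the numerator relationship matrix $A$) with marker-realised relationships
(the VanRaden genomic matrix $G$) through its inverse

$$ H^{-1} = A^{-1} +
   \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1} \end{bmatrix}, $$

where $A_{22}$ is the pedigree block of the genotyped animals and $G^*$ a
blended, rescaled $G$. Genomic breeding values (GEBVs) $\hat a_g$ of the
genotyped animals are then converted into per-marker allele-substitution
effects by the back-solve

$$ \hat u = \lambda D W' G^{*-1} \hat a_g, \qquad \lambda = \frac{1}{2\sum_j
   p_j(1-p_j)}, $$

with $W$ the centred dosage matrix and $D$ per-marker weights (identity
here: unweighted single-pass ssGWAS). Marker p-values, Bonferroni
significance ($0.05/m$) and suggestive ($1/m$) thresholds, strong-LD runs
around the top region, gene annotation and hypergeometric term enrichment
complete the GWAS workflow. The package implements every stage, plus a
gene-dropping simulator so the whole chain can be validated against known
truth.

## Variance components: AI-REML

`aiReml()` maximises the restricted likelihood in
$(\sigma^2_a, \sigma^2_e)$ by average-information updates. All derivatives
come from mixed-model-equation identities rather than dense $V^{-1}$:
$P y = \hat e/\sigma^2_e$, $\operatorname{tr}(P Z H Z') =
(q - \lambda\,\operatorname{tr}(H^{-1}C^{aa}))/\sigma^2_a$ with $C^{aa}$
the animal block of the inverse coefficient matrix, and the AI matrix is
built from the working variates $Z\hat a/\sigma^2_a$ and
$\hat e/\sigma^2_e$ (two extra MME solves per iteration). Whenever an AI
step would leave the parameter space, an EM step — which cannot decrease
the restricted likelihood — is taken instead. Defaults: start at half the
phenotypic variance for each component, relative tolerance `1e-8`, at most
200 iterations; non-convergence returns the current estimates flagged
`converged = FALSE`. The standard error of $h^2 =
\sigma^2_a/(\sigma^2_a+\sigma^2_e)$ uses the inverse AI matrix and the
delta method; other delta-method variants would be equally defensible, so
the reported SE should be read as *a* first-order approximation, not *the*
SE. The whole path is validated in the test suite against direct
maximisation of the explicit dense REML log-likelihood.

The implementation factorises the coefficient matrix densely (guarded at a
few thousand equations) because the AI traces need the full $C^{aa}$
block; that is the intended desk scale of this package. `solveMME()` also
offers a sparse solve when no inverse blocks are requested.

## Relationship matrices

* `aMatrix()` is the tabular method; `inbreeding()` is the Meuwissen–Luo
  ancestor recursion, so $F$ scales past dense limits; `aInverse()`
  applies Henderson's rules *with* inbreeding (Mendelian-sampling variance
  $\tfrac12 - \tfrac14(F_s + F_d)$, adjusted when a parent is unknown).
  We always include inbreeding in $A^{-1}$: it is exact, and omitting it
  is the only reason estimates could drift from software that drops it.
* Unknown parents are treated as draws from one non-inbred base
  population; no unknown-parent groups or metafounders.
* `a22Matrix()` evaluates the tabular method on the pedigree pruned to
  genotyped animals and their ancestors, then slices — exact, and cheap at
  desk scale.
* `vanRadenG()` uses method 1, $G = WW'/(2\sum p(1-p))$, with allele
  frequencies from the genotyped animals themselves (the study gives no
  base-frequency procedure). Note a structural fact exploited by the
  tests: with sample frequencies, $W$ has zero column sums, so $G$ is
  singular by construction.
* `blendTuneG()` therefore first matches the mean diagonal and mean
  off-diagonal of $G$ to those of $A_{22}$ (two-parameter rescaling) and
  then blends $G^* = 0.95\,G_t + 0.05\,A_{22}$ — standard single-step
  practice; both knobs are exposed.

## Genotype QC

Markers are filtered in a fixed order — call rate < 0.90, then MAF < 0.01,
then Hardy–Weinberg exact p < $10^{-6}$ — with each marker attributed to
the first filter it fails; animals are never removed. The HWE test is the
exact conditional test on the heterozygote count (the PLINK-style test),
computed by the stable mid-point recurrence. Missing dosages are
mean-imputed (2p) only for building $G$.

## The ssGWAS back-solve and its p-values

The back-solve uses the *same* blended/tuned $G^*$ as the mixed model, so
the operator and the fitted GEBVs are mutually consistent; when
$G^* = WDW'/k$ exactly, $W\hat u$ reconstructs $\hat a_g$ to machine
precision (a test asserts this, and a second test verifies the exact
duality with ridge-regression SNP-BLUP at matched variance ratio on an
all-genotyped toy). $\lambda$ is the VanRaden scaling $1/k$. Sampling
variances propagate $\mathrm{Var}(\hat a_g) = G^*\sigma^2_a -
C^{aa}_{gg}\sigma^2_e$ (prediction-error covariance from the MME inverse)
through the back-solve operator; $z = \hat u/\mathrm{sd}(\hat u)$ is
referred to the standard normal, two-sided. This is the POSTGSF90-style
construction; markers whose propagated variance is not positive get
p = 1 and a flag rather than a fabricated statistic. Classification is
strict at both cutoffs: significant means $p < 0.05/m$, suggestive means
$0.05/m \le p < 1/m$.

## Linkage disequilibrium

Haplotype frequencies for a marker pair come from unphased dosages by the
standard two-locus EM (only double heterozygotes are ambiguous; the EM
starts from linkage-equilibrium products, iterates to relative tolerance
$10^{-9}$, and its multinomial log-likelihood is non-decreasing — asserted
in tests). Phasing tools are deliberately not involved. From the
frequencies, $D$, $D' = |D|/D_{\max}$ and $r^2$ follow the textbook
definitions. "Strong-LD blocks" are simplified to maximal runs of
consecutive markers whose all pairwise $D'$ reach a threshold (default
0.8, exposed); confidence-interval block definitions need coverage bounds
we have no basis to set. A perfectly symmetric double-heterozygote
likelihood (cis/trans indistinguishable) is resolved deterministically by
the initialisation and flagged `ambiguous`.

## Annotation and enrichment

SNPs inside a gene interval are genic; otherwise the nearest gene on each
side is reported with the unsigned bp gap to its nearer boundary, ties
reported on both sides — strand is ignored for distances. Enrichment is a
one-sided upper-tail hypergeometric test per term against an explicit,
user-supplied universe (the original study's background is unstated, so
the universe is a required input, not a guess). Raw p < 0.05 flags a term,
mirroring common DAVID-style reporting; a Benjamini–Hochberg column is
emitted alongside but deliberately not used for flagging.

## What the simulator emulates — and what it does not

`simConfig()`/`simulateDataset()` generate a closed nucleus-herd-like
population: a founder cohort, discrete generations from random
hierarchical mating (each female of the previous generation mated to one
random male; ~17% male sex ratio, configurable), the youngest animals
genotyped, biallelic markers gene-dropped with Haldane recombination on
per-chromosome maps, and phenotypes $y = \text{HYS} + \text{sex} + a + e$
with herd-year-season effects drawn once per level.

Breeding values support two architectures:

* **pedigree-flow polygenic** (default, `n_qtl = 0`): founders
  $\sim N(0, \sigma^2_a)$, offspring = parent average + Mendelian sampling
  with variance $\tfrac12\sigma^2_a(1-(F_s+F_d)/2)$;
* **genome-borne**: `n_qtl` markers get Normal effects rescaled so the
  QTL share of founder additive variance is exactly `qtl_var_prop`
  (`qtl_var_prop = 1` makes the trait fully marker-determined).

The distinction matters scientifically. A purely pedigree-flow trait has
genetic covariance $A$ even among genotyped animals, so ssGBLUP — which
asserts covariance $G^*$ there — is *misspecified*, and AI-REML visibly
inflates $\sigma^2_e$ under that mismatch while PBLUP stays unbiased. This
is a property of the method, not a defect of the estimator, and the
package's recovery experiments therefore use the genome-borne
architecture (all markers causal), the design under which ssGBLUP is the
generating model, as in typical single-step simulation studies. The
recovery experiment (also run by `scripts/acceptance.R`) simulates 560
founders, 4 generations at one offspring per dam (~1,960 records), half
the animals genotyped at 2,000 markers on 10 one-Morgan chromosomes, with
$\sigma^2_a = 66.74$, $\sigma^2_e = 67.31$ ($h^2 = 0.498$), and averages
ssGBLUP AI-REML $\hat h^2$ over 10 replicate seeds. Problem sizes were
chosen as the smallest at which the estimator's sampling noise is clearly
below the tolerance being demonstrated.

Not emulated: selection and overlapping generations, mutation, sex
chromosomes, genotyping error and real missingness patterns, population
admixture, and the LD of a real 60K chip (our maps are sparse and founder
haplotypes start in linkage equilibrium, so LD arises only from
transmission and drift). Passing tests on these data show the algorithms
are implemented correctly under their own assumptions; they cannot show
robustness to the many ways real pig data violate them.

## Numerical and design choices

* Fixed effects enter as treatment contrasts (reference level dropped per
  factor); aliased columns are removed by QR so confounded configurations
  still solve. Software using generalised inverses reports different
  individual levels but identical estimable functions — tests assert the
  latter kind of quantity only.
* Single global integer seed; pedigree, genotype and phenotype stages
  derive fixed offsets from it, so every dataset is byte-reproducible.
* PLINK text is the genotype interchange format; the counted allele is
  the data minor allele (ties to the lexicographically smaller label),
  "0 0" is missing. Files written by `writeDataset()` are minor-allele
  coded so a write/read cycle reproduces the dosage matrix exactly.
* Dense-materialisation guards: `aMatrix()` at 20,000 animals; dense MME
  inverse blocks at 6,000 equations.
* The pipeline (`runPipeline()`) recomputes every stage on each run;
  no cache layer. At the package's intended scale a full run takes
  seconds to minutes, and recomputation keeps provenance trivially
  correct — every output table carries its thresholds and QC parameters
  in a header comment instead.

## Known limitations

* Single trait, single additive random effect; no maternal, permanent
  environment or multi-trait models.
* AI-REML needs the dense inverse coefficient matrix, capping the desk
  scale at a few thousand animals; an iterative trace-free variant would
  be the natural extension.
* Near the $\sigma^2_a = 0$ boundary the EM fallback converges slowly
  (the AI step keeps proposing negative components); estimates are
  correct but iteration counts grow.
* Variant-class labels (intron/UTR) require transcript structure and are
  out of scope; annotation reports genic/intergenic only.
* The enrichment test treats annotations as given — no ontology-graph
  propagation.
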