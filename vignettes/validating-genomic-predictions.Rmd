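---
title: "Validating genomic prediction equations by bivariate pedigree REML"
author: "gebvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating genomic prediction equations by bivariate pedigree REML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gebvalid)
```

## The problem

A genomic prediction equation (PE) is a vector of per-SNP allele
substitution effects, usually trained in a reference ("training")
population; applying it to an animal's allele dosages gives a genomically
estimated breeding value (GEBV).  The quantity a breeding organisation
cares about is the *accuracy* of those GEBV in its own seed-stock
population: the square root of the fraction of the additive genetic
variance of the target trait that the GEBV explains there.  Accuracies
carried over from cross-validation inside the training population can
mislead - the link between training and target populations may be weak,
and the usual correlation-based estimators are themselves biased when the
animals involved are related or inbred.

`gebvalid` implements the alternative: treat the GEBV as a second trait,
pair it with the phenotypic target trait, and estimate their *genetic
correlation* $r_g$ in a bivariate animal model fitted by REML on the
pedigree of the target population.  $r_g$ is the GEBV accuracy; as a
by-product the analysis yields the heritability of the GEBV
$h^2_{GEBV} = \sigma^2_g / (\sigma^2_g + \sigma^2_{e_g})$, a diagnostic
for genotyping or imputation error (error-free GEBV are linear functions
of dosages and essentially perfectly heritable).

## The bivariate model

Let $\mathbf y$ be the filtered phenotype records of one trait and
$\mathbf y_{GEBV}$ the GEBV records.  For the early weight traits
(200/400/600-day weight) the model is

$$
\begin{pmatrix} \mathbf y \\ \mathbf y_{GEBV} \end{pmatrix} =
\begin{pmatrix} \mathbf X & 0 \\ 0 & \mathbf 1 \end{pmatrix}
\begin{pmatrix} \mathbf b_p \\ b_g \end{pmatrix} +
\begin{pmatrix} \mathbf Z_d & 0 & \mathbf Z_m & \mathbf Z_p \\
                0 & \mathbf Z_g & 0 & 0 \end{pmatrix}
\begin{pmatrix} \mathbf u_d \\ \mathbf u_g \\ \mathbf u_m \\ \mathbf p
\end{pmatrix} +
\begin{pmatrix} \mathbf e_p \\ \mathbf e_g \end{pmatrix},
$$

with contemporary group as the only fixed effect for the phenotype and a
single mean for the GEBV; $\mathbf u_d$, $\mathbf u_g$ and $\mathbf u_m$
are direct genetic (phenotype), direct genetic (GEBV) and maternal genetic
effects, jointly multivariate normal with covariance
$\Sigma_g \otimes \mathbf A$ where $\mathbf A$ is the numerator
relationship matrix; $\mathbf p$ is the maternal permanent environment of
the dam, $\mathbf p \sim N(0, \mathbf I\sigma^2_p)$.  Residuals of the two
channels are correlated ($\sigma_{e_{p,g}}$) *only* for animals observed on
both traits; with zero overlap that covariance is structurally fixed at
zero, and the fitted likelihood is invariant to it - `buildDesign()`
enforces this rule rather than leaving it to the optimizer.  All other
traits drop the maternal terms (the 2-trait direct-effects model).

`A` is built for every recorded animal with (by default) three generations
of ancestors retained (`pruneToGenerations()`, `n_gen` exposed); unknown
parents are treated as unrelated founders and genetic groups are not
fitted.  The sparse `A`-inverse is assembled directly from Henderson's
per-animal contributions with Mendelian-sampling variances from the
Meuwissen-Luo recursion; inbreeding enters by default (switchable, since
some REML programs default otherwise, and the published analyses do not
state their setting).

## REML machinery

The restricted log-likelihood is evaluated exactly through the
mixed-model-equations identity
$-2\,l_R = (n-p)\log 2\pi + \log|\mathbf R| + \log|\mathbf G| +
\log|\mathbf C| + \mathbf y'\mathbf P\mathbf y$,
with one sparse CHOLMOD factorization of the coefficient matrix per
evaluation; the symbolic analysis and all incidence cross-products are
precomputed once per design, so an evaluation is a coefficient update plus
a numeric refactorization.  $\log|\mathbf A|$ falls out of the
Meuwissen-Luo variances at no extra cost.

Maximization runs over an unconstrained parameterization: Cholesky factors
of the genetic block (ordered GEBV-first so that fixing $\sigma_{g,m}=0$,
an identifiability guard on small data, is a single zeroed factor entry)
and of the $2\times 2$ residual block, log-variances elsewhere.  Every
iterate is therefore positive semi-definite by construction.  We use a
quasi-Newton (BFGS) search on this surface rather than classical
average-information updates with EM fallbacks: the stationary point is the
same, and the Cholesky surface removes the need for step-halving
safeguards.  The average-information matrix *is* computed - once, exactly,
at the optimum, using only solves against the final factorization - and
its inverse provides the standard errors; $r_g$ and $h^2_{GEBV}$ get
delta-method standard errors from that covariance.

Numerical choices worth knowing:

* residual and permanent-environment variances are floored at $10^{-9}$
  times the corresponding observed variance - below that the determinant
  and quadratic terms of the MME identity cancel catastrophically, and a
  boundary fit (e.g. error-free GEBV, $\sigma^2_{e_g}\to 0$) simply settles
  at the floor ($h^2_{GEBV}\approx 1$);
* a computed $\mathbf y'\mathbf P\mathbf y$ that comes out negative, or a
  CHOLMOD warning during factorization, marks the evaluation as failed
  (`-Inf`) instead of letting a corrupt value win the line search;
* both channels are standardized internally through the parameter scaling
  (the reported likelihood stays on the data scale);
* convergence is BFGS's relative-tolerance criterion ($10^{-10}$ on the
  log-likelihood) with the flag reported in the result.

`restrictedLogLik()` is exported and is checked against a dense
brute-force restricted likelihood (projecting on the fixed-effect contrast
space of $\mathbf V = \sum \mathbf Z\mathbf G\mathbf Z' + \mathbf R$) on
random toy datasets to $10^{-8}$ in the test suite.

## Phenotype filtering

`applyPhenotypeFilters()` applies, in a fixed order, the record rules used
for the seed-stock datasets: (1) for the early weight traits, records are
dropped unless sire, dam, maternal grandsire and embryo-transfer recipient
dam are all known, and only the first record per animal and trait is kept;
(2) single-record contemporary groups are deleted; (3) where a validation
set is given, records are kept only for validation animals, their direct
progeny, and whole contemporary groups containing such a record - exactly
one contemporary-group step, never the closure of it.  Counts per stage
are logged (the filter report).  Contemporary-group definition itself and
pre-adjustment of raw phenotypes for systematic effects are upstream of
this package: records arrive with a `cg` label and an adjusted value.
The dedup-before-group-pruning order is a declared choice (it prevents
deduplication from creating new singleton groups that would survive); the
source analyses do not state their order.

## Genomic prediction

`trainSnpBlup()` fits ridge-type SNP-BLUP,
$\hat\alpha = (Z'Z + \lambda I)^{-1}Z'(y-\bar y)$ with
$\lambda = 2\sum_k p_k(1-p_k)\,(1-h^2)/h^2$, the choice that makes the
implied GEBV identical to GBLUP breeding values under a VanRaden
method-1 GRM (`buildGRM()`); the identity is asserted to $10^{-6}$ in the
tests.  The assumed $h^2$ is a tuning input, not an estimate.  Monomorphic
SNPs are dropped, missing dosages are mean-imputed ($2p$), and
`applyPE()` reconciles SNP sets by intersection (warning below 50%
coverage).  `crossvalidatePE()` offers animal-wise random folds and
family-aware folds (whole sire groups held out), because relatedness
between folds inflates the apparent accuracy.

`innerProductAccuracy()` is the conventional estimator the REML approach
replaces.  Its `center = FALSE` form takes raw inner products of
expectation-zero vectors; the expectation of such a product is the trace
of the covariance matrix, so when the mean diagonal of the relationship
matrix among the validation animals exceeds 1 the implied covariance - and
an accuracy scaled by an assumed base heritability - is inflated.  The
test suite demonstrates this against the matched REML estimate on inbred
full-sib lines (mean diagonal ~1.3): the naive mean overshoots the true
accuracy, the REML mean does not.

## What the simulators emulate - and what they do not

Two generators provide known truth.

`simulatePopulation()` is the study-shaped generator: several breeds
diverged from a common ancestral pool (Balding-Nichols frequencies at the
breed's $F_{ST}$), discrete generations of random mating within breed with
a small sire fraction (paternal half-sib families, reused dams), QTL that
are by default a subset of the genotyped SNPs with effects
$N(0, \sigma^2_a / 2\sum p_kq_k)$ (optionally jointly drawn with maternal
effects), breed-specific QTL fixed elsewhere (`qtlSharing`), and phenotypes
$y = cg + u_d + u_m(\mathrm{dam}) + pe(\mathrm{dam}) + e$.  The
`hiddenQtl` mode moves all QTL off the marker panel, so markers tag the
trait only through relatedness - the regime in which across-breed
prediction collapses.  Defaults describe a beef-weight-like trait on a
phenotypic-variance-1 scale: $h^2 = 0.3$, and for maternal runs
$m^2 = 0.1$ with a small permanent-environment variance - ordinary values
for weaning-weight-type traits.  Deliberately *not* simulated: linkage
and recombination maps (downstream methods use only genomic/pedigree
covariance), selection (beyond a trivial truncation toggle), genotyping
platforms and imputation.  Passing tests on these populations therefore
says nothing about map-dependent phenomena (LD decay, within-chromosome
structure) in real data.

`simulateBivariateData()` draws records *directly under the bivariate
model* (breeding values $N(0, \Sigma_g\otimes A)$ over a nested-family or
user-supplied pedigree) - the right surface for parameter-recovery
studies, because the generating process and the fitted model coincide and
every component is known.  `driftPedigree()` (small closed populations)
and hand-built full-sib lines supply inbred pedigrees where needed.

All randomness flows from one master seed through named substreams; the
same seed reproduces a population byte for byte.

## The synthetic study replica

`runStudy()` re-creates the across-breed design at desk scale: by default
three weakly diverged breeds (ANG, HER analogues) plus one strongly
diverged breed (BRM analogue, $F_{ST}=0.25$), prediction equations trained
on pooled (ALL) and single-breed subsets with every validation animal
excluded, validation sets of widely used sires plus current-generation
animals (about a quarter of the original breed sample sizes), phenotype
filtering with the connection rule, and a bivariate REML fit per
(validation breed, trait, PE) cell.  A second configuration adds a
validation breed absent from all training subsets under `hiddenQtl` - the
no-pure-breed-representation situation.  The replica targets the
*qualitative* phenomena (pooled-training superiority within represented
breeds; unusable, unstable accuracies for the absent breed); the original
tables' numeric values depend on proprietary data and are out of reach by
construction.

## Monte-Carlo scales used by the test suite

Problem sizes in the acceptance tests are the package's own choices,
picked from pilot power analyses so each asserted bound sits several
Monte-Carlo standard errors from its expected value: the A-inverse
identity uses 100 random pedigrees up to 500 animals; the likelihood
oracle 50 toy datasets of up to ~30 records across both model variants;
parameter recovery runs the full grid ($h^2 \in \{0.2, 0.4\}$, true
accuracy $\in \{0.2, 0.5, 0.8\}$) at n = 2000 records with 20 replicates
per cell - at smaller n the genetic correlation shows a real small-sample
bias at the low-$h^2$/low-accuracy corner, which vanishes at this size.
With 20 replicates a per-cell check of the empirical-vs-delta SE ratio or
of per-component bias would mostly measure replicate noise, so those two
bounds are asserted on grid-pooled summaries at the same thresholds.  The
GEBV-trait heritability is generated at 0.8 so that the smallest
component ($\sigma^2_{e_g} = 0.2$) is estimated with usable relative
precision.  The study replica runs 20 replicates per batch.

## Known limitations

* Maternal components over one-generation pedigrees (founder dams, no
  maternal grandsire links) are poorly separable from direct effects; use
  two-generation designs (`generations = 2`) for maternal recovery work.
  The directional consequence - ignoring a true maternal effect inflates
  the direct heritability - holds regardless and is tested.
* Standard errors come from the average-information matrix at the optimum;
  near boundaries (variances at the floor) it can be singular, in which
  case a pseudo-inverse is used and the affected SEs should be read with
  care (`NA` where not computable).
* The REML surface can be flat for $\sigma_{g,m}$ on small data; `fixGm`
  pins it to zero.
* Dense `A` construction (`additiveRelationshipMatrix()`) is quadratic in
  animals; it is intended for validation-scale pedigrees (thousands), not
  national evaluations.

## A worked call

```{r example, eval = TRUE}
vc <- list(sigma2_a = 0.3, sigma_ag = 0.5 * sqrt(0.3 * 0.8), sigma2_g = 0.8,
           sigma2_ep = 0.7, sigma_epg = 0.1, sigma2_eg = 0.2)
sim <- simulateBivariateData(vc, nRecords = 400, seed = 2)
fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
fit
sim$truth$rg      # generating accuracy
```
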