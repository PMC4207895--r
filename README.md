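# gebvalid

Validation of genomic prediction equations in pedigreed seed-stock
populations, for quantitative geneticists and breeding-program analysts.

A genomic prediction equation (PE) — per-SNP allele substitution effects
plus an intercept — turns an animal's allele dosages into a genomically
estimated breeding value, GEBV = μ + Σₖ xₖ αₖ.  The parameter that decides
whether those GEBV are worth using in a given seed-stock population is
their **accuracy** there: the genetic correlation r_g between the GEBV and
its phenotypic target trait, equal to the square root of the fraction of
additive genetic variance the GEBV explains.  `gebvalid` estimates it the
robust way: GEBV are modelled as observations of a second trait in a
**bivariate animal model** fitted by REML on the population's pedigree,

    y       = Xb + Z_d u_d + Z_m u_m + Z_p p + e_p      (phenotype)
    y_GEBV  = 1 b_g + Z_g u_g + e_g                     (GEBV)

with (u_d, u_g, u_m) ~ N(0, Σ_g ⊗ A), A the numerator relationship
matrix, contemporary group the only fixed effect for the phenotype, and a
residual covariance between the channels only for animals observed on
both.  Maternal genetic and maternal permanent environment effects are
fitted for early weight traits; all other traits use the two-trait direct
model.  The accuracy is r_g = σ_a,g / √(σ²_a σ²_g), with standard errors
from the inverse average-information matrix and the delta method.  The
heritability of the GEBV, h² = σ²_g / (σ²_g + σ²_e_g), doubles as a
genotyping/imputation-error diagnostic (error-free GEBV are ≈ perfectly
heritable).

The package covers the full pipeline:

* **Pedigrees** — reading/validation, generation pruning, the tabular A,
  inbreeding, a Henderson/Meuwissen–Luo sparse A⁻¹, relationship
  summaries between animal sets.
* **Prediction** — VanRaden GRM, ridge SNP-BLUP (exactly GBLUP-equivalent),
  applying and cross-validating PEs, the naive inner-product accuracy
  estimator with its inflation diagnostic.
* **Phenotype preparation** — the seed-stock record filters (weight-trait
  identifier rules, first-record deduplication, single-record
  contemporary-group deletion, validation-connection reduction) with a
  per-stage count report.
* **Bivariate REML** — sparse mixed-model-equations likelihood, Cholesky
  (PSD-guaranteed) parameterization, BFGS maximization, AI-matrix SEs;
  univariate fits with the same machinery.
* **Synthetic data & study replica** — a multi-breed gene-dropping
  simulator with known truth (Balding–Nichols breed divergence,
  breed-specific or hidden QTL, maternal effects) and an orchestrator
  reproducing the across-breed validation design (pooled vs single-breed
  training, a validation breed absent from training).

## Worked example

Simulate records directly under the bivariate model with a known accuracy
of 0.5, then re-estimate it:

```r
library(gebvalid)
vc <- list(sigma2_a = 0.3, sigma_ag = 0.5 * sqrt(0.3 * 0.8), sigma2_g = 0.8,
           sigma2_ep = 0.7, sigma_epg = 0.1, sigma2_eg = 0.2)
sim <- simulateBivariateData(vc, nRecords = 600, seed = 42)
fit <- remlFit(sim$dataset, sim$ainv, maternal = FALSE)
fit
```

```
REMLResult ( plain model ): logL = -1630.1356 (converged)
  r_g = 0.439 +/- 0.138  h2_GEBV = 0.703 +/- 0.0949
         sigma2_a sigma_ag sigma2_g sigma2_ep sigma_epg sigma2_eg
estimate   0.3629   0.2229   0.7110    0.6942    0.1061     0.301
se         0.1052   0.0885   0.1329    0.0877    0.0632     0.085
```

The estimated accuracy r̂_g = 0.44 ± 0.14 covers the generating value 0.5;
the variance components (true values 0.3, 0.22, 0.8, 0.7, 0.1, 0.2) are
each within about one standard error.  On real data the same call takes a
filtered phenotype table and a GEBV table (`assembleTraitDataset()`) plus
an A-inverse from the population's pedigree (`aInverse()` after
`pruneToGenerations()`), with `maternal = "auto"` switching the maternal
terms on for the early weight traits.

A full synthetic study — train PEs on breed subsets, predict into
validation breeds, estimate every accuracy — is one call:

```r
grid <- runStudy(studyDesign(nReplicates = 5, seed = 1))
summarizeGrid(grid)$summary
```

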