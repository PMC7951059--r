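# MYCNimmune

Tools for dissecting how *MYCN* amplification (MNA) reshapes the tumor
immune landscape in bulk expression cohorts — written for computational
biologists studying neuroblastoma and other *MYCN*-driven cancers — and
for deriving a composite prognostic **MYCN immune score**.

The pipeline covers, end to end:

- **Preranked gene-set enrichment** (weighted KS running statistic,
  gene-label permutation null, NES and pooled-null FDR) on
  *MYCN*-correlation or differential-expression rankings;
- **Immune-cell deconvolution**: signature-matrix construction from
  reference profiles and per-sample fraction estimation by linear nu-SVR
  (NNLS fallback) with a permutation significance test;
- the **surface-protein immune interaction network**: STRING-style edges
  (combined score > 400) between differentially expressed tumor surface
  genes (|logFC| ≥ 0.5; knockdown lists at |logFC| ≥ 1) and immune
  population surface proteins (reliable surface location; normalized
  expression score > 1.5);
- **signed co-expression modules** (adjacency ((1+r)/2)^8, topological
  overlap, adaptive branch cutting at minimum size 20) with eigengenes,
  module–trait z-profiles, population composition and hypergeometric
  enrichment;
- **regulon inference** (module-wise over-representation of TF target
  priors), per-sample regulon activity and 3-cluster structure;
- the **MYCN immune score**; per patient, with log2 expression x and
  min-max-normalized weights Ŵ from an L1 logistic MNA model (C = 0.1,
  50 resampling rounds) and a Bonferroni-screened lasso Cox model
  (λ₁ = 0.25):

  immᴾ = (1/nₚ) Σᵢ xᵢ (Ŵᵢᴾᴹ + Ŵᵢᴾᶜ),  immᴺ = (1/nₙ) Σᵢ xᵢ (Ŵᵢᴺᴹ + Ŵᵢᴺᶜ),
  score = immᴾ / immᴺ,

  z-scored within the cohort and stratified at z < −0.5 (low),
  −0.5 ≤ z ≤ 1 (medium), z > 1 (high);
- **survival validation**: Kaplan–Meier/log-rank over score strata,
  multivariate Cox independence, and score–gene-panel correlations.

A first-class synthetic-cohort module (`simulateCohort()`,
`simulateReferenceMixtures()`, `simulateInteractome()`,
`simulateRegulonPrior()`) plants signature genes, proportional-hazards
survival structure, latent-factor modules, mixing fractions and regulons
with full ground truth, so every stage is testable without downloading
cohort data.

## Worked example

```r
library(MYCNimmune)

sim <- simulateCohort(cohortConfig(
  nSamples = 600, mnaFraction = 0.3, nGenes = 2000,
  nPosGenes = 60, posEffect = 1.5, nNegGenes = 40, negEffect = 1.5,
  hazardBetas = list(pos = 0.8, neg = -0.8), noiseSd = 1, seed = 11))

model <- deriveImmuneSignature(sim$cohort,
                               rownames(exprsMatrix(sim$cohort)),
                               seed = 11)
model
#> ImmuneScoreModel:54positive /30negative signature genes; mean held-out AUC 1.000

scores <- computeScores(sim$cohort, model)
table(scores$stratum)
#>
#>    low medium   high
#>    357     63    180

cl <- clinicalData(sim$cohort)
km <- kaplanMeierLogrank(scores$stratum, cl$surv_time, cl$surv_event)
km$p
#> [1] 8.487947e-131
```

The model found 54 positive (MNA/hazard-associated) and 30 negative
(non-MNA/protective) signature genes — of the 60 and 40 planted — with
no noise genes, perfect held-out MNA classification, and the three score
strata separate survival decisively (log-rank p ≈ 1e-131): the high
stratum carries the planted hazard, the low stratum the planted
protection.

## Full pipeline

`runPipeline(config, outDir, seed)` (also callable through
`inst/scripts/run_pipeline.R`) executes every stage on one simulated
cohort and writes per-stage TSV tables plus a JSON run log; runs are
byte-for-byte reproducible given seed and config. See the methods
vignette (`vignettes/mycn-immune-methods.Rmd`) for the model, parameter
and design-decision documentation.
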