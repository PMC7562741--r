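# immunoprofiler

Multi-stage transcriptomic immunoprofiling of inflamed tissue from
small-cohort bulk expression data.

Synovial biopsies from rare inflammatory conditions yield tiny cohorts
(often 3–8 arrays per group), so characterizing the immune infiltrate
cannot rest on any single analysis. This package implements the
complementary stages such studies chain together, each with the
small-sample corrections that regime demands, and a synthetic-data
generator with recorded ground truth so the whole chain is testable
without patient data:

1. **Preprocessing** (`filterLowIntensity`, `detectOutlierSamples`,
   `collapseProbes`) — low-intensity floor (default log2 intensity 2.34),
   automated PC + UPGMA-dendrogram outlier screen, probe→gene collapse.
2. **Moderated differential expression** (`fitModerated`, `adjustBH`,
   `mergeAnnotations`) — empirical-Bayes variance shrinkage: per-gene
   variances *s²_g* (*d_g* df) are pooled toward a prior *s₀²* with *d₀*
   prior df estimated by closed-form moment matching on log *s²_g*,

   *s²_post* = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g),  t = LFC / (s_post·√(1/n₁+1/n₂)),

   referred to t on d₀+d_g df, Benjamini–Hochberg adjusted, gated at
   FDR < 0.2 (chosen a priori to limit false negatives at n≈4 per group).
3. **Cell/function taxonomy enrichment** (`fisherEnrichment`, `enrichAll`)
   — right-sided Fisher exact test per category, sample odds ratio
   OR = ad/bc with Woolf 95% CI (Haldane–Anscombe correction for zero
   cells), OR = 0 flagged for plotting at the CI upper bound.
4. **Co-expression network modules** (`buildTOM`, `detectModules`,
   `computeEigengenes`, `mergeModules`, `correlateTraits`, `qcModule`) —
   soft-threshold adjacency |cor|^β (β = 30), topological overlap matrix,
   average-linkage clustering with a static cut, PAM-style reassignment,
   eigengene merging at dissimilarity 0.2, Pearson module–trait
   correlation (cohort, SLEDAI, anti-dsDNA, C3, C4, CRP) and module QC
   (|r| ≥ 0.5, p < 0.05 is "strong").
5. **Per-sample gene-set scoring** (`expressionStatistic`,
   `enrichmentScores`, `compareGroups`) — Gaussian-kernel CDF statistic
   (bandwidth s_i/4), weighted Kolmogorov–Smirnov random walk per sample,
   Welch t contrast and Hedges g with small-sample correction
   J = 1 − 3/(4(n₁+n₂−2)−1).
6. **Signature refinement** (`spearmanMatrix`, `refineSignature`,
   `mapOrthologs`) — two-pass Spearman co-expression filter: keep genes
   significantly correlated (α = 0.05) with ≥ 25% of the original
   signature, then positively correlated (ρ > 0) with ≥ 25% of the
   refined set; ortholog mapping through a user-supplied table.
7. **Connectivity-score drug-target summaries** (`filterConnectivity`,
   `summarizeTargets`, `rankRegulators`) — perturbagen scores in
   [−100, 100] filtered to [−100, −75] (compounds/knock-downs) or
   [50, 100] (overexpression), agonist/antagonist direction-consistency
   check, per-target n ≥ 2 summaries (range, mean ± SEM, top compound)
   and top-50 upstream-regulator rankings.

`generateExpression`, `generateTaxonomy` and `generateConnectivityTable`
produce inputs with planted fold changes, latent-factor modules tied to
clinical traits, planted category enrichments and planted drug-target
groups, all recorded in a ground-truth object for recovery testing.
`runPipeline` chains every stage from one configuration with plain
CSV/GMT/JSON intermediates and an md5 manifest.

## Worked example

A synthetic two-cohort study (4 cases vs 4 controls, 2,000 genes, 150
planted differential genes at 1–2.5 log2 units, two 120-gene modules):

```r
library(immunoprofiler)
cfg <- pipelineConfig(
  outDir = "demo", seed = 42,
  simulation = simConfig(nGenes = 2000, nPerCohort = c(4, 4),
                         nSignal = 150, lfcRange = c(1, 2.5),
                         nModules = 2, moduleSize = 120, seed = 42),
  network = networkParams(minSize = 60, cutHeight = 0.995))
res <- runPipeline(cfg)
```

Output (abridged):

```
significant genes: 148 of 2000

    category a   or ciLow ciHigh       p significant
1 cellType32 5 5.82  2.15  15.75 0.00344        TRUE
2 cellType01 4 3.76  1.29  11.01 0.03089        TRUE

module sizes:
     blue     brown      grey turquoise
      323       278      1045       354

      module  trait     r       p n
      blue    SLEDAI  0.20 6.3e-01 8
      brown   SLEDAI -0.24 5.7e-01 8
   turquoise  SLEDAI  0.99 3.9e-06 8

   target count             range   mean  sem   topCompound
1 targetA     3 (-95.55)-(-88.04) -91.18 2.25 targetA_cpd03
2 targetB     3 (-88.99)-(-85.40) -87.66 1.14 targetB_cpd03
```

148 of the 150 planted differential genes pass the q < 0.2 gate; the
taxonomy categories seeded with signal genes are the significant ones;
the cohort-differential genes co-cluster into the `turquoise` module,
whose eigengene tracks the disease-activity trait (r = 0.99) while the
cohort-independent planted modules do not; and the planted drug-target
groups are summarized as mean ± SEM over their compounds, strongest
opposition first. At n = 8 the network cut is lowered to 0.995 because
small-cohort background correlations inflate the topological overlap
(see the methods vignette).

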