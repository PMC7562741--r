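---
title: "Methods: small-cohort transcriptomic immunoprofiling"
author: "immunoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-cohort transcriptomic immunoprofiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoprofiler)
```

# Scope and model

This package profiles the immune state of inflamed tissue from a bulk
log2 expression matrix with two small cohorts (case = 1, control = 0)
and a per-sample clinical table. Nothing here assumes more than ~4
samples per group, which drives every statistical choice: variance
moderation for the t-statistics, small-sample bias correction for effect
sizes, Welch rather than pooled contrasts for gene-set scores, and a
pre-specified permissive FDR gate (0.2) so true positives are not
discarded at n = 4.

The central container is `ExpressionBundle`, a `SummarizedExperiment`
with one `exprs` assay, a binary `cohort` column, optional clinical
traits (SLEDAI, anti-dsDNA, C3, C4, CRP) in `colData`, and — for
synthetic data — a ground-truth record in `metadata()`.

# The synthetic-data generator

`generateExpression(simConfig(...))` emulates the structure every
downstream stage assumes, with all planted quantities recorded:

* **Baseline**: per-gene intensities N(7, 1.5²) on the log2 scale with
  residual noise sd 0.5 — the simplest model consistent with log2 array
  data. Defaults: 20,000 genes, 4 vs 4 samples.
* **Signal genes**: a cohort mean shift equal to a recorded LFC with
  magnitude drawn from `lfcRange` (default 0.5–2.5 log2 units, half up,
  half down).
* **Modules**: gene = loading × latent factor + noise, factors N(0,1)
  per sample, loadings uniform on 0.7–1.3 (mild heterogeneity, so
  within-module correlations average ≈ 0.8 at noise sd 0.5 — the range
  reported for strong co-expression modules on arrays).
* **Traits**: SLEDAI is a linear function of configured latent factors
  plus a cohort shift, then rounded and floored at zero; the remaining
  traits carry cohort-level shifts at realistic clinical scales (CRP ~3
  vs ~12 mg/L, C3 ~110 vs ~82 mg/dL, C4 ~20 vs ~13 mg/dL, anti-dsDNA
  ~10 vs ~100 IU/mL). Module–trait correlations therefore have known
  targets.

`generateTaxonomy` mimics curated cell/function classification schemes
(32 cell categories over a 926-gene union; 52 function groups), with
mild overlap between neighbouring categories (such schemes are not
disjoint) and one category constructed to overlap the signal genes at a
configured odds ratio, solved exactly from the 2×2 relation a·d/(b·c).
`generateConnectivityTable` plants drug-target groups with exact or
sampled scores, decoys strictly inside (−75, 50) — outside every filter
window — and one same-side agonist/antagonist pair.

What the generator does **not** emulate: probe-level hybridization,
batch effects, heavy-tailed noise, correlated background genes, or
cohort-size imbalance beyond what is configured. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
generative model, not performance on any real dataset.

# Preprocessing

Low-intensity filtering keeps a gene if *any* sample reaches the cutoff
(i.e., the gene's maximum is at or above it). The alternative — dropping
a gene when any single sample is low — was considered and rejected: it
couples the filter to single-sample noise. The default cutoff 2.34 is
the conventional visual floor for binned log2 array intensities; the IQR
mode (used before gene-set scoring) removes the least variable genes at
a configurable quantile (default 0.5).

The outlier screen automates what is usually a visual call, so it is
deterministic and testable: a sample is flagged only when **both** (i)
its distance from its cohort centroid in PC1–3 exceeds 3× the MAD of all
such distances and (ii) it joins the Euclidean/UPGMA dendrogram last, at
more than 1.5× the previous merge height. Both sub-criteria are reported
separately so a user can inspect borderline cases.

Probe collapse is deterministic: best probe by the stated rule
(`min_p` for DE tables, `max_mean` or `max_kME` for matrices), ties
broken lexicographically by probe id.

# Moderated differential expression

The hierarchical model treats gene variances as s²_g ~ s₀²·F(d_g, d₀).
The prior (d₀, s₀²) is estimated by closed-form moment matching on
log s²_g: the excess of var(log s²_g) over trigamma(d_g/2) identifies d₀
through the inverse trigamma (a Newton solve), and the mean then
identifies s₀². d₀ = 0 reduces exactly to the ordinary pooled t; d₀ = ∞
to a z-statistic with fixed variance. The estimates agree with the
reference empirical-Bayes implementation (limma) to ~1e-14 on shared
fixtures, which the test suite asserts as an independent cross-check —
the package's own fit is always the one used.

Two annotation definitions can be analyzed separately and merged:
the union of genes is taken and a gene present in both keeps its
smaller-p entry (ties: smaller q, then source order). Significance is
re-evaluated per kept entry at the existing gate rather than re-adjusted
across the merged list — re-running BH after a winner-takes-all merge
would make the q-values incoherent with either source list. Genes whose
two entries disagree in LFC sign are kept but reported as discordant.
Deduplication happens after the significance gate, for the same reason.

# Taxonomy enrichment

The right-tail p-value is the exact hypergeometric tail P(X ≥ a). The
odds ratio is the *sample* OR ad/bc — not the conditional MLE — because
the reporting convention for empty overlaps (OR = 0, point drawn at the
CI upper bound on log2-scaled forest plots) requires it. CIs are Woolf
(log-normal) with the Haldane–Anscombe 0.5 added to all cells only when
a cell is zero, which keeps bounds finite for degenerate tables. The
default universe is every gene surviving low-intensity filtering; the
universe is a genuine analysis choice and is exposed as an argument.

# Co-expression modules

Adjacency is |cor|^β, unsigned by default with β = 30 — at n ≈ 8–20,
correlations are inflated and a high power is needed to suppress
background. TOM follows the standard shared-neighbour formula with unit
diagonal. Module detection replaces dynamic tree cutting with a
deliberately simpler, fully deterministic procedure: average-linkage
clustering of 1 − TOM, a **static** cut, dissolution of clusters below
`minSize` (default 100), then a PAM-style pass that reassigns each
unassigned gene to the module with the highest mean TOM similarity when
that exceeds its mean similarity to the unassigned background.

The static cut needs a height strictly inside the dendrogram. With
β = 30, within-module merge heights sit at 1 − TOM ≈ 0.95–0.9995 while
merges involving unrelated genes sit essentially at 1 (background TOM
below 1e-4), so the default cut is 0.9999 — just inside the background
plateau. A dynamic-cut height of 1.0 means "no height constraint" and
has no direct static analogue; an absolute static cut at 1.0 degenerates
to a single cluster. At very small n (≈8), background correlations are
large enough that the plateau moves down; lowering the cut (e.g. 0.995)
is then appropriate and is shown in the README example. Module labels
come from a fixed palette in decreasing size order, so labelling is
reproducible run to run.

Eigengenes are the first right singular vector of the per-gene
standardized module matrix, sign-fixed against the module mean profile;
merging joins modules whose eigengene dissimilarity falls below 0.2
(complete linkage, iterated to stability). Trait correlations are
Pearson over all samples (cohort as 0/1), with pairwise deletion for
missing values. QC reports per-cohort eigengene consistency, the
kME-vs-gene-trait concordance, and a strong/weak call at |r| ≥ 0.5
(boundary inclusive) and p < 0.05.

# Per-sample gene-set scores

The expression statistic is the Gaussian-kernel smoothed CDF
ẑ_ij = (1/n)Σ_k Φ((x_ij − x_ik)/h_i) with bandwidth h_i = s_i/4; genes
are ranked per sample by ẑ and given the symmetric weight |p/2 − rank|.
The walk adds normalized weight^τ on in-set genes (τ = 1 default) and
subtracts 1/(p − |set|) otherwise; the default score is the maximum
positive plus minimum negative deviation ("diff"), with "max" available.

A note on invariance: because ẑ compares each gene to its own
cross-sample distribution, the scores are *exactly* invariant under
per-gene and global affine rescalings (the bandwidth rescales with the
data), and each gene's cross-sample ordering of ẑ is preserved under any
monotone per-gene transform. They are **not** exactly invariant under
arbitrary monotone transforms of a single sample's values — no fixed
gene set can occupy the top of every sample's ranking by construction,
either. The test suite asserts the invariances that actually hold.

Group contrasts use Welch's t (Satterthwaite df, computed in closed form
so constant score vectors degrade gracefully) and Hedges g with
J = 1 − 3/(4·df − 1); at d = 1 and n = 4 vs 4 the mean of g is within
±0.1 of the truth over 1,000 replicates (asserted in the tests).

# Signature refinement

Both passes exclude the candidate gene from its own reference count, and
the fractional threshold uses the ceiling: pass 1 requires significant
correlation (two-sided p < α) with ≥ ⌈f·(k−1)⌉ of the original k-gene
signature, pass 2 requires positive ρ with ≥ ⌈f·(k₁−1)⌉ of the pass-1
set. Self-exclusion and ceiling are the conservative choices where the
procedure's description is silent; two-sided p is used because the
sidedness of "significantly correlating" is unstated (both are exposed
as parameters). The audit trail records per-gene counts at each pass, so
every removal is explainable. P-values use the t-approximation to
Spearman's ρ with mid-ranked ties, matching the conventional `rcorr`
computation.

# Connectivity summaries

Filter boundaries are inclusive (the score windows are quoted as closed
ranges). The direction-consistency check excludes a target before
summarization when its agonists and antagonists both score on the same
side of zero; single-direction targets pass vacuously but are flagged.
SEM uses the n−1 sample sd, so for two compounds SEM = |x₁ − x₂|/2
exactly. Report rounding is half-to-even at two decimals, applied
through an exact decimal snap so values ending in 5 round to the even
neighbour regardless of binary representation. Ties for the top (most
negative) compound break by perturbagen id. Connectivity scores are
inputs; computing them from raw signatures is out of scope.

# Pipeline, determinism, and problem sizes

`runPipeline` chains the stages with plain CSV/GMT/JSON intermediates
and an md5 manifest; a failing stage aborts with its name and a partial
manifest. Every random stage derives from the single config seed, so a
config reruns byte-identically.

The recovery properties asserted by the test suite use deliberately
modest problem sizes — e.g. module recovery on 500 genes × 20 samples
with three 120-gene modules over 20 seeds, scoring power on 1,000 genes
× 8 samples over 200 seeds, Fisher-tail equivalence on 10,000 random
tables with universes up to 2,000 — sizes at which the Monte-Carlo
bands stated in the tests are comfortably resolved while the whole suite
stays quick to run. `scripts/acceptance.R` recomputes the same
quantities end to end at the sizes printed in its source.

# Known limitations

* The static-cut module detector is simpler than dynamic tree cutting
  and can fragment weakly connected modules near the cut; the PAM pass
  mitigates but does not eliminate this. Consensus or bootstrapped
  module stability is out of scope.
* The Fisher universe is an explicit argument because no universally
  correct choice exists; results can shift materially with it.
* The scoring stage's kernel statistic is rank-stable only in the senses
  described above; heavy preprocessing differences between samples can
  move scores.
* Signature refinement assumes ≥ 4 signature genes present and at least
  4 samples; with n ≈ 8 its pass-1 significance filter is weak, which is
  why the decoy-rejection guarantees are stated at n = 20.
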