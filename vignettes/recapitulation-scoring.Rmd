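---
title: "Scoring cross-species recapitulation of a multi-study expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-species recapitulation of a multi-study expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recapitome)
```

## The problem

Animal models of human disease are usually validated on a handful of
phenotypes. A complementary, transcriptome-wide question is: *of the genes and
pathways that characterize the human condition, how many does a given model
reproduce, and in the right direction?* `recapitome` answers this for the
common design in which the human signature comes from several independent
case/control expression studies (for instance old versus young muscle biopsies
across several cohorts) and each candidate model contributes one
model-versus-control contrast in another species.

The pipeline has five stages, each usable on its own:

1. **diffexpr** — per-contrast gene statistics: log2-CPM normalization,
   Welch's *t* per gene, Benjamini–Hochberg adjustment, and a thresholded
   up/down/none call.
2. **meta_vote** — vote-counting meta-analysis: a gene joins the consensus
   signature when at least `min_support` studies (default 2) call it
   differentially expressed *in the same direction*.
3. **orthology** — translation of model-species identifiers into the human
   namespace through an ortholog table.
4. **enrichment** — one-sided hypergeometric over-representation of a gene
   list against a GMT collection; a set with raw `p < dep_alpha` (default
   0.01) is a differentially expressed pathway (DEP).
5. **concordance** — the scores: percentage of human DEPs (and DEGs)
   recapitulated per model, uniqueness partitions and Venn regions, top-N
   pathway tables, biological-category rollups, and gene-level
   direction-of-regulation (quadrant) concordance.

## The vote-counting consensus

Vote counting deliberately avoids pooling effect sizes across platforms:
microarray and RNA-seq fold changes are not on a common scale, so the
consensus asks only for repeated, same-direction significance. Three choices
here were genuinely open and are package decisions:

* **Conflicts.** A gene that reaches `min_support` in *both* directions is
  flagged `conflicted`, excluded from the retained signature, and reported.
  Requiring "the same direction" makes exclusion the conservative reading;
  silent dropping would hide a real cross-study disagreement.
* **Summary effect.** Downstream direction comparisons need one human fold
  change per gene. We use the median log2FC over the studies supporting the
  retained direction — robust to a single outlying platform, and it always
  carries the consensus sign.
* **Universes.** Studies test different gene panels. A gene missing from a
  study's universe counts as "no call" (it is not evidence against), and the
  enrichment background defaults to the *intersection* of study universes —
  the set on which every study could have voted — with union available for
  sensitivity analysis.

## Enrichment

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ with universe size $N$, set size $K$ (after intersecting the set
with the universe), query size $n$ and overlap $k$. Two deliberate choices:
sets that vanish after universe restriction are reported with $p = 1$ rather
than dropped, and **no multiple-testing correction is applied across sets** —
the DEP definition is a raw `p < 0.01`, matching the fixed-threshold
convention of commercial pathway suites that this stage replaces. DEP counts
are therefore collection-dependent: the same signature scored against a
different GMT yields a different number of DEPs, which is why the
recapitulation *percentage* (model DEPs among human DEPs) is the primary
statistic, not the DEP count itself.

## Orthology

The default `one_to_one_only` policy keeps only bijective source/target pairs.
The alternatives (`best_confidence`, `expand_all`) exist for sensitivity
analyses, but a one-to-many mapping lets a single model gene vote several
times in enrichment, which biases recapitulation upward; when a table is
mapped under `expand_all` and two sources collapse onto one target, the row
with the smaller p-value is kept.

## Concordance scores

Gene-level direction concordance pairs the consensus `summary_lfc` with the
model log2FC over the genes in scope (default `shared_degs`: significant in
both the consensus and the model) and classifies each pair by the sign of the
product — the two "same-direction" quadrants of the human-versus-model
fold-change plot. Pairs with an exact zero on either axis sit on a quadrant
boundary; they are excluded and counted separately (`n_zero_excluded`) so
that concordant + discordant = 100% over the judged pairs. Category rollups
apply the same sign rule within biological categories, whose
pathway-to-category assignment is an *input table* — category schemes are
curation, not computation.

## The synthetic generator

Because the real inputs of such analyses are scattered across repositories
and proprietary collections, the package ships a generator whose defaults
emulate a five-study human muscle-aging meta-analysis: 5 studies, 20 case and
20 control samples each, 2000 genes, a planted signature of 200 genes with
signed log2 fold changes (Rademacher sign times |N(1, 0.3)|), each study
carrying any planted effect with probability 0.8. Counts are negative
binomial (dispersion 0.1) with gene-wise log-normal baselines (log-mean
`log(200)`, log-sd 1.5) and per-sample log-normal library-size factors
(sd 0.2) so CPM normalization is non-trivial. A model dataset overlaps the
signature in exactly `round(rho * 200)` genes, keeps the human sign with
probability `kappa`, and adds 50 model-only perturbed genes; `rho` and
`kappa` are thus planted analogues of the recapitulation and concordance
percentages. The single seed expands into fixed per-study substreams, so
adding a study or model never changes earlier data.

What the generator does **not** emulate: microarray intensity scales and
platform-specific preprocessing, batch effects, paired designs, gene-wise
dispersions, and correlated genes. Passing recovery tests therefore shows the
*logic* of the pipeline is right under a realistic count model, not that any
particular real dataset will behave as cleanly.

## Numerical choices and calibration

* Welch's *t* on log2-CPM replaces count-model fitting: the package's
  contribution is downstream of per-study differential expression, external
  DESeq2/limma tables can be ingested verbatim (`ingest_de_table()`), and at
  20 samples per group Welch on log-CPM is close to nominal (the test suite
  checks the type-I rate on null simulations against 0.05 within three
  binomial standard errors over 50 seeds).
* The hypergeometric test is discrete, so its attainable size at a 0.01
  threshold is below 0.01 and depends on $(N, K, n)$. The calibration check
  uses sets of 100 genes and queries of 1000 in a 2000-gene universe, where
  the attainable size (0.0089) is close enough to nominal for an honest
  two-sided band; with small sets the same check would trivially under-reject.
* When both group variances are zero, the Welch p-value is defined as 1 for
  equal means and the smallest positive double otherwise, keeping p in (0, 1].
* Ties in DEP rankings are broken lexicographically by set name so every
  table is reproducible.
* Parameter recovery is asserted at the **DEG level**: `rho` is planted on
  genes, and gene-level recapitulation responds linearly to it, while
  pathway-level recapitulation saturates (a set remains enriched while most
  of its planted members survive). The pipeline reports both levels; the
  pathway level is the headline statistic on real data, the gene level is
  the calibration handle.
* Test and recovery runs use 300–2000 genes and 8–20 samples per group,
  with 10–50 seeds per stochastic property — sizes at which binomial error
  bands are tight enough to be informative while the whole suite stays quick.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
models <- list(combo = model_sim_config(0.7, 0.7, seed = 2),
               aged  = model_sim_config(0.45, 0.65, seed = 3))
bundle <- simulate_bundle(cfg, models, out_dir = "bundle")
report <- run_pipeline(bundle$config_path)
report$pathway_recapitulation
report$gene_recapitulation
report$concordance$combo
```

## Limitations

* Vote counting ignores effect-size magnitude and study precision; it cannot
  be better than its per-study calls, and the per-study significance
  threshold is a user decision (default BH 0.05, no fold-change floor).
* Raw-p DEP calling is collection-dependent and intentionally uncorrected;
  absolute DEP counts should not be compared across collections.
* The quadrant rule judges only direction, not magnitude, of fold-change
  agreement.
* One shared NB dispersion is a simplification; power estimates from the
  generator transfer to real data only approximately.
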