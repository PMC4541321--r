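---
title: "Topological pathway activities from directed gene-metabolite walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological pathway activities from directed gene-metabolite walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drwgm)
```

## The problem

Pathway-level classifiers for two-phenotype omics studies (e.g. benign
vs. tumor, localized vs. metastatic) summarize each pathway into one
activity score per sample and classify on those scores instead of on
thousands of individual genes. The quality of the summary hinges on how
member genes are weighted. `drwgm` weights genes by their *topological
importance* in a directed gene-metabolite metabolic network, estimated by
a random walk with restart that integrates two lines of evidence: which
genes are differentially expressed, and which metabolites are
differentially abundant in a matched metabolomic cohort. Hub enzymes that
sit upstream of many differential metabolites tend to show small but
consistent expression shifts; the walk concentrates weight on exactly
those genes, which stabilizes the activity scores across cohorts.

## Graph model

Each metabolic pathway is a set of reactions. A reaction contributes a
directed bipartite motif: an edge from every substrate compound to every
catalyzing gene, and from the gene to every product compound; reversible
reactions also contribute the opposite edges. Enzymes annotated with
several genes yield one gene node per gene with identical connectivity.
When a compound appears as both substrate and product of one reaction,
both edges are created. Pathway graphs are merged into one global graph
(each gene and metabolite appears once), all edges are **reversed** — so
probability mass later flows from downstream products toward the upstream
genes that generate them — and a ground node is attached with
bidirectional edges to every node. The ground node guarantees that every
node has positive out-degree and that the walk has a unique stationary
distribution; it is excluded from all reporting. Node order is fixed
(genes, then metabolites, lexicographic; ground last) so every matrix and
weight vector is reproducible bit-for-bit.

A gene-only variant contracts the metabolites out: gene `g1` points to
`g2` when some product of a reaction catalyzed by `g1` is a substrate of
a reaction catalyzed by `g2`. It serves as the expression-only baseline.

## The walk

With `M` the row-normalized adjacency matrix (`M[i, j] = 1/outdeg(i)`),
the walk iterates

    W_{t+1} = (1 - r) * t(M) %*% W_t + r * W_0

until the L1 change between consecutive iterates falls below `tol`
(default `1e-10`). The transposed form is the one under which the i-th
entry of `W_t` is the probability of being at node i after t steps. The
restart probability `r` defaults to `0.7`; results are insensitive to
moderate changes because the stationary vector is a geometric mixture of
walk lengths. A sparse direct solve of `(I - (1-r) t(M)) x = r W_0` is
implemented as an independent oracle and cross-checked against the power
iteration in the tests.

The start vector `W_0` encodes the evidence: measured genes get
`-log(p)` from a two-tailed pooled-variance t-test, min-max rescaled to
`[0, 1]` over the measured genes (the rescale makes the log base
irrelevant); measured metabolites get weight 1 when their two-sided
Wilcoxon rank-sum p-value is below `met_alpha = 0.01`, else 0 (a
`-log(p)`-based alternative is available via
`metabolite_weighting = "pvalue"`). The concatenated vector is
L1-normalized with the ground entry fixed at 0. Nodes missing from the
profiles start at 0 but still accumulate mass through their neighbors.
The `drw-gm-nm` variant zeroes the metabolite entries (same graph, gene
evidence only); the `drw` variant walks the gene-only graph.

Two choices here were genuinely open. First, whether the combined start
vector uses the raw `-log(p)` gene weights or the rescaled ones: we use
the rescaled vector, since the rescaling step exists only to produce it,
and record the choice here. Second, the t-statistic orientation is
second-phenotype-minus-first (factor level order); only the *consistency*
of the sign between training and test matters downstream.

## Pathway activity

For pathway `P_j`, the member genes with training `p < 0.05` (pooled t)
form the model `{g_1, ..., g_nj}`; the per-sample activity is

    a(P_j) = sum_i W_inf(g_i) * sgn(t_i) * z(g_i) / sqrt(sum_i W_inf(g_i)^2)

where `z` is the gene's z-scored expression (mean 0, sd 1 across the
cohort's own samples — test cohorts are normalized over test samples) and
`sgn(t_i)` is frozen from training. The square-root-of-squared-weights
denominator is a design decision: it makes a single-gene pathway reduce
to `±z` exactly, is invariant to rescaling all walk weights, and matches
the `1/sqrt(k)` normalization family of the condition-responsive-genes
baseline with weights inserted. Pathways with no differential member are
dropped. Model genes missing from a test platform are dropped with the
denominator recomputed, so cross-platform evaluation degrades gracefully
instead of failing.

Baselines implemented behind the same interface: per-sample **mean** and
**median** of all member z-rows (no significance filter, as in the
classical mean/median summaries), and a **CORG-style greedy** search that
ranks members by `|t|` and grows a sign-aligned `/sqrt(k)` average while
the profile's `|t|` strictly increases.

## Classification protocols

Features are pathway activities; the classifier is maximum-likelihood
logistic regression (a vanishing ridge, `1e-6`, is applied only when the
IRLS fit fails to converge on quasi-separable data). AUC is the
Mann-Whitney statistic with midrank ties.

*Within-dataset*: per repeat, a stratified 5-fold split; each fold in
turn is the test set. All statistics — z-scores, t-tests, the walk, the
activity models — are computed on the training folds only. The training
set is split three times (stratified 2/3 vs 1/3) into a
feature-evaluation set (ranks features by activity t-test p-value and
fits the classifiers) and a feature-selection set (accepts a feature only
if the selection-split AUC strictly increases; the top-ranked feature
always enters because an empty model has no AUC to compare against). Each
optimized classifier is scored on the held-out fold: 15 AUCs per repeat,
1500 under the standard 100 repeats.

*Cross-dataset*: the whole first cohort trains everything once; per
repeat its samples are partitioned into 5 stratified subsets, each subset
in turn acting as the feature-selection set against the other four. Each
optimized classifier is evaluated on the full independent cohort (frozen
models, test-side z-normalization): 5 AUCs per partition, 500 under 100
repeats.

Two protocol details are stated nowhere in the protocols we mirror and
were fixed here: splits are stratified (purely random splits can produce
single-class folds on small cohorts), and accuracy uses the 0.5
probability threshold. Repeats are driven by per-repeat seeds drawn once
from the master seed, so runs are reproducible and repeats independent.
If a training fold yields *no* pathway with a differential member gene
(common on null data), the pathway whose best member p-value is smallest
is retained as a single fallback feature rather than aborting, mirroring
the top-ranked-feature rule; the separate `min_diff_genes` guard
(default 50 differential genes across the whole graph) still aborts runs
whose training signal is too sparse for the method to be meaningful, and
should be lowered or disabled for small simulated graphs.

*Reproducibility power*: pathways are ranked by training `|t|` of their
activities; `Cscore(N)` is the mean over the top `N` of
`t_train * t_test` paired by pathway. Discriminative features that stay
discriminative in the same direction on an independent cohort score
high; sign flips subtract.

## The synthetic generator

`simulate_study()` builds the study the tests and the acceptance script
run on. Each pathway is a chain of reactions through its metabolites;
peripheral genes catalyze single steps, hub genes catalyze steps across
the whole chain, so hubs have several-fold higher degree and sit upstream
of many compounds. In risk pathways (3 of 10 by default) all hub genes
shift between phenotypes by a standardized effect of 1.5 with low noise
(sd 0.5), an equal number of peripheral genes shifts with the same
standardized effect but unit noise — equally significant by construction,
differing only in topology — and half the pathway's metabolites
(preferring hub products) shift detectably in an independent log-normal
metabolite cohort (15 + 15 samples). The expression cohort has 30 + 30
samples. Everything is fixed by one seed.

The generator emulates the statistical structure the method assumes —
hub connectivity, low-variance consistent hub shifts, metabolite evidence
adjacent to the true signal — and deliberately not the messiness of real
data: no platform or batch effects, no correlated noise, Gaussian
expression, and a graph that is far smaller (hundreds of nodes) than a
genome-scale metabolic network. Passing tests therefore demonstrate
correctness of the machinery and the qualitative behavior of the method
under its own assumptions, not clinical performance.

## Numerical choices and degenerate inputs

- Zero-variance features cannot be z-scored; their rows are set to 0 with
  a warning (dropping them would desynchronize cohorts).
- Identical groups give `t = 0`, `p = 1` rather than `0/0`.
- If all gene p-values coincide the min-max rescale is undefined; all
  measured genes get equal weight, with a warning.
- Rank-sum tests are exact for group sizes up to 25 (no ties), normal
  approximation with continuity correction otherwise.
- Ranking ties (stationary weights, feature p-values) break
  lexicographically by id, so orderings are deterministic.
- Sample sd (`n - 1`) is used throughout; for z-scores this is a constant
  factor per cohort and cancels in every downstream statistic.
- The power iteration verifies its fixed-point residual
  (`< 10 * tol` in L1) before returning, and errors with the residual if
  `max_iter` is exhausted.

## Problem sizes used by the tests and the acceptance script

Solver cross-checks use 50 random directed graphs of 20-200 nodes. The
protocol-arithmetic and null-calibration runs use reduced studies (5
pathways, 6 genes and 6 metabolites each, 12-15 samples per class); the
null estimate averages 20 protocol repeats spread over 5 independently
simulated null cohorts, because repeats within one cohort share its
sampling noise. The benchmark runs use the generator defaults above with
5 evaluation repeats per method and an independently simulated second
cohort for the reproducibility comparison (Cscore over the top
`min(10, shared pathways)`; the weighted methods retain only pathways
with differential members, so fewer than 10 may be available).

## Known limitations

- Two-phenotype classification only; no multiclass decomposition.
- The t-test is the only gene-level differential statistic (pooled by
  default, Welch by option); no multiple-testing correction is applied
  anywhere, by design — raw p-value thresholds are part of the method.
- Edge weights are not supported: transition probabilities are purely
  degree-based.
- A fold-change-based gene initialization and p-value-based metabolite
  weights exist as options but are not part of the default method.
- The reduced KGML reader covers reactions, substrates, products,
  reversibility and gene annotations only; the reaction-table TSV is the
  canonical input format.
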