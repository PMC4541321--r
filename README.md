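# drwgm

Pathway-based two-phenotype classification from joint transcriptomic and
metabolomic evidence. `drwgm` scores the topological importance of every
gene in a directed gene–metabolite metabolic network with a random walk
with restart, turns those scores into per-sample pathway activities, and
evaluates pathway-feature classifiers with reproducible cross-validation
protocols. It is aimed at computational biologists who have a gene
expression cohort, a matched (or public) metabolite cohort, and a set of
metabolic pathways, and who want pathway biomarkers that transfer across
cohorts rather than gene lists that do not.

## Method

Metabolic reactions define a directed bipartite graph (substrate →
enzyme gene → product; reversible reactions in both directions). The
per-pathway graphs are merged, all edges are reversed so that evidence
flows from downstream products to the upstream genes that generate them,
and a ground node is attached to make the transition matrix
row-stochastic. With `M` the row-normalized adjacency matrix, the walk

    W_{t+1} = (1 − r) Mᵀ W_t + r W_0,   r = 0.7

is iterated to its stationary vector `W_∞` (L1 change < 1e-10). The
start vector `W_0` carries the evidence: genes get min–max-rescaled
`−log p` weights from two-tailed t-tests, differential metabolites
(rank-sum p < 0.01) get weight 1. For a pathway `P_j` whose member genes
pass p < 0.05, the activity of each sample is the weighted, sign-aligned
combination of z-scores

    a(P_j) = Σᵢ W_∞(gᵢ) · sgn(tᵢ) · z(gᵢ) / √(Σᵢ W_∞(gᵢ)²)

Classifiers are logistic regressions over greedily selected pathway
activities, evaluated with a 5-fold × 3-split × repeats within-dataset
protocol (15 AUCs per repeat) or a 5-partition cross-dataset protocol
against an independent cohort (5 AUCs per partition). The Cscore
statistic — the mean over the top-N training-ranked pathways of
`t_train × t_test` — quantifies how well activities reproduce across
cohorts. Baselines behind the same interface: mean/median member
summaries, a CORG-style greedy gene search, the walk without metabolite
evidence (`drw-gm-nm`), and the walk on a metabolite-contracted
gene-only graph (`drw`).

## Worked example

A fully synthetic study — 10 chain-structured pathways with high-degree
hub enzymes, 3 of them carrying planted signal on hubs, equally
significant noisy peripheral genes, and an independent metabolite cohort
with differential compounds next to the hubs:

```r
library(drwgm)

study <- simulate_study(sim_spec(seed = 1))
study
#> sim_study: 10 pathways (3 risk), 100 genes x 60 samples,
#>            100 metabolites x 30 samples

graph <- build_global_graph(study$reactions)
z  <- z_normalize(study$expr)
gd <- gene_ttests(z)                      # per-gene pooled t-tests
md <- metabolite_tests(study$met)         # per-metabolite rank-sum tests
tm <- transition_matrix(graph)
w_inf <- drw_walk(tm, initial_weights(graph, gd, md))
head(rank_nodes(w_inf, tm, kind = "gene"), 5)
#>   node_id kind     weight rank
#> 1  g02_04 gene 0.02933707    1
#> 2  g03_01 gene 0.02786092    2
#> 3  g02_02 gene 0.02661908    3
#> 4  g03_02 gene 0.02577290    4
#> 5  g01_01 gene 0.02422764    5
```

All five top-weighted genes are planted signal genes from the three risk
pathways (`pw01`–`pw03`); the hub genes (`g*_01`, `g*_02`) dominate the
top of the ranking even though the planted peripheral genes are equally
significant in the t-tests. The full protocol:

```r
report <- within_dataset_eval(study$expr, study$met, graph,
                              eval_config(n_repeats = 2, seed = 9,
                                          min_diff_genes = 1))
report
#> eval_report [within-dataset, drw-gm]: 30 AUCs, mean 0.9708 (sd 0.0380)
head(report$selection_freq, 3)
#> pw01 pw02 pw03
#>   25   13    7
```

The three planted risk pathways are exactly the most frequently selected
features. Reproducibility against a second, independently simulated
cohort:

```r
study2 <- simulate_study(sim_spec(seed = 2))
models <- fit_all_models(graph, gd, w_inf, z)
a_tr <- activity_matrix(models, z)
a_te <- activity_matrix(models, z_normalize(study2$expr), frozen = TRUE)
c_score(a_tr, a_te, 5)
#> c_score(N = 5) = 74.9154 over 6 pathways
```

A command-line interface wrapping the same functions ships in
`inst/cli/drwgm` (subcommands `simulate`, `build-graph`, `diff`, `walk`,
`activity`, `classify`, `cscore`).

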