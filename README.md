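# flnmod — modular analysis of disease functional linkage networks

Proteins encoded by genes associated with a common disorder tend to be
functionally linked: they interact, share pathways and subcellular
compartments, and co-occur in disease annotations. `flnmod` turns that
observation into a reproducible analysis pipeline for a disease of interest.
It was built around a Type 2 diabetes functional-linkage-network study design
and is applicable to any disease with a curated core-protein list and a
STRING-style weighted association table.

The pipeline:

1. **Network construction** — expand the disease *core proteins* with their
   first neighbors in a confidence-thresholded edge list (integer STRING
   scale 0–1000, default cutoff 940), drop singletons, keep the giant
   component. Quality is tracked by *coverage* (fraction of the core list
   captured) and *constitution* (core fraction of the network), with
   ROC-style threshold sweeps and random-seed negative controls.
2. **Functional modules** — maximal cliques (every member pair linked,
   modularity Q = 1; one protein may sit in many modules), enumerated by
   pivoted Bron–Kerbosch and canonically ordered.
3. **Module scoring** — per classification scheme (pathway, localization,
   disease class), the redundancy

   `R = 1 + (Σ_k f_k ln f_k) / ln n`

   (one minus normalized Shannon entropy of the class frequencies `f_k`
   over a universe of `n` classes; `R = 1` for a single shared class), with
   permutation p-values from 10³ label-set shuffles.
4. **Nonlinear ranking** — combined score `S = Σ_j α_j S_j^β_j` over the
   four features (log-size plus three redundancies), coefficients fitted by
   a real-valued genetic algorithm supervised by planted ideal modules.
5. **Condensed network** — induced subgraph on the union of the top-k
   modules, k chosen where core-protein capture saturates.
6. **Non-overlapping GO decomposition** — term–protein incidence `B`,
   co-occurrence `G = B·Bᵀ`, compatibility graph on zero-overlap pairs, and
   the maximal-clique configuration covering the most proteins.
7. **Disease–disease network** — pairwise disease overlap
   `DO = |d_i ∩ d_j| / |d_i ∪ d_j|` over the condensed proteins, permutation
   p-values (10³ replicates), Benjamini–Hochberg FDR, and the filtered
   (shared ≥ 2, p < 0.01) disease graph.

A deterministic synthetic-data generator (`generate_bundle`) emits complete
input bundles with certified ground truth — planted cliques, homogeneous
annotations, a provably optimal GO configuration, planted disease pairs — so
the whole pipeline is testable without any database access.

## Worked example

```r
library(flnmod)

cfg <- synth_config(rng_seed = 7, proteome_size = 400,
                    n_planted_modules = 10, go_n_terms = 8,
                    planted_pairs = c(5, 4, 3))
bundle <- file.path(tempdir(), "bundle")
truth <- generate_bundle(cfg, bundle)

out <- run_pipeline(bundle, reps = 1000, rng_seed = 7)
network_stats(out$giant, core = read_protein_list(file.path(bundle, "core_proteins.txt")))
#> network: 159 nodes, 303 edges
#> coverage: 0.6750
#> constitution: 0.3396
#> degrees: 12 distinct values, max 12
out$fit
#> GA fit: best mean planted rank 5.50 after 100 generations
#> nonlinear module-scoring model
#>   alpha: 0.6290 0.2530 0.0736 0.0444
#>   beta:  1.2944 3.9809 1.7663 4.8631
```

The thresholded giant component keeps 159 of 400 proteins (67.5% of the core
list; about a third of the network is core). 128 maximal cliques are
enumerated (sizes 2–10, mean 2.32), 8 of size ≥ 4; the GA drives the ten
planted ideal records to the top of the ranking (mean rank 5.5, the optimum),
core capture saturates at k = 8 of the ranked size-≥4 modules, and the
condensed network contains 54 proteins with 184 interactions.

Recovery against the generator's ground truth (ranking every module, and
testing disease overlaps over the full proteome the pairs were planted in):

```r
out2 <- run_pipeline(bundle, reps = 1000, rng_seed = 7, min_module_size = 2)
annot <- disease_annotation(
  read_annotation_table(file.path(bundle, "protein_disease.tsv")),
  term_class = stats::setNames(
    read_annotation_table(file.path(bundle, "disease_classes.tsv")),
    c("term", "class")))
dmap <- disease_protein_map(sprintf("P%05d", 1:400), annot)
pairs <- permutation_fdr(overlap_scores(dmap), dmap, reps = 1000, rng_seed = 7)
verify_truth(truth, list(modules = out2$modules, ranking = out2$ranking,
                         go = out2$go_full, disease_pairs = pairs))
#> planted module recovery: 100.0%
#> planted rank median: 5.5 (percentile 0.043)
#> GO optimum matched: TRUE
#> planted disease pairs at p<0.01: 100.0%
```

All ten planted cliques are recovered among the maximal cliques, their
median rank under the fitted model sits in the top 5% of all 128 modules,
the GO decomposition returns exactly the certified optimal configuration,
and all three planted disease pairs (5, 4 and 3 shared proteins) reach
p < 0.01 at 10³ permutations — 4 significant pairs pass the shared ≥ 2,
p < 0.01 filter overall.

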