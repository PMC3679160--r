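---
title: "Modular analysis of disease functional linkage networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular analysis of disease functional linkage networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flnmod)
```

# Overview

`flnmod` implements a modular analysis of disease-related functional linkage
networks. Starting from a weighted protein association list (STRING-style
integer confidence scores on a 0–1000 scale) and a list of disease *core
proteins* gathered from prior literature, the pipeline:

1. expands the core set with its first neighbors and thresholds the edge
   list on a confidence cutoff (`build_network`, `expand_seeds`);
2. removes singletons and keeps the giant component (`drop_singletons`,
   `giant_component`);
3. enumerates *functional modules* as maximal cliques
   (`enumerate_maximal_cliques`);
4. scores each module for annotation homogeneity under three classification
   schemes — pathway, subcellular localization, disease — with permutation
   significance (`redundancy`, `score_table`);
5. combines the features into one score via a nonlinear model whose
   coefficients are fitted by a genetic algorithm supervised with planted
   ideal modules (`ga_fit`, `rank_modules`);
6. assembles a *condensed network* from the top-ranked modules, choosing the
   cut by core-capture saturation (`assemble_condensed`, `choose_k`);
7. decomposes the condensed network's biology into a maximal set of
   mutually non-overlapping GO terms (`go_decompose`);
8. links diseases that share condensed-network proteins, with permutation
   p-values and Benjamini–Hochberg FDR (`overlap_scores`,
   `permutation_fdr`, `disease_network`).

Every stage is testable offline through a deterministic synthetic-data
generator with known ground truth (`synth_config`, `generate_bundle`,
`verify_truth`).

# Network construction

Edges are read from whitespace/TSV text with columns
(protein, protein, confidence). Confidences are integers in [0, 1000];
fractional 0–1 inputs are rejected unless `rescale01 = TRUE` explicitly
requests ×1000 rescaling, because the thresholds this analysis sweeps
(900–990, default cutoff 940) live on the integer scale. Self-pairs are
dropped and duplicate unordered pairs collapse to their maximum confidence.

Seed expansion means one step: the thresholded subgraph induced on the core
proteins plus every protein at distance one from a core protein; the
expansion is not iterated. Singleton removal precedes giant-component
extraction. Two quality measures summarize a constructed network against the
core list:

* **coverage** — the fraction of the core list captured in the network;
* **constitution** — the fraction of network nodes that are core proteins.

`roc_points` reports, per threshold, the captured core fraction (TPR) and
the captured non-core proteins over the non-core proteins attainable in the
*unthresholded* seed-expanded network (FPR denominator fixed at the maximum
network the seed set can reach). `random_seed_control` repeats the same
expansion for uniformly sampled seed sets as a negative control.

On the reference data this pipeline was designed around, the published
singleton-free giant component has 2,770 nodes and 15,041 edges; the same
source also states 2,734 proteins of which 497 (17.71%) are core, and
497/0.1771 ≈ 2,806 — three mutually inconsistent node counts. The package
takes no side: it always reports its own computed counts.

# Functional modules

A functional module is a maximal clique: every member pair is linked
(within-module modularity Q = 1) and no outside protein is adjacent to all
members. Enumeration delegates to igraph's pivoted Bron–Kerbosch
implementation; pivoting changes speed, never the output set, which the test
suite verifies against a brute-force subset oracle on hundreds of random
graphs. Output is canonicalized (members sorted, list ordered by descending
size then lexicographic id) so downstream ranking is reproducible and
independent of input order. Size-2 maximal cliques are enumerated; filtering
at size ≥ 4 — the conventional cut for biologically meaningful modules — is
a separate explicit step whose summary statistics describe the *pre-filter*
enumeration.

# Redundancy (annotation homogeneity)

A classification scheme maps proteins to classes from a fixed universe of
$n$ classes. For a module whose annotated members have relative class
frequencies $f_k$, the redundancy is one minus the normalized Shannon
entropy:

$$R = 1 + \frac{\sum_k f_k \ln f_k}{\ln n}, \qquad 0 \ln 0 := 0 .$$

$R = 1$ exactly when all annotated members share one class; $R = 0$ at
maximal dispersion (uniform spread over all $n$ classes). For members
uniform over $m \le n$ classes, $R = 1 - \ln m / \ln n$, strictly
decreasing in $m$ — the concentration-monotonicity law the tests check for
all $m \le n \le 50$. Note the statistic is intentionally normalized by the
scheme universe, so small modules cannot reach high entropy: a 2-member
module split over two classes still scores $1 - \ln 2/\ln n$. Multi-label
proteins contribute fractional weight $1/L$ to each of their $L$ labels
(deterministic and order-free); a majority-collapse alternative
(`multi_label = "best"`) assigns each protein its single most
module-frequent label. Modules with fewer than two annotated members score
0, preventing vacuous homogeneity.

Significance: $10^3$ null replicates permute the protein → label-set
assignment as a whole across the scheme's annotated proteins, preserving
each protein's label multiset and the scheme's label counts. Empirical
p-values use the add-one convention $p = (1 + \#\{R_{null} \ge
R_{obs}\})/(reps + 1)$, so $p > 0$ always. Because module membership stays
fixed while assignments move, this null is informative; the same shuffle
applied to the *disease-pair* statistic would be degenerate (see below).

# Nonlinear ranking model and its GA fit

Each module yields four features in [0, 1]: the size feature
$\ln N / \ln N_{max}$ (normalized over the enumerated module set) and the
three redundancies. The combined score is a weighted power sum

$$S = \sum_{j=1}^{4} \alpha_j S_j^{\beta_j}, \qquad \alpha_j \ge 0,\;
\sum_j \alpha_j = 1,\; \beta_j \in (0, \beta_{max}],$$

which stays in [0, 1] and is monotone non-decreasing in every feature. A
multiplicative family $\prod_j S_j^{\alpha_j \beta_j}$ is available behind
the same interface (`form = "product"`).

The coefficients are estimated by a real-valued genetic algorithm. Ten
artificial *planted* records representing the best achievable modules
(every redundancy 1, size feature at the observed maximum; or one maximal
feature each in the `per-scheme` variant) are appended to the real records.
A chromosome encodes $(\alpha, \beta)$; after every operator the weights are
renormalized to the simplex and the exponents clipped to their box. Fitness
is the mean rank of the planted records when all records are scored and
sorted by descending $S$ (ties broken by module id) — the GA searches
parameter space while the records form the fixed evaluation set. Defaults:
population 100, 100 generations, tournament size 3, blend crossover rate
0.8, per-gene Gaussian mutation rate 0.1 with sd 0.1, elitism 1,
$\beta_{max} = 5$. A seed is mandatory and runs are bit-reproducible. Note
that with all-maximal plants the fitness landscape is flat wherever no real
record matches the plants feature-wise (their score is 1 under any simplex
weights); the fit becomes informative exactly when real modules compete on
some features, which is also the regime the per-scheme variant probes.

The final ranking sorts real modules (plants excluded) by descending $S$,
ties by larger size then lexicographic id.

# Condensed network and k selection

For a candidate count $k$, the condensed network is the subgraph *induced*
on the union of the top-$k$ modules' member sets — edges between members of
different modules are retained. The induced reading is deliberate: in the
reference analysis the reported condensed edge count exceeds what the
cliques alone could contribute. A within-module-only mode
(`induced = FALSE`) exists for sensitivity checks. The selection curve
sweeps $k \in \{25, 50, 75, 100, 150, 250\}$ by default, recording size,
core content and connected components; `choose_k` picks the smallest $k$
whose core capture is within `tol` (default 0.05) of the curve's maximum —
a concrete rule standing in for the published "saturation" criterion, which
states the plateau but no explicit tolerance.

# Non-overlapping GO decomposition

Let $B$ be the binary GO-term × protein incidence matrix over the analysis
proteins. $G = BB^T$ counts per-term proteins on the diagonal and shared
proteins off it; zero off-diagonal entries identify compatible
(non-overlapping) term pairs, giving a compatibility graph that is the
complement of the overlap graph. Candidate configurations are the maximal
cliques of the compatibility graph; each is scored by the total proteins
covered (the sum of its diagonal counts — exact, since its terms are
pairwise disjoint). Ties break toward fewer terms, then the
lexicographically smallest term list; the tie-break is an implementation
choice recorded here, as the source analysis states none. An exhaustive
mode enumerates every pairwise-compatible subset (refused above 20 terms —
candidate counts grow exponentially; the reference analysis reports over
50,000 combinations) and is used both as an in-package cross-check and to
certify the synthetic generator's ground truth. Proteins left uncovered are
always reported: non-assignment typically means a protein is associated
with *many* terms, not none.

# Disease–disease overlap

Disease terms are mapped to their annotated proteins restricted to the
analysis set (condensed-network proteins). Every unordered term pair sharing
at least one protein receives a disease-overlap score; the default is the
Jaccard index

$$DO = \frac{|d_i \cap d_j|}{|d_i \cup d_j|},$$

with the overlap coefficient and geometric normalization selectable behind
the same interface. Significance uses $10^3$ null replicates in which each
term independently redraws a protein set of its observed size, uniformly
without replacement from the analysis proteins. This null preserves every
term's protein count and the protein universe. A whole-term-set shuffle
across proteins — the obvious alternative — is *degenerate* here: permuting
which protein carries which term set is a column permutation of the
incidence matrix and leaves $MM^T$, hence every shared count and DO score,
numerically unchanged; such a null would return $p = 1$ everywhere. (The
module-redundancy permutation does not suffer this because module membership
is an independent, fixed structure.) An `edge-shuffle` alternative permutes
the protein column of the association list. p-values use the add-one
convention; Benjamini–Hochberg q-values are reported alongside, and the
published filter (shared ≥ 2, p < 0.01) is the default for the
disease–disease network, with `use_q = TRUE` switching the criterion to FDR.

Because the shared-protein count is integer-valued, its permutation p-value
is conservatively biased under ties; in calibration experiments the null
p-values control type-I error correctly (fraction below 0.05 is at most
~0.05) but sit slightly above uniform (mean p ≈ 0.53–0.56), so uniformity
checks for this statistic use wider bands than for the module-redundancy
p-values, which are effectively continuous for modules of 30–40 annotated
members.

# Synthetic data generator

`generate_bundle` emits a complete input bundle plus certified ground
truth, byte-identical under a fixed configuration:

* **Network**: disjoint planted cliques (default 20, sizes 3–10) over a
  background graph (preferential attachment, mean degree 4; a configuration
  model is selectable). Planted edge confidences (945–1000) sit above the
  default threshold (940) while background confidences (700–999) straddle
  it, so thresholding is a meaningful operation. Consecutive planted
  cliques are chained by single above-threshold anchor edges so they land
  in one (giant) component; an anchor touches one member only, so clique
  maximality is unaffected. At generation time every planted clique is
  asserted to survive thresholding intact and to be maximal — background
  edges that would extend one are removed.
* **Core list**: planted members are flagged core with probability 0.7,
  topped up with random proteins to the configured core fraction (0.2).
* **Schemes**: per scheme (50 pathway classes, 30 compartments, 23 disease
  classes — the localization and disease universes at reference scale, the
  pathway universe scaled to the synthetic proteome of 1,000), each planted
  module draws a home class and each member carries it with probability
  `p_hom` (default 0.8, else uniform); background proteins are annotated
  uniformly (80%), a tenth of them with a second label. Second labels are
  confined to background proteins so planted homogeneity is a pure function
  of `p_hom`.
* **GO**: disjoint term blocks (12 terms, 3–8 proteins) plus deliberately
  overlapping extra terms (30% of the base count); the optimal
  configuration is certified by exhaustive search at generation time, so
  oracle tests never depend on the code path under test.
* **Diseases**: 40 terms with sparse background annotations and planted
  overlapping pairs at exact shared counts (default 5, 4, 3), kept clear of
  background noise so the truth records exact overlaps.

What the generator does **not** emulate: realistic STRING confidence-score
distributions, GO DAG topology and ancestor propagation, the heavy-tailed
and correlated annotation patterns of real databases, or literature bias in
core-protein lists. Passing the recovery tests therefore demonstrates the
pipeline's correctness and statistical calibration under its stated
assumptions, not database-level realism.

# Numerical and degenerate-input conventions

* Redundancy: $0 \ln 0 = 0$; results clamped to [0, 1] against floating
  error; schemes need $n \ge 2$ classes; modules with < 2 annotated members
  score 0.
* Permutation p-values: add-one convention, ties counted in the null tail
  (`>=` with a $10^{-12}$ guard for float comparisons in the disease path).
* Empty inputs: an empty edge file is an empty edge list; an empty network
  maps to itself under `giant_component`; coverage is an error for an empty
  core set, constitution for an empty network; an empty module list gives
  count 0 with NA summaries, never zeros.
* Tie-breaks are deterministic everywhere: component ties by
  lexicographically smallest node list, ranking ties by size then id, GO
  configuration ties by fewer terms then term list.
* GA: chromosomes repaired (simplex renormalization, box clipping) after
  every operator; identical seeds give bit-identical fits.

# Problem sizes used by tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on the
default synthetic bundle (1,000 proteins, 20 planted modules, 1,000
permutation replicates, GA population 100 × 100 generations), plus
property checks: clique-oracle equivalence on 200 random graphs of up to 12
nodes, redundancy laws for all $m \le n \le 50$, p-value calibration at 200
modules × 1,000 replicates, GO exhaustive-search equivalence on 100
instances of up to 15 terms, and planted disease-pair recovery across 5
seeds at 1,000 replicates. These sizes were chosen so the whole suite
completes in a few minutes on one CPU while every statistical check retains
power.

# Known limitations

* Reproduction of the published reference counts requires the original
  supplementary exports (network edge list, GO associations, disease
  tables), which are not shipped with the package; the corresponding
  acceptance tests report exactly which files they expect under
  `inst/extdata/supplementary/`.
* The redundancy statistic's universe normalization makes small modules
  look homogeneous; interpret $R$ jointly with module size (the ranking
  model does, via the size feature).
* The GA fit is only informative when real modules compete with the plants
  (see above); with all-maximal plants and weak real modules any valid
  parameter vector is optimal, and the returned one depends on the seed.
* Identifiers are opaque case-sensitive strings; all inputs must already
  share one namespace.
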