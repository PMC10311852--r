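---
title: "Path-based drug-gene interaction prediction on literature knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based drug-gene interaction prediction on literature knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blgpa)
```

## The problem and the data model

Text-mining pipelines over the biomedical literature produce *predications*:
subject--relation--object triples (e.g. `Gefitinib INTERACTS_WITH EGFR`),
each extracted from one article and typed with UMLS semantic types. Together
with `MENTIONED_IN` edges (a concept occurs in an article) and `HAS_MESH`
edges (an article is indexed under a MeSH concept), these triples form a
provenance-aware multigraph in which drugs and genes are concept nodes.
`blgpa` predicts missing drug--gene interaction links on such a graph, and --
unlike embedding approaches -- keeps every prediction traceable to explicit
graph paths.

Labels follow the closed-world assumption standard in this setting: a
drug--gene pair not listed in the interaction benchmark is treated as a
negative. This is known to be only approximately true (some "negatives" are
undiscovered positives), which is one reason evaluation emphasises the
positive class.

## Feature construction

For a pair $(d, t)$ all *simple* paths of length at most $l$ connecting the
two nodes are enumerated. Traversal is orientation-agnostic: a stored edge
can be walked in either direction, and paths record only relation labels.
This is deliberate -- literature chains such as
$d \rightarrow$ `MENTIONED_IN` $\rightarrow$ article $\leftarrow$
`MENTIONED_IN` $\leftarrow t$ are only realizable by walking one mention
edge in reverse, and the path notation carries no direction. Simple paths
(no node revisits) are used because literature graphs contain strong hub
concepts: walks with revisits would explode combinatorially without adding
new relation chains. Two safeguards are exposed for dense graphs, a degree
cap on intermediate nodes (off by default) and a path cap (100,000 by
default, flagged when it fires).

Each path yields two feature blocks:

**Semantic encoding (SE).** Position $j$ of a path owns one count per
semantic-type code and one per scored relation label -- with the default
vocabularies $127 + 35 = 162$ features per position, $3 \times 162 = 486$ in
total at $l = 3$. A feature counts the distinct articles supporting the
corresponding triple, crediting the semantic type each article attributes to
the node at the *start* of the transition; the final node's type is never
encoded (on drug--gene paths it is always the gene type). Per-pair vectors
are the element-wise sum over all connecting paths. Two readings of the
count semantics are reachable in the field -- article-frequency counts and
per-path presence/absence -- so the article-frequency reading is the default
and `binary_se = TRUE` selects the binary one; under unit support the two
coincide. When one article attributes two different types to the same node,
both type features are credited.

**Path ranking (PR).** The *relational chain* of a path is its relation
sequence with nodes ignored. On the training pairs, each observed chain is
scored by support: the fraction of positive pairs whose path set contains it
minus the same fraction over negatives (pair-level containment -- duplicated
paths within a pair change nothing). The top $M = 100$ chains by this
importance (ties broken lexicographically, so ranking is deterministic)
define the PR block: entry $k$ counts the paths whose chain *equals* the
rank-$k$ chain. Equality, rather than contiguous-subsequence containment,
matches the worked example's per-path values of exactly 1; a
`substring_match` flag enables the other reading. Chains of every length
$1 \dots l$ are eligible.

The concatenated vector has $l \times 162 + M = 586$ entries with all
defaults. A disconnected pair featurizes to the zero vector.

## Classifier, sampling regimes and evaluation

A random forest (100 trees, otherwise default settings, unweighted classes
by default with a `classwt` escape hatch) is fit on the concatenated
features; predictions threshold the positive-class probability at 0.5
(configurable). `blgpa()` returns a classed model object with
`predict`/`print`/`summary`/`plot` methods.

Real benchmarks are imbalanced at roughly 1:54, so `sample_dataset()`
provides three regimes: balanced 1:1, 1:10, and 1:54. `blgpa_cv()` runs
stratified 10-fold outer cross-validation (stratification guarantees
positives in every fold) and reports positive-class precision, recall and F1
per fold plus their arithmetic means across folds -- the "macro average for
the positive class" read as per-fold metrics averaged over folds, which
matches standard cross-validation reporting. In the ratio regimes each
fold's training pool is further subsampled: an inner 5-fold cross-validation
picks the training negative:positive ratio from the grid
$\{1, 2, 5, 10, 20, 54\}$ by best inner F1 (ties to the smaller ratio).

Chain mining is strictly fold-local: chains are mined only from each fold's
training pairs, never from test pairs, and the report retains the pair ids
used for mining, ratio selection and training so `leakage_audit()` can
verify the separation after the fact. All randomness -- negative sampling,
fold assignment, inner subsampling, forest fitting -- derives from one seed,
making reports bit-reproducible.

## Explainability

`feature_importance()` ranks all features by the forest's impurity
importance, normalized to sum to one. `fit_surrogate()` distills the forest
into a single decision tree trained on the forest's *predicted* labels
(distillation, not a fit to ground truth -- the tree approximates the model);
its hyperparameters (maximum depth, minimum leaf size) are chosen by
cross-validated fidelity, the agreement between tree and forest.
`post_prune()` then greedily collapses, at each iteration, the internal node
whose removal loses the least fidelity, as long as fidelity stays at or
above a configurable floor (default 0.95 accuracy); the paper-trail metric
pair is accuracy plus positive-class F1. On the distillation data this
procedure is provably monotone: leaf classes are majority classes, so
neither fidelity nor depth can increase. If even the unpruned tree misses
the floor it is returned unchanged with a flag. `trace_decision()` renders
the root-to-leaf rule for one pair, e.g.

```
IF rel1_TREATS > 49.5 AND PATH2 > 8.5 THEN Interaction (800/841)
```

with leaf purity as majority count over leaf total. The base tree inducer is
`rpart`; fitted trees are converted to an internal structure whose split
convention ("right iff feature > threshold") agrees with `rpart` on any data
point because thresholds are midpoints of observed values.

## The synthetic benchmark

`generate_kg()` emulates the statistical structure the method relies on:
labels are assigned first (default: all 20 x 20 drug--gene combinations,
half positive), then for each pair and each *planted chain* a realizing path
is wired with probability `p_pos` (0.9) for positives and `p_neg` (0.1) for
negatives; random semantic edges (2 expected per concept node) and concept
mentions (1 per node) are layered on top, and every triple draws its article
support from a geometric distribution with mean 2. Concept types come from a
small 8-code sub-vocabulary so SE blocks are exercised without the full
127-type set.

Intermediate nodes of planted paths are fresh by default and reused with
probability 0.3 from keyed pools: first-half positions share only among
paths of the same drug, second-half positions only among paths of the same
gene. The keying matters -- a single global pool lets fragments of different
pairs' paths recombine into a realizing path for a pair that was never
planted, which would break the generator's contract that containment
frequencies equal the configured probabilities (most visibly in the limiting
case `p_pos = 1, p_neg = 0`, where no negative may contain the chain).
Keyed reuse still produces hub intermediates, but only along one drug's or
one gene's neighbourhood.

What the generator does *not* emulate: realistic extraction noise
(mis-typed or spurious predications correlated with frequency), the fat-tail
degree distribution of real literature hubs, ontology structure, or
benchmark-scale imbalance. Passing tests on synthetic graphs therefore
demonstrate correctness of the machinery and recoverability of planted
signal, not performance on real literature graphs.

A note on attainable accuracy: with a single chain planted at rates
$p_+ = 0.9$ and $p_- = 0.1$, chain containment is the only label-dependent
signal, so the best possible classifier is the containment rule with
expected precision, recall and F1 all $\approx 0.9$ -- planting rates place
a hard ceiling on any learner, and observed cross-validated F1 sits slightly
below it (forest imperfection plus binomial fluctuation in the realized
plantings). Benchmarks intended to show near-perfect recovery should plant
at more extreme rates.

## Numerical and design choices

* Path order is lexicographic by node then relation sequence; chain ties
  break lexicographically; fold assignment deals shuffled class members
  round-robin -- every ordering in the pipeline is deterministic.
* Positional feature names are 1-based (`rel1_*` is the first relation),
  matching the display convention of the model family.
* Ontology `is_a` edges carry no article and count as support 1; they are
  admitted in graphs but never scored as SE/PR features (encoding skips the
  relation feature with a warning and keeps the node-type feature).
* Metrics with empty denominators (no predicted positives, no true
  positives) are defined as 0.
* `M` larger than the number of observed chains shortens the PR block with a
  message rather than padding.
* Problem sizes in the test suite are chosen for tight feedback loops: the
  reference synthetic condition is 400 pairs on a ~450-node graph, oracle
  comparisons use graphs of at most 12 nodes where exhaustive enumeration is
  trivially correct, and the permutation null uses 20 repetitions.

## Limitations

* The exact membership of the 35 scored relations on real SemRep graphs is
  deployment-specific; the shipped list is a documented stand-in and the
  layout adapts to any vocabulary file with the same JSON shape.
* `enumerate_paths()` is exponential in the worst case; the caps bound work
  but truncate path sets (flagged) rather than sampling them.
* The surrogate explains the forest, not the biology: high fidelity means
  the tree mimics the model, including its mistakes.
* Model objects retain their training feature matrix (needed for surrogate
  fitting and feature selection); on very large pair sets this is a memory
  cost.
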