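---
title: "Cleaning noisy pairwise constraints for overlapping community detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning noisy pairwise constraints for overlapping community detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Semi-supervised community finding lets a human oracle steer an otherwise
unsupervised algorithm with *pairwise constraints*: a **must-link** (ML) pair
should share at least one community, a **cannot-link** (CL) pair should share
none. Real annotators are imperfect, so a fraction of these labels is simply
wrong, and wrong constraints actively mislead constrained algorithms. In
overlapping community structure the usual consistency tricks are unavailable:
must-link is *not* transitive (an overlapping node can be must-linked to
members of two communities that are mutually cannot-linked), so noisy labels
cannot be detected by closure arguments alone.

`occlean` frames noisy-constraint removal as *outlier detection in a
topological feature space*. Each constraint pair is described by seven
features computed from the network alone; a detector is fit per constraint
view (ML and CL separately), and constraints flagged as outliers are
discarded before the surviving set guides constrained label propagation.

## Pipeline at a glance

1. **Feature extraction** (`extract_features()`): per pair
   — shared-edge indicator, common-neighbor count, neighborhood Jaccard,
   reciprocal shortest-path distance (0 when disconnected), cosine of
   adjacency rows, SimRank, and cosine similarity in a random-walk
   skip-gram embedding. Columns are min-max scaled to [0, 1] over the
   current constraint set because margin- and distance-based detectors need
   commensurate scales; a constant column maps to 0.
2. **Cleaning** (`clean_constraint_set()`): per view, a model is fit on the
   surviving rows for `sub_iterations` rounds (default 2), removing flagged
   rows and refitting. Four categories are available (`default_config()`):
   traditional detectors (one-class SVM for ML, isolation forest for CL),
   pure autoencoders scored by reconstruction error, encoder-plus-detector
   pairings, and the hybrid process (sparse autoencoder on ML, AE3 encoder
   + isolation forest on CL) which performed best end-to-end.
3. **Propagation** (`run_slpa()`, `run_pcslpa()`): speaker-listener label
   propagation with overlap via a per-node label memory; the constrained
   variant doubles the weight of labels arriving from must-link partners,
   repairs cannot-link agreement after every round, and enforces constraints
   in post-processing (cannot-link is hard: the output never violates it).
4. **Active loop** (`run_acslpa()`): per iteration, informative pairs are
   selected by label-memory entropy, labelled by the (noisy) oracle, pooled
   with the accumulated cleaned set, re-cleaned with freshly trained models,
   and used for a constrained propagation run. Discarded constraints are
   rechecked once after the loop so that correctly labelled pairs
   mistakenly flagged as noise are not wasted; a final constrained run
   produces the output cover.

## A small worked example

```{r, eval = FALSE}
library(occlean)

bench <- generate_benchmark(benchmark_params(N = 1000, mu = 0.3, On = 0.1,
                                             Om = 2, seed = 42))
cache <- feature_cache(bench$network, seed = 11)

res <- run_acslpa(bench$network, bench$cover,
                  acslpa_config(iterations = 10, seed = 3), cache = cache)
overlapping_nmi(res$cover, bench$cover)   # constrained, cleaned
overlapping_nmi(run_slpa(bench$network, slpa_params(seed = 3)),
                bench$cover)              # unsupervised baseline
```

## The synthetic benchmark generator

`generate_benchmark()` produces overlapping-community networks in the
standard LFR style: degrees from a truncated power law (exponent `t1 = 2`,
mean 10, max 50), community sizes from a truncated power law (`t2 = 1`) in
[10, 50] ("small" regime, N = 1000) or [20, 100] ("large" regime,
N = 5000), `round(On * N)` overlapping nodes with `Om` memberships each,
and a mixing parameter `mu` giving the fraction of each node's edges that
leave its communities. Edges are realized by configuration-model stub
matching within and across communities with double-edge-swap repair;
unplaceable stubs are dropped and counted. This is a re-implementation, not
a byte-compatible port of the original generator: realized average degree is
within a few percent of its target and realized mixing within about 0.01 of
`mu`, which is accurate enough for the detection experiments but means any
comparison with results computed on the original generator's output is
statistical, not exact.

The generator emulates degree and community-size heterogeneity, controlled
overlap, and tunable boundary sharpness. It does not emulate degree
assortativity, clustering beyond what communities induce, attribute
homophily, or the very skewed community sizes of real co-purchase/friendship
networks — so green tests here show the machinery works under controlled
heterogeneity, not that detection rates transfer to any particular real
network.

## Choices made where the design was open

* **The seventh feature.** The architecture fixes seven inputs but only six
  pair descriptors are standard companions in this setting; the seventh is
  neighborhood Jaccard, the most conventional companion of common-neighbor
  counts. Any externally printed detection rates inherit this uncertainty.
* **Shortest paths** are encoded as `1/d` so that disconnection maps to a
  finite 0.
* **SimRank** uses decay 0.8 and tolerance 1e-4 with a cap of 100 sweeps;
  the feature cache runs 5 sweeps, the iteration count reported as
  sufficient in the original fixed-point formulation, because the change per
  sweep decays geometrically and later sweeps are immaterial as a feature.
* **Embeddings** default to 64 dimensions from 10 walks of length 80 per
  node, window 10, 5 negative samples, unbiased walks; training is
  single-threaded so a seed fixes the result bit-for-bit.
* **Autoencoders** use rectifier hidden layers and a logistic output (inputs
  are scaled to [0, 1]), plain mini-batch gradient descent with batch 256,
  and the two training regimes 100 epochs at rate 0.01 (small networks) and
  30 epochs at rate 0.001 (large networks). The sparse variants put an L1
  weight of 1e-3 on the bottleneck activations. Note that the large-network
  regime under plain gradient descent is deliberately conservative and does
  not drive the reconstruction error near zero; detection quality on large
  networks drops accordingly (this also reproduces the qualitative
  small-versus-large gap in must-link detectability).
* **Noise injection** flips exactly `round(rate * min(|ML|, |CL|))` labels
  (round half up, at least one when the rate is positive and the smaller
  view non-empty), drawn jointly from the union of both views — so noise
  can concentrate entirely in the smaller view, as observed on real
  networks.
* **PC-SLPA mechanics.** The constrained propagation rules are this
  package's own concrete contract (double-weighted must-link speakers,
  per-round cannot-link repair, post-processing enforcement). They respect
  cannot-link hard constraints and encourage must-link without assuming
  transitivity, but they are a reconstruction: comparisons with published
  numbers produced by other constrained-propagation implementations are
  qualitative.
* **Informative-pair selection** ranks nodes by the entropy of their label
  memories and pairs each uncertain node with its highest-attachment
  neighbor and with a sampled non-neighbor from a different community,
  falling back to uniform sampling of unqueried pairs. One caveat found by
  measurement: because a listener stores only the argmax received label,
  boundary nodes (e.g. bridge endpoints between two cliques) often hold
  near-pure memories, so memory entropy is a weaker uncertainty signal than
  one might expect; the uniform fallback therefore matters in practice.
* **Cleaning order and book-keeping.** Each active iteration re-cleans the
  pooled set (accumulated survivors plus the fresh chunk) with retrained
  models; `kept` and `discarded` always partition the queried pairs. The
  discarded pool is rechecked once, after the loop. Sub-iterations default
  to 2; results are mildly sensitive to this count, and it is exposed in
  `cleaning_config()`.
* **Ground-truth filtering** (for covers in the SNAP community-file
  dialect) keeps the `top_k` largest communities, drops the least dense
  quartile (`floor(0.25 n)` by internal density `2 m / (n (n - 1))`, ties
  discarding the smaller community first), deduplicates exact node sets, and
  applies a minimum size. The quartile cut is a one-shot ranking step: by
  construction a second application would cut again, so only the other three
  steps are idempotent.
* **Overlapping NMI** uses the binary node-membership formulation with the
  zero-entropy admissibility guard and the `max(H(A), H(B))` normalization;
  identical covers score exactly 1 even in the presence of zero-entropy
  communities. Other overlapping-NMI variants differ by several points, so
  scores should not be mixed across variants.

## Problem sizes used in the shipped studies

The replication harness (`experiment1_suite()`, `experiment3_suite()`, and
`scripts/acceptance.R`) evaluates a representative desk-scale grid rather
than the full 64-network sweep: eight small-regime networks (both mixing
values, both overlap fractions, `Om` in {2, 8}) with two replicate
constraint selections each, plus four large-regime networks at `mu = 0.3`
and four at `On = 10%`. Active selection uses 10 iterations with a total
budget of 2% of all pairs capped at 5000. These sizes keep a full
replication run in the tens of minutes on a single core while preserving
every qualitative contrast the studies examine.

## Known limitations

* Detection rates on these benchmarks are substantially higher than on real
  annotation noise: selection concentrates must-link queries on attached
  neighbors and cannot-link queries on cross-community pairs, which makes
  flipped labels topologically conspicuous. Harder, boundary-concentrated
  query strategies would lower them. A side effect, visible in the shipped
  detector suites, is that must-link noise (flipped distant pairs) is the
  *easier* view to clean here, whereas with boundary-heavy query strategies
  the cannot-link view is usually reported as the easier one.
* No modelling of per-annotator reliability or disagreeing oracles; labels
  are fixed once per pair.
* Unweighted, undirected networks only; no hierarchical communities.
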