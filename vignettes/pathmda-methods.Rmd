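---
title: "Path-based scoring of microbe-disease associations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based scoring of microbe-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmda)
```

## The problem and the model

Curated catalogues of human microbe-disease associations are sparse: a few
hundred verified pairs over hundreds of microbes and a few dozen diseases.
`pathmda` prioritises the unverified pairs under the guilt-by-association
premise that microbes involved in phenotypically similar diseases tend to
be functionally similar, and vice versa. The only input is the binary
association matrix $Y$ ($n_m$ microbes $\times$ $n_d$ diseases).

**Similarity.** Each disease is represented by its interaction profile
(its column of $Y$) and each microbe by its row. Similarity on each axis
is the Gaussian interaction profile (GIP) kernel,

$$K(i,j) = \exp\left(-\gamma \, \lVert IP(i) - IP(j) \rVert^2\right),
\qquad
\gamma = \gamma' \Big/ \left(\tfrac{1}{n}\sum_i \lVert IP(i)\rVert^2\right),$$

i.e. a radial kernel whose bandwidth is normalised by the mean number of
associations per node on that axis, so the similarity scale adapts to the
catalogue's sparsity. $\gamma' = 1$ on both axes by default; it is exposed
because cross-validation could in principle tune it.

**Network.** Known associations (weight exactly 1), microbe-microbe
similarities ($K_M$) and disease-disease similarities ($K_D$) are fused
into one undirected weighted heterogeneous network. Similarity edges with
weight below a threshold $T$ are dropped; the comparison is `>= T`, so
equality survives and association edges (weight 1) can never be removed.
The default is $T = 0$ (keep everything): no published value exists for
this cutoff, dropping edges silently changes which paths exist, and
runtime is governed by the length bound instead.

**Scoring.** A candidate pair is supported by every cycle-free path of at
most $L$ edges between the microbe and the disease. A path $p$ with edge
weights $w_1, \dots, w_{len}$ scores

$$S(p) = \left(\prod_e w_e\right)^{\alpha \cdot len(p)},$$

an exponential length decay (all weights lie in $(0,1]$, so longer and
weaker paths are both penalised), and the pair's total score is the sum of
$S(p)$ over all such paths. The direct edge of a known pair contributes
exactly 1.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $L$ | maximum path length (edges) | 3 | longer paths contribute negligibly under the decay while enumeration cost grows geometrically; swept 1-4 in tests |
| $\alpha$ | decay coefficient (unitless exponent multiplier) | 2.26 | the value established for the closest published path-based association models of this family; ranking robustness to $\alpha$ is exercised in tests |
| $T$ | similarity edge cutoff in $[0,1]$ | 0 | the only default that cannot silently discard relevant paths |
| $\gamma'_m, \gamma'_d$ | GIP bandwidth scales | 1 | the standard simple choice for GIP kernels on sparse interaction data |

## Numerical choices

* **Exact closed form for $L \le 3$.** For a fixed length $l$, the decayed
  score of a path is a product of per-edge factors $w^{\alpha l}$, so the
  sum over length-$l$ *walks* is an entry of the $l$-th power of the
  elementwise-powered adjacency matrix. With a zero diagonal, every walk
  of length 1 or 2 between distinct endpoints is already simple; for
  length 3 the two non-simple walk families (revisiting the source or the
  target) are removed by inclusion-exclusion. `predict_associations()`
  uses this closed form at the default $L = 3$, which is what makes full
  leave-one-out runs (one network and score recomputation per held-out
  pair) take seconds to minutes rather than hours. For $L \ge 4$ the
  recursive depth-first search is used directly. The test suite asserts
  both routes agree with a permutation brute-force path enumerator to
  1e-10.
* **Deterministic order everywhere.** DFS expands neighbours in ascending
  node order (lexicographic path order), score-table ties break by
  ascending (disease, microbe) name with locale-independent radix sorting,
  and integer association counts are formed before any division in the
  bandwidth, so repeated runs are bit-identical.
* **Degenerate inputs.** A node that loses its last association inside
  cross-validation gets the zero profile; the kernel is still well defined
  for it. Only an entirely empty matrix makes the bandwidth denominator
  vanish, which is an error. An isolated held-out pair legitimately scores
  0 and ranks last.
* **Rank ties.** A held-out pair tied with candidates receives the
  mid-rank, which makes the AUC equal the Mann-Whitney statistic with tie
  correction.

## Evaluation protocols

All three protocols remove the held-out associations *and recompute the
kernels, the network and all scores from the reduced matrix*, so test
information never leaks into the similarities.

* **Global LOOCV** ranks each held-out pair against every unverified pair
  of the original matrix (one shared candidate set).
* **Local LOOCV** ranks it only among the test disease's unconfirmed
  microbes. Candidate sets then differ in size across tests, so the
  pooled ROC is built on normalised ranks $(r-1)/n$ swept over $[0,1]$ —
  the only size-consistent pooling; on shared candidate sets it reduces
  to the usual rank-sum construction (asserted to 1e-10 in tests).
* **Repeated k-fold CV** partitions the known pairs into $k$ near-equal
  folds per repeat, recomputes once per fold (all fold pairs removed
  together), ranks globally, and reports mean and sd of the per-repeat
  AUCs. With $k$ equal to the number of known pairs it reproduces the
  global LOOCV AUC exactly (a tested identity). The conventional repeat
  count is 100; scaled-down runs simply pass a smaller `repeats`.

The ROC staircase is integrated exactly (the reported AUC equals
$1 - \overline{u}$, the mean normalised rank complement), so threshold
sweep and pair counting cannot disagree.

## What the synthetic generator emulates — and what it does not

`simulate_associations()` plants community structure: microbes and
diseases are assigned round-robin to blocks (deterministic sizes, one
fewer source of variance), and a pair associates with probability `p_in`
inside a block and `p_out` across. This reproduces the single property
the predictor relies on — similar diseases share microbes. Empty rows and
columns are repaired with one within-block association so every node is
connected; in the matched null (`p_in == p_out`) the repair instead
samples uniformly, because a block-restricted repair would itself plant
the very signal the null must lack.

The default reduced spec (60 microbes $\times$ 12 diseases, 4 blocks,
`p_in` 0.7, `p_out` 0.01) is a *degree-preserving* reduction of the
curated catalogue's scale (292 $\times$ 39, ~450 pairs): expected disease
degree stays near 11, as in the real data, so diseases genuinely share
several microbes each. Copying the full-scale cell probabilities onto the
small grid instead would leave most microbes without any sampled
association and the fixture dominated by repair singletons, whose
held-out pairs are information-free — a property of the repair, not of
the method. `hmdad_scale_fixture()` keeps the full scale and solves
`p_in` from the closed-form expectation (sampling plus expected repairs)
to hit ~450 associations.

The generator does **not** mimic the real catalogue's heavy-tailed
per-microbe degree distribution, taxonomic name structure, or curation
biases (heavily studied diseases accumulate associations). Passing
signal-recovery tests therefore shows the pipeline recovers planted
community structure at realistic sparsity; it does not certify
performance on any particular real catalogue, which also depends on
curation quality and on the unpublished $(L, \alpha, T)$ used for
reported figures.

Problem sizes used by the test suite and the acceptance script — the
reduced 60 $\times$ 12 fixture for full cross-validation runs, 10
repeats for k-fold, the 292 $\times$ 39 fixture for prediction and a
single LOOCV round — were chosen so the complete battery runs in a few
minutes on one core while still exercising every code path at the
catalogue's true scale.

## Worked example

```{r example}
Y <- simulate_associations(block_model_spec(seed = 1))
Y
cfg <- pmda_config()
cfg
ts <- predict_associations(Y, cfg)
head(score_table(ts, known = Y), 5)
loocv(Y, cfg, "global")
```

## Known limitations

* Nodes with no remaining associations cannot be ranked usefully (cold
  start): a new microbe or disease enters the network only through its
  known pairs.
* GIP similarity inherits catalogue bias — heavily investigated nodes
  look more similar to everything. No external similarity source (disease
  semantic similarity, microbe functional similarity) is integrated.
* Exact enumeration only: no sampling approximation is provided for
  $L > 4$ on large dense networks, where the path count explodes.
* Every distinct name string is a distinct node; taxonomic reconciliation
  is upstream curation work, out of scope here.
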