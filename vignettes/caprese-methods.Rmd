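---
title: "Reconstructing progression trees with probability raising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing progression trees with probability raising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprese)
```

## The inference problem

Cumulative processes such as cancer progression acquire alterations in a
partially ordered fashion: an event tends to appear only in lineages that
already carry its "cause". What we usually observe, however, is
*cross-sectional* data — one binary genotype per patient, with no timing
information. `caprese` reconstructs a rooted tree (or forest) over a set of
pre-selected binary events from an `m x n` sample-by-event 0/1 matrix:
every event gets at most one parent, the synthetic root `⋄` (label
`DIAMOND_ROOT`) represents the unaltered state, and each subtree hanging
off the root is an independent progression path.

The generative model behind this picture is the *tree-induced
distribution*: each edge `u -> v` carries a probability `p(v)`, a sample
contains the root always, and contains `v` iff it contains `u` and an
independent Bernoulli trial with probability `p(v)` succeeds. The
probability of observing an alteration set is then the product of the edge
probabilities connecting the root to that set, times the complement of
every outgoing edge that was not extended. Two consequences matter for
inference: a child is never observed without its parent (in noise-free
data), and a child's marginal probability never exceeds its parent's —
frequency is a proxy for temporal order.

## Scores: probability raising and the shrinkage-like estimator

All scores are computed from exact empirical frequencies on the
root-adjoined matrix. Event `a` is a **prima facie cause** of `b` when

* `a` raises the probability of `b`: `P(b | a) > P(b | ¬a)`, and
* `a` is more frequent than `b`: `P(a) > P(b)` (temporal priority).

Probability raising is mutual — if `a` raises `b` then `b` raises `a` — so
the direction of an edge comes entirely from the frequency clause. Both
inequalities are strict and are evaluated by cross-multiplying integer
counts, so no floating-point rounding can decide an edge. Equal-frequency
pairs are treated as temporally indistinguishable and produce no edge in
either direction; literally identical columns are merged into a composite
event beforehand (`merge_indistinguishable()`), and events observed never
or always are dropped (`drop_degenerate_events()`) because their
conditional probabilities are undefined.

Each ordered pair is scored by the **shrinkage-like estimator**

    m(a -> b) = (1 - lambda) * alpha(a -> b) + lambda * beta(a, b)

with the normalized probability-raising ratio and a correlation-like
correction factor

    alpha(a -> b) = (P(b|a) - P(b|¬a)) / (P(b|a) + P(b|¬a))
    beta(a, b)    = (P(a,b) - P(a)P(b)) / (P(a,b) + P(a)P(b))

Both live in `[-1, 1]`: `-1` for mutually exclusive pairs, `0` under
independence, `+1` when `b` never occurs without `a`. `alpha` is sharp but
saturates in noise-free data (every ancestor of `b` scores exactly 1), so
`beta`, which decays with the marginal of the candidate parent and hence
with temporal distance, breaks the tie in favour of the nearest genuine
cause. `lambda` trades the two off:

* `lambda = 0.01` (package convention for noise-free data): essentially
  pure probability raising with `beta` as an infinitesimal tie-break;
* `lambda = 0.5` (default): equal-weight averaging, the robust choice for
  noisy data;
* `lambda = 1`: pure correlation, generally too blunt.

The simulation sweeps in the test suite reproduce the expected behaviour:
mean tree edit distance as a function of `lambda` is U-shaped with an
interior optimum around `1/2` when uniform noise is present, while without
noise the small-`lambda` regime is optimal, and the optimum's location is
insensitive to the dataset size in the 50–250 sample range.

## The reconstruction algorithm

1. Adjoin the root to every sample and compute all pairwise scores.
2. **Probability-raising step**: each event `b` selects the candidate
   parent `a` maximizing `m(a -> b)` among its prima facie causes with
   `m(a -> b) > 0`; events with no valid candidate attach to the root.
   Because a prima facie cause is strictly more frequent than its effect,
   the resulting structure cannot contain a cycle. Exact score ties are
   broken toward the more frequent parent, then the lexicographically
   smaller label, making the fit deterministic.
3. **Independent progressions filter**: the best prima facie cause of `b`
   may still be spurious — most visibly when `b` actually starts a
   separate progression path. Probability raising against the omnipresent
   root is undefined (`P(¬⋄) = 0`), so the filter falls back on a
   correlation-like weight `w(a, b) = P(a, b) / (P(a) + P(b))`, which for
   the root reduces to `w(⋄, b) = P(b) / (1 + P(b))`. The edge into `b` is
   replaced by a root edge exactly when the root weight strictly exceeds
   `w(g, b)` for **every** upstream prima facie cause `g` of `b` (its
   ancestors in the candidate tree). Under exact tree-induced frequencies
   this never severs a genuine chain (the condition degenerates to
   `P(g) > 1`) and always separates exactly independent events (it
   degenerates to `P(g) < 1`), and a kept edge implies strictly positive
   dependence between child and parent — a non-negative effective
   threshold on the estimator. The filter is a single pass over the
   candidate structure; re-parenting to the root cannot create cycles.
4. Each edge finally receives the conditional frequency
   `P(parent, child) / P(parent)` as its estimated progression
   probability.

### The oncotree baseline

The classical correlation-based alternative weighs every directed edge by

    w(a -> b) = log( P(a) / (P(a) + P(b)) * P(a,b) / (P(a) P(b)) )

(temporal priority times likelihood ratio, natural log) on the
root-adjoined matrix and extracts the maximum-weight arborescence rooted
at `⋄`. No R package in this stack exposes a maximum-weight arborescence,
so `max_arborescence()` implements Chu–Liu/Edmonds (greedy best-incoming
edge, cycle contraction, recursive resolution) and is verified in the test
suite against exhaustive enumeration of all acyclic parent maps on small
instances. Both methods consume the same probability tables, so
comparisons are like-for-like.

## Synthetic data: what is emulated, and what is not

The generator defines the package's reference study conditions:

* **Topology**: `n_events = 20` labelled events; events are attached
  sequentially, each to a uniformly random existing node of depth below
  `depth_cap = ceiling(log2(n_events))` (5 at 20 events). The cap favours
  path-like trees; very wide stars, which are intrinsically harder for
  every reconstruction method, are de-emphasized. Forests fix the number
  of root children via `n_trees` (3 in the forest experiments).
* **Probabilities**: the events' *observation* (marginal) probabilities
  are sampled i.i.d. uniform on `(0.05, 0.95)` and sorted decreasingly
  along the attachment order, so child marginals never exceed parental
  ones; each edge probability is the child/parent marginal ratio. Sampling
  observable marginals — rather than conditional edge probabilities —
  keeps every event detectable at realistic sample sizes (an event with
  marginal 0.05 is seen ~2.5 times in 50 samples), which is what makes
  near-exact recovery at 250 samples attainable at all.
* **Noise**: the uniform channel replaces each entry independently with a
  fair coin with probability `nu` (flip rate `nu/2` per direction); the
  asymmetric channel applies false-positive/false-negative rates
  `eps_plus` / `eps_minus`. Uniform `nu` equals the asymmetric channel at
  `eps_plus = eps_minus = nu/2` in distribution.
* **Algebraic requirements**: the framework assumes every event frequency
  strictly inside (0, 1) and all columns pairwise distinct.
  `sample_valid_dataset()` redraws a dataset (up to 100 times) until these
  hold, mirroring the assumption that the requirements "are verified"
  before reconstruction; at 50 samples this mostly re-rolls datasets in
  which a high-probability edge produced literally identical
  parent/child columns.

What the generator does **not** emulate: unobserved confounders and
selection bias, non-independent measurement errors (batch effects),
missing data (the model is fully observed), DAG-like confluences (an event
with two genuine parents), and event-calling errors upstream of the binary
matrix. Passing simulation tests therefore certify the estimator and
algorithm under the model's own assumptions, not robustness to model
misspecification on real cohorts.

## Evaluation and confidence

Reconstruction quality is *structural*: the Zhang–Shasha tree edit
distance (unit-cost relabel/insert/delete) between the reconstructed and
generating trees, computed after sorting children by label so the ordered
algorithm becomes order-invariant on progression trees, plus the
structural Hamming distance (number of re-parented events) when the event
sets coincide. The edit-distance implementation is checked against an
exhaustive search over valid tree mappings on small cases. A single
mis-assigned parent costs 2 edits (the moved node is deleted and
re-inserted), which is worth remembering when reading mean TED values.

Bootstrap confidence follows the usual two modes: non-parametric
(resample rows with replacement, refit, count exact-tree matches and
per-edge occurrences) and parametric (resample from the fitted tree's
induced distribution through the asymmetric noise channel at
caller-specified error rates, e.g. the CGH-study convention of
`eps_plus = 0.21`, `eps_minus = 0.027`). All confidences are exact
resample-count ratios; the exact-tree confidence can never exceed any
fitted edge's confidence.

## Problem sizes and numerical choices

The reference comparison (also recomputed by `scripts/acceptance.R`) uses
100 random 20-event trees, noise-free sampling at 50 and 250 samples, 10
replicate datasets per tree and size, and `lambda = 0.01`; the lambda
study uses 40 trees at 50–250 samples with `nu = 0.15`; the asymptotic
checks use 50 trees at 10,000 samples (noise-free) and margin-satisfying
trees — all edge probabilities in (0.2, 0.9), comfortably clear of the
noise scale — at 50,000 samples with `nu = 0.025`. These sizes were chosen
so the full study runs comfortably on a laptop-class single core while
keeping Monte-Carlo error well below the effect sizes of interest.

Numerical decisions worth knowing about:

* every strict inequality that decides an edge (raising, priority, the
  filter) is evaluated on cross-multiplied integer counts, exactly;
* estimator matrices are computed vectorized in doubles and agree with the
  exact-count formulas to 1e-12 (tested);
* candidate-parent ties, arborescence ties and child orderings are all
  broken deterministically (frequency, then label, radix/C collation), so
  identical inputs give identical forests on any platform;
* degenerate inputs fail fast with informative errors, or are repaired by
  the documented drop/merge preprocessing when `preprocess = TRUE`.

## Limitations

The method infers *trees*: an event with several genuine causes will keep
at most one of them, and the number of false negatives grows with the
connectivity of the true process. The single-cause and closed-world
assumptions (all relevant events observed and pre-selected) are inherited
from the model. Uniform noise is a deliberately simple error model;
events with systematically different error rates are only partially
covered by the asymmetric channel. Finally, composite events created by
merging identical columns carry concatenated labels, which downstream
structural comparisons treat as plain labels — exactly right for the
merged dataset, but worth keeping in mind when comparing against an
external ground truth.
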