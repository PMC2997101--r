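---
title: "The arithmetic-harmonic cut: model, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The arithmetic-harmonic cut: model, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahcut)
```

## The objective

`ahcut` clusters a set of objects from their pairwise distances by
recursive bipartition of the complete weighted graph on those objects.
A bipartition (V1, V2) is scored by the *arithmetic-harmonic cut*
objective

$$f(V_1, V_2) \;=\; \underbrace{\sum_{u \in V_1,\, v \in V_2} w(u,v)}_{\text{cut\_sum}}
\;\times\;
\underbrace{\sum_{\substack{u,v \text{ on the same side}}} \frac{1}{w(u,v)}}_{\text{intra\_recip}}$$

and maximised. The first factor grows when the two clusters are far
apart; the second grows when within-cluster distances are small. Taking
the *product* of the two factors makes the objective invariant under a
uniform rescaling of all distances — a property any objective defined on
distances (rather than similarities) should have, since the unit of a
distance matrix is arbitrary. The objective is scored by a single
internal routine, so an alternative combination of the two factors (for
example their sum, which is not scale-invariant) can be swapped in at one
place if a different trade-off is ever wanted.

Conventions for degenerate cases: a side with at most one vertex
contributes nothing to `intra_recip`; with `n = 2` the unique split has
value 0; `n = 1` has no partition. Pairs absent from a non-complete graph
contribute to neither factor.

The decision form of the problem asks whether any bipartition reaches a
target encoded by two positive integers `k` and `l`. The two integers
are combined as the rational threshold `k / l` — a pair of integers is
the natural encoding of a rational bound for a product that is generally
non-integral. Although weights and thresholds could in principle be
compared in exact rational arithmetic, inputs arrive as floating-point
TSV values, so `meets_target()` compares in floating point with a
`1e-12` relative slack; at that slack an exactly attained threshold
counts as met.

### Zero distances and the weight floor

Because the objective sums reciprocals of within-side distances, a zero
distance (two identical objects) is not representable. `ah_graph()`
clamps every off-diagonal entry below `weight_floor` (default `1e-9`) up
to the floor and warns. Clamping rather than merging duplicates keeps
the evaluation total without silently changing the number of objects;
the floor is small enough that duplicate objects still end up on the
same side in practice.

## Solver stack

### Exact enumeration

For small instances `enumerate_optimum()` enumerates all
`2^(n-1) - 1` non-trivial bipartitions, fixing the first label on side 1
(the objective is symmetric under swapping sides). Assignments are
walked in gray-code order so each step updates the two factors in
O(n); the winner's breakdown is recomputed from scratch, which removes
any accumulated floating drift from the reported optimum. Ties resolve
to the lexicographically smallest side-1 label set, with a `1e-12`
relative tolerance deciding what counts as a tie. The routing threshold
between exact and heuristic solving (`exact_threshold`, default 15,
i.e. `2^14` evaluations — sub-second) and the hard cap (22, about two
million evaluations) are both configuration, not constants.

### Greedy construction

`greedy_partition()` seeds the two sides with the endpoints of a
maximum-weight edge — the two most distant objects — then repeatedly
takes the unassigned vertex with the largest total distance to the
assigned set and places it on the side that yields the larger partial
objective (evaluated incrementally, with a still-singleton side simply
contributing 0 to the reciprocal term). Two of the loop's rules are
genuinely open design points, and both are exposed as options:

* *which vertex next*: total attachment weight (default), single
  heaviest edge, or fixed lexicographic order (`strategy =`);
* *tie handling*: lexicographic in deterministic mode, uniform at random
  in randomized mode.

Maximum attachment weight was chosen as the default because it is the
standard differential-greedy ordering and is consistent with the
max-weight seed rule; placing by partial objective directly serves the
quantity being optimised. On a disconnected graph each connected
component contributes its own max-weight seed pair before the main loop.
The randomized variant used by diversity restarts draws the seed edge
uniformly from the top decile of edges by weight.

Greedy doubles as the first stage of `fpt_decide()`: a greedy solution
that meets the target is returned as a certificate; when it fails, the
instance is known to be small in the relevant parameters, and the
procedure falls back to exhaustive search. The quantitative instance
bound behind that argument is not re-derived here; the fallback is
simply routed through the exact solver (and refuses instances above the
hard cap).

### Memetic optimiser

`evolve()` maintains a complete ternary tree (default depth 3, 13
nodes — the population shape used by the pocket/current literature this
follows) of pocket/current pairs. Per generation, every parent pocket is
recombined with each child's current solution by **differential greedy
crossover**: the child's side labels are first flipped if that increases
agreement with the parent, vertices on which both agree are fixed, and
the disagreeing remainder is re-filled by the randomized greedy loop.
If alignment leaves one side's seed empty, the heaviest edge among the
unassigned vertices re-seeds it: when both seeds are empty its two
endpoints go to opposite sides exactly like a greedy seed, and when only
one is empty the endpoint with the larger total distance to the opposite
seed fills it. (Placing *both* endpoints of a maximum-distance pair on
one side would work against the objective, so the rule splits them.)

Offspring are improved by **variable neighbourhood search**: the order-k
neighbourhood flips the side of exactly k vertices; order 1 is scanned
exhaustively via incremental O(degree) move evaluation,
orders `k >= 2` try `vns_samples` (default 100) random k-subsets; any
strict improvement moves the incumbent and resets k to 1; the search
stops when k exceeds `k_max` (default 3 — single and double flips do
nearly all the work in bipartitioning, and each additional order
multiplies cost for sharply diminishing returns). `k > k_max` is the
only stop criterion. Moves that would empty a side are never taken.

The improved offspring replaces the child's current; a current strictly
better than its node's pocket becomes the pocket; and whole individuals
are swapped along tree edges until every parent's pocket is at least as
good as its children's (moving pocket/current pairs together keeps
`pocket >= current` true at every node). After
`stagnation_generations` (default 20) without improvement of the root
pocket, the best individual is kept and the rest of the population is
re-initialised from randomized greedy starts. The run stops at
`max_generations` (default 200). All "strictly better" comparisons use
an absolute `1e-12` slack so floating-point noise cannot cycle
solutions. The defaults are sized for desk-scale problems (tens to a
few hundred objects) and are all configurable.

Each VNS result and each returned partition is re-evaluated from
scratch, so cached breakdowns always match a full recomputation to well
under the documented `1e-9` relative tolerance.

### Recursive hierarchy

`build_dendrogram()` applies `bipartition_dispatch()` (exact below
`exact_threshold`, memetic above) to the graph, recurses on the two
induced subgraphs, and stops at single vertices — no early stopping by
split quality, so the tree is always complete down to leaves. Children
are ordered so the side containing the lexicographically smallest label
comes first, making Newick output reproducible. `cut_tree(k)` expands
the frontier node with the largest split value until k sets remain;
splits of large, well-separated sets carry the largest objective values,
so they are undone first. This expansion order is this package's
convention — the recursive construction itself does not define a flat
clustering — and it is what makes "cut at k clusters" comparisons
well-defined. Split values are annotations on internal nodes (exported
as Newick comments), not metric branch lengths.

## Distances

`correlation_distance()` computes `d(x, y) = 1 - r(x, y)` between sample
columns of an expression matrix, with `r` the mean-centred Pearson
correlation (the default) or the uncentred cosine variant, which older
expression tooling distinguishes. Entries lie in `[0, 2]`; perfectly
correlated samples are at distance 0, which the graph constructor's
weight floor then clamps. Missing values are rejected rather than
imputed — silent imputation would corrupt benchmark comparisons — and a
zero-variance sample is an error naming the sample. All supplied genes
are used; filtering is the caller's concern.

## Synthetic data

`generate_expression()` draws three groups of samples from multivariate
normal distributions with diagonal covariance `sigma^2 I` that differ
only in their mean vectors: each group owns a disjoint block of
`n_signature` genes, of which `n_down` are under-expressed (mean
`mu_down`) and `n_up` over-expressed (mean `mu_up`); all other genes
have mean zero. The defaults — groups of 30/15/15 samples (one
predominant subtype, two rarer ones), 500 genes, 30 signature genes per
group split 10 down / 20 up, shifts of ±1 and a common `sigma = 0.5` —
are desk-scale choices that preserve the qualitative regime of
large-sample subtype benchmarks: signatures are a small fraction of the
genes, and the per-gene shift (two standard deviations) is modest, so
recovery has to come from aggregating many weakly informative genes.
With these defaults the pairwise centred-correlation distances place
same-group samples around 0.8 and different-group samples around 1.0 —
separated, but by only a few estimation standard errors, so the planted
structure is recoverable yet not trivial. `sigma` is a free parameter
(in real data one would anchor it to a quantile of observed per-gene
standard deviations).

The generator emulates group structure only: no batch effects, dropout,
heavy tails, gene-gene correlation or missingness. Tests passing on
this generator therefore demonstrate correctness of the optimisation
and recovery machinery under the stated model, not robustness to the
artefacts of real expression data.

`planted_partition_graph()` is the distance-space analogue (exact block
distances plus optional uniform noise) used for solver-level tests, and
`random_weighted_graph()` supplies unstructured instances for
oracle-equivalence checks.

## Validation problem sizes

The shipped tests and the acceptance script validate at sizes chosen to
make exhaustive oracles feasible: solver equivalence on 200 random
complete graphs with n in 3..10 (every instance fully enumerated),
incremental-vs-scratch agreement on 1000 random move triples, planted
three-group recovery on ten pipeline runs of 60 samples × 500 genes, and
a 12-vertex three-group fixture whose every split is enumeration-checked.
These sizes are the package's own validation design; the solvers
themselves handle larger inputs (the memetic path has no enumeration
anywhere).

## Known limitations

* The objective is defined on distances; similarity matrices must be
  converted by the caller.
* Exact solving is capped at 22 vertices by design.
* The memetic solver offers stochastic, not guaranteed, optimality above
  `exact_threshold`; determinism is per-seed.
* `cut_tree`'s largest-split-first expansion is a convention; other
  orders (e.g. balanced frontier) could be added.
* Reproducibility uses one R RNG stream seeded once per top-level call;
  component-level substreams were considered and dropped as needless
  complexity at this scale.
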