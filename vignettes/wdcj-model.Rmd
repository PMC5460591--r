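---
title: "The wDCJ model: distances, scenarios and evolution with intergene sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wDCJ model: distances, scenarios and evolution with intergene sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdcj)
```

## The model and its assumptions

A genome is a weighted perfect matching on `2n` labelled vertices.  Each
vertex is a gene extremity (every gene contributes a tail `g_t` and a
head `g_h`), each edge is an adjacency between two extremities, and the
edge weight is the intergene size: the number of nucleotides between the
two genes, a non-negative integer.  This representation covers circular
chromosomes exactly and co-tailed linear genomes after dropping the
telomeric extremities; it assumes equal gene content with no duplicates
(a matching, by construction).  `gene_order_to_genome()` performs the
standard encoding from signed circular gene orders: a gene traversed as
`+g` contributes the extremity order `(g_t, g_h)`, as `-g` the order
`(g_h, g_t)`, and each adjacency joins the trailing extremity of a gene
to the leading extremity of its circular successor, weighted by the
intergene between them.

A wDCJ cuts adjacencies `ab` and `cd` and rejoins `ac|bd` or `ad|bc`,
assigning the new adjacencies any non-negative integer weights with
`w(ac) + w(bd) = w(ab) + w(cd)`.  Biologically, the freed nucleotides of
the two broken intergenes are redistributed over the two new intergenes;
the total intergene size `W` of the genome is invariant, which is why
only evenly weighted pairs (`W(g1) = W(g2)`) are comparable
(`genome_pair()` enforces this).

The breakpoint graph of a pair is the union of the two matchings: a
disjoint set of even, alternating cycles.  With `c` cycles of which
`n_u` have nonzero imbalance `I(C) = w1(C) − w2(C)`, the distance is
`n − c + 2m`, where `m` is the minimum number of cycle merges that turn
the unbalanced cycles into balanced ones.  The structure theory behind
this formula — in any optimal scenario freezes and split-then-merge
round trips can be eliminated, merges can be pushed before splits, and
balanced cycles are never merged — is not re-implemented as a rewriting
system; it is embodied in the *normal form* of every scenario the
package emits: `m` merges first, then only splits.

`m = n_u − p`, where `p` is the maximum number of zero-sum groups into
which the multiset of unbalanced imbalances can be partitioned
(Max-Zero-Sum-Partition).  This is the NP-hard core; everything else is
polynomial.

## The solvers and their parameters

**Dynamic program** (`mzsp_dp()`, used by `wdcj_distance(method =
"dp")`).  A Held-Karp style table over the `3^{n_u}` ways of splitting
the index set into (current part, still free, already used).  The
implementation iterates over zero-sum subsets `S` and enumerates the
part containing the smallest element of `S`, which visits exactly those
`3^n` states; a witness partition is recovered by backtracking.  It runs
in C++; the default capacity `cap = 20` elements (about `3^20 ≈ 3.5e9`
state transitions, a few seconds) raises a distinct capacity error
beyond that, pointing to the ILP route.  Under the evolution model
`n_u` stays around ten even for `k = 10000` operations on `n = 1000`
genes (see below), so the cap is generous in practice.

**Integer program** (`mzsp_ilp()`).  The formulation has binary
variables `x[i,j]` (cycle `i` in part `j`, `j ≤ floor(n_u/2)`, since a
zero-sum part needs at least two nonzero imbalances) and part-use
indicators `p[j]`, with constraints (each cycle in exactly one part;
each part's imbalance sum zero; `p[j] ≤ Σ_i x[i,j]`) and objective
`max Σ_j p[j]`.  The inequality on `p[j]` is the natural linear
encoding of "a part counts only if it is used": maximisation pushes
`p[j]` to 1 exactly for nonempty parts.  No MILP
solver is part of this package's dependency set, so the program is
solved by an exact depth-first branch and bound written for this model:
elements are assigned to parts in index order, infeasible branches are
cut when more parts are open (nonzero partial sum) than elements remain,
and the admissible bound `p ≤ #nonempty + floor((remaining − open)/2)`
prunes the search.  `symmetry_break = TRUE` (default) only ever opens
the lowest-indexed unused part — the standard cure for the permuted-part
symmetry of assignment formulations — and provably does not change the
optimum (tests compare both settings).

**Brute force** (`mzsp_bruteforce()`, capacity 10).  A full enumeration
of set partitions, kept deliberately independent of the other two
solvers so it can serve as their oracle in the test suite.

**Approximation** (`wdcj_distance(method = "approx")`).  Step (a) pairs
every imbalance with an opposite where possible (optimal for pairs:
`Σ_v min(count(v), count(−v))` pairs); step (b) greedily extracts
zero-sum triplets from the remainder, which is a 1/3-approximation of
the optimal triplet count; step (c) chains every cycle still unbalanced
into a single balanced cycle.  The result is at most 4/3 of the exact
distance and never below it.  The greedy orders are not fixed by the
theory, so determinism is imposed: candidates `x` are scanned in
ascending value (ties by index), and the completing pair `(y, z)` is the
first zero-sum hit in ascending pair order.  A leftover of exactly one
cycle is impossible (its imbalance would be a nonzero total) and is
asserted, not handled.

## Scenarios

`sorting_scenario()` turns a distance report into operations.  Merges:
within each zero-sum part, cycles are chained in ascending cycle index;
each merge cuts the genome-1 edge at the canonical start vertex of each
cycle and lets each join inherit the weight of the cut edge on its side
(identity transfer — any conserving rule would do; identity keeps replay
trivially checkable).  Splits: while any cycle has length ≥ 4 (all are
balanced by then), the first triple `e, f, g` of consecutive edges with
`e, g` in genome 1 and `w(e) + w(g) ≥ w(f)` — guaranteed to exist in a
balanced cycle, else summing the reversed inequality around the cycle
would force a negative weight — is resolved by cutting `e` and `g` and
joining the middle pair at weight `w(f)`, which detaches one balanced
trivial cycle.  The first qualifying triple from the canonical start is
taken (the theory proves existence, not choice).  Scenario length always
equals the reported distance, for exact and approximate plans alike;
`validate_scenario()` replays every step under the full invariant
checks.

## The evolution chain and its equilibrium

`simulate_trajectory()` runs the Markov chain: an unordered pair of
distinct adjacencies is chosen uniformly, the recombination type is a
fair coin, and the new weights are `x + y` and the remainder, with
`x ~ U{0..w(ab)}`, `y ~ U{0..w(cd)}` (endpoints included — the integer
counting that underlies the equilibrium argument needs the closed
range), the side again a fair coin.  The equilibrium probability of a
genome is proportional to the product of its intergene sizes.
`sample_equilibrium_genome()` samples it directly: a uniform matching,
weights as independent Gamma(shape 2, scale 1) variates — the
parameterisation whose normalisation is a symmetric Dirichlet with
concentration 2 — scaled to the requested total `W` and rounded by
largest remainder so the integer total is met exactly.  The rounding
bias is `O(n/W)` and negligible at the default scales (`W = 1e5`,
`n = 10` in the reproduction script).

`fit_dirichlet_alpha()` is a Newton iteration on the one-parameter
log-likelihood (gradient `N d [ψ(dα) − ψ(α)] + Σ log x`), started from
the method-of-moments value, with tolerance `1e-8`.  The likelihood is
concave in `α`, so convergence is immediate.  Degenerate inputs are
handled explicitly: vectors with a zero coordinate make the
log-likelihood `−∞` and are dropped with a warning; variance-free input
(all vectors uniform) drives the MLE to infinity and returns `Inf` with
a warning.

Detailed balance of the chain holds exactly only in the large-weight
limit: the proportionality argument for the transition probabilities
neglects boundary effects of the integer draws, and states with
zero-weight edges (equilibrium probability zero) remain reachable.
`stationarity_ratio_check()` therefore computes the two-sided
equilibrium ratio by exact enumeration of the `(x, y)` draws; tests
assert it lies near 1 and converges to 1 as the four involved weights
are scaled up, and the small-state empirical check of the visit
distribution is restricted to strictly positive weights.

## Synthetic instances

The generators define the study conditions, they are not tuning knobs.

* `reduction_from_3partition()` reproduces the hardness construction:
  both genomes share one matching on `8n` vertices, so the breakpoint
  graph is `4n` trivial cycles; the first `3n` carry imbalances `a_i`,
  the last `n` carry `−B`.  The bounds `B/4 < a_i < B/2` force every
  balanced group to use exactly three `a_i` and one `−B`, hence the
  distance is `6n` iff the 3-Partition instance is satisfiable (the
  tests also exercise an unsatisfiable instance, whose distance is 14
  rather than 12).
* `random_genome_pair()` draws two independent uniform matchings with
  weights uniform on `0..max_weight` and evens the totals by adding the
  deficit to the canonically last edge of the lighter genome — the
  simplest conserving correction; it slightly inflates one weight and is
  documented rather than hidden.
* `random_zero_sum_multiset()` draws `size − 1` nonzero values and
  closes with the negated sum, rejecting out-of-range closures.

What these emulate — and what they do not: uniform random matchings and
uniform/Gamma weights probe the combinatorics at realistic imbalance
densities, but real genomes have length-biased intergene distributions,
unequal gene content, duplications and indels, none of which the model
covers (non-co-tailed genomes and indel models are explicitly out of
scope).  Passing tests therefore certify the algorithms on the model's
own terms, not goodness of fit to any particular genome pair.

## Verification design and problem sizes

The distance path is checked against an oracle that knows nothing of
breakpoint graphs: the full wDCJ move graph on all genome pairs with at
most 6 vertices and total weight at most 6 (about 360000 ordered pairs),
whose unweighted shortest paths are computed with igraph.  Pairs are
grouped by breakpoint-graph signature — `(n, c, sorted imbalances)`
determines both the exact and the approximate distance — so each
signature is solved once while every pair is still compared with the
oracle individually.  The same family plus 500 random pairs (`n ≤ 8`,
weights `≤ 10`) bounds the empirical approximation ratio by 4/3.  The
partition solvers are cross-checked exhaustively (elements in `−6..6`,
up to 6 of them) and on 200 random zero-sum multisets.  The chain is
checked at `n = 100` over 20 trajectories of 2000 steps (the mean of
`n_u` at every `k` stays below `k/√n`) and once at `n = 1000` over
10000 steps, where `n_u` stays of order ten with a flat mean — the
regime in which the fixed-parameter and integer-programming solvers stay
fast.  These sizes were chosen so each claim is tested at the scale at
which it is stated while the whole suite remains a routine run.

## Known limitations

* Only circular (or pre-converted co-tailed) genomes; no capping of
  linear chromosomes, no unequal content, no gene families.
* `mzsp_dp()` is memory- and time-exponential past ~20 unbalanced
  cycles; the branch-and-bound ILP has no polynomial guarantee either
  (the problem is strongly NP-hard) but is the practical fallback.
* The equilibrium statements are exact only in the continuous /
  large-weight idealisation; at small weights the discrete boundary
  effects are visible, which is why the checks scale the weights up.
* The alternative chain in which rearrangement sites are drawn
  proportionally to the weights of the involved edges is out of scope.
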