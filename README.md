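# wdcj — genome rearrangement by double cut and join with intergene sizes

Comparative genomics usually models a genome as an ordering of genes and
measures evolutionary distance by counting rearrangements, classically
with the double cut and join (DCJ) operation.  But consecutive genes are
separated by intergenic regions of very different sizes, and ignoring
those sizes is known to distort distance estimation.  `wdcj` implements a
rearrangement model in which the intergene sizes evolve together with the
gene order.

A genome with circular (or co-tailed) chromosomes is a **weighted perfect
matching**: the `2n` vertices are gene extremities, each of the `n` edges
is a gene adjacency, and its weight is the intergene size in nucleotides.
A **wDCJ** cuts two adjacencies `ab` and `cd` and rejoins `ac|bd` or
`ad|bc`, giving the two new adjacencies arbitrary non-negative integer
weights subject to conservation, `w(ac) + w(bd) = w(ab) + w(cd)`.  For two
evenly weighted genomes (`W(g1) = W(g2)`), the union of the matchings is
the breakpoint graph, a disjoint set of even alternating cycles; each
cycle `C` has imbalance `I(C) = w1(C) − w2(C)` and is *balanced* when
`I(C) = 0`.  The distance is

```
wDCJ(g1, g2) = n − c + 2m ,      m = n_u − p ,
```

where `c` counts cycles, `n_u` counts unbalanced ones, and `p` is the
largest number of zero-sum groups the unbalanced imbalances can be split
into (each group of `k` cycles is balanced with `k − 1` merges).
Computing `p` — the Max-Zero-Sum-Partition problem — is strongly NP-hard,
but fixed-parameter tractable in `n_u`.  The package provides:

* **genome I/O** — weighted adjacency lists (`.wadj`) and circular gene
  orders with intergene sizes (`.wgo`), converted via the
  tail/head-extremity encoding;
* **breakpoint graphs** — deterministic cycle decomposition with
  per-cycle weights and imbalances (`breakpoint_graph()`);
* **exact distances** — `wdcj_distance(pair, "dp")`, an `O*(3^{n_u})`
  Held-Karp style dynamic program (in C++), and `"ilp"`, the
  integer-programming formulation of `p` solved exactly by branch and
  bound (`mzsp_dp()`, `mzsp_ilp()`, `mzsp_bruteforce()`);
* **a 4/3-approximation** — `"approx"`: merge opposite-imbalance pairs,
  then greedy zero-sum triplets (a 1/3-approximation of the triplet
  optimum), then chain the rest;
* **explicit scenarios** — `sorting_scenario()` emits an optimal (or
  certified approximate) list of wDCJ operations, all merges before all
  splits, replayable and checkable with `validate_scenario()`;
* **evolution simulation** — the Markov chain that applies uniform random
  wDCJ with uniform integer weight re-draws (`simulate_trajectory()`),
  whose equilibrium gives a genome probability proportional to the
  product of its intergene sizes; `sample_equilibrium_genome()` samples
  it directly (uniform matching + Gamma(2,1) weights, i.e. a symmetric
  Dirichlet(2) law after normalisation) and `fit_dirichlet_alpha()`
  recovers the concentration by maximum likelihood;
* **hard and random instances** — `reduction_from_3partition()` (the
  NP-hardness construction: `4n` trivial cycles, distance `6n` iff the
  3-Partition instance is satisfiable), `random_genome_pair()`,
  `random_zero_sum_multiset()`.

## Worked example

Two circular genomes on genes `a`, `b`, `c` whose intergene sizes total
14 nucleotides each:

```r
library(wdcj)
g1 <- gene_order_to_genome(gene_order(list("+a 5 -b 7 +c 2")))
g2 <- gene_order_to_genome(gene_order(list("+a 1 +b 9 +c 4")))
pair <- genome_pair(g1, g2)
breakpoint_graph(pair)
#> breakpoint graph: n = 3, c = 2 (balanced 0, unbalanced 2)
#>   cycle length w1 w2 imbalance
#> 1     1      4 12 10         2
#> 2     2      2  2  4        -2
```

Two unbalanced cycles with imbalances `+2` and `−2` form one zero-sum
group (`p = 1`), so one merge is unavoidable: the distance is
`n − c + 2m = 3 − 2 + 2 = 3`.

```r
rep <- wdcj_distance(pair, method = "dp")
rep
#> wDCJ distance (dp): 3  [n = 3, c = 2, n_b = 0, n_u = 2, m = 1, p = 1]
scn <- sorting_scenario(pair, plan = rep)
scn
#> wDCJ sorting scenario (dp): 3 step(s), 1 merge(s) then 2 split(s)
validate_scenario(scn)
#> [1] TRUE
```

The three steps (one merge, then two splits, each peeling off one
adjacency of `g2` with its final intergene size):

```
CUT a_h-b_h[5] a_t-c_h[2] JOIN a_h-a_t[5] b_h-c_h[2]
CUT a_h-a_t[5] c_h-b_h[2] JOIN a_t-c_h[4] a_h-b_h[3]
CUT a_h-b_h[3] c_t-b_t[7] JOIN b_h-c_t[9] a_h-b_t[1]
```

The same computations are available from a shell through the thin wrapper
installed with the package:

```sh
wdcj=$(Rscript -e 'cat(system.file("scripts", "wdcj", package = "wdcj"))')
$wdcj dist --method dp pair.wadj
$wdcj sort --method dp pair.wadj
$wdcj simulate --n 1000 --steps 10000 --total-weight 100000 --seed 42 --out traj.tsv
```

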