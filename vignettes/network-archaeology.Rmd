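---
title: "Network archaeology: models, estimators, and bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network archaeology: models, estimators, and bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarch)
```

## The inference problem

A network grows by accretion: nodes arrive one at a time and connect to the
existing graph. Long after the growth has finished we observe a single
*snapshot* whose labels have been scrambled by a permutation $\pi$ drawn
uniformly at random, and we want to recover the hidden arrival order
$\pi^{-1}$. A total-order answer is hopeless — graphs have too many internal
symmetries, and the set of maximum-likelihood orderings is exponentially
large — so the estimators in this package return *partial orders*: they rank
some pairs of nodes and abstain on the rest.

Three quantities summarize a partial order $\sigma$ with $K(\sigma)$
comparable pairs on $n$ nodes:

* **density** $\delta(\sigma) = K(\sigma) / \binom{n}{2}$,
* **precision** $\theta(\sigma)$ = fraction of comparable pairs whose
  declared direction matches the true arrival order,
* **recall** $\rho(\sigma)$ = correct pairs over all $\binom{n}{2}$ pairs,
  so $\rho = \theta \cdot \delta$ whenever $K > 0$.

`score_order()` computes all three against a known ground truth; the identity
is exercised on every scored instance in the test suite.

## Growth models and their defaults

`simulate_pa(n, m)` implements preferential attachment: at $t = 1$ a single
node is created with $m$ self-loops (each contributing 2 to its degree); node
$t > 1$ then makes $m$ independent connections, picking node $k$ with
probability $\mathrm{deg}_{t-1}(k) / (2 E_{t-1})$, where $E_{t-1}$ is the
number of edges already present. For fixed $m$ the denominator is the
familiar $2m(t-1)$; stating it through the edge count is what lets the same
rule drive the variable-$M$ model, where each arrival draws
$M \sim \mathrm{unif}\{a, b\}$. All $m$ draws of one step see degrees frozen
at $t-1$, and parallel edges are kept — the snapshot is a multigraph.
`simulate_ua()` differs only in choosing targets uniformly among existing
nodes; it reuses the self-loop seed so that the degree identities
($\sum \deg = 2mt$) hold across models.

`simulate_cooper_frieze()` covers the general web-graph model: each step
adds a new node with probability `cf_new_node_prob` (default 0.75) or,
otherwise, adds edges between existing nodes; every endpoint not belonging
to the arriving node is chosen preferentially with probability
`cf_pref_prob` (default 0.5) and uniformly otherwise. Two details of the
published description are open and were fixed here once: an edges-only step
draws a fresh $M$ from the same $\mathrm{unif}\{a,b\}$ distribution as a
node step, and every endpoint flips its own preferential/uniform coin.
Both choices are the least-structured reading of the description, and at the
parameter extremes (`cf_new_node_prob = 1`, `cf_pref_prob` $\in \{0, 1\}$)
the process provably collapses onto the PA and UA simulators, which the test
suite verifies distributionally. The model starts from one node (an
edges-only step before any node exists would be undefined), so the first
step is always a node addition.

`permute_snapshot()` applies the uniform relabeling and retains the hidden
inverse permutation for evaluation. Every simulator takes an explicit seed
and uses one RNG stream, so runs are bit-reproducible.

## Peeling and the three estimators

Orient every edge of the grown graph from its younger to its older endpoint
and you get the age DAG; it encodes exactly the order information that holds
with probability one. `peel()` recovers this DAG from the scrambled
snapshot: repeatedly collect all nodes at the *current minimum degree* into
a bin, orient their edges toward the surviving endpoints, and delete them.
On a fixed-$m$ PA snapshot the minimum-degree nodes are precisely the
degree-$m$ nodes, the recovered arc multiset equals the relabeled true DAG
on every tested seed, and every arc crosses strictly between bins.
Min-degree rounds are also well defined on variable-$M$, UA and
Cooper–Frieze snapshots, where peeling is a heuristic; that generalization
is the package default (`mode = "min_degree"`), with `mode = "fixed_m"`
available as a strict variant that asserts the fixed-$m$ regime. Edges
joining two nodes of the same bin cannot be oriented with probability 1 and
are dropped (for fixed-$m$ PA this never happens to a non-loop edge);
self-loops never carry order information.

Three estimators read the peel differently:

* `perfect_precision_order()` — "u before v" iff v reaches u along DAG
  arcs. We use directed *reachability* rather than raw arcs because a
  partial order must be transitive; the raw arc count is kept as a
  diagnostic (`raw_arc_pairs`). On fixed-$m$ PA and UA snapshots its
  precision is exactly 1, but it certifies only a vanishing share of pairs.
* `peeling_order()` — earlier bins are younger; pairs within a bin stay
  incomparable. Dense ($\Theta(n^2)$ pairs) and still highly precise.
* `peeling_plus_order()` — additionally orders same-bin pairs by *average
  neighbor level* (mean peel level over the node's neighbor multiset,
  self-loops excluded): a high value marks a young node. Exact ties and
  isolated nodes stay incomparable, so its density can sit marginally below
  1; it trades a little precision for a near-total order.

Scoring a bin order never materializes its $\sim n^2/2$ pairs: correct-pair
counts are Fenwick-tree inversion counts in $O(n \log n)$, which is why the
robustness experiments at $n = 5000$ run in seconds.

## Posterior pair probabilities via linear extensions

The probability $p_{u,v}(H)$ that $u$ arrived before $v$ given the snapshot
equals the fraction of linear extensions of the recovered DAG that rank $u$
first. Counting linear extensions is #P-complete, so `exact_pair_probs()`
(exhaustive backtracking) is capped at small $n$ and serves as the oracle
for the sampler.

`mcmc_pair_probs()` implements the ratio-form random walk on the
linear-extension graph $G_{LE}$: states are extensions, moves are adjacent
transpositions, and a swap is admissible iff the two adjacent nodes are not
joined by a DAG arc (adjacent elements of an extension can only be
comparable through a direct arc — a longer path would force an intermediate
element between them). The walk chooses uniformly among admissible swaps,
with *no* lazy self-loops, so its stationary distribution is proportional to
the state degree $d(\lambda)$; the accumulators
$$\hat p^{(k)}_{u,v} = \frac{\sum_{t \le k} \mathbf 1\{X_t(u) < X_t(v)\}/d(X_t)}
                            {\sum_{t \le k} 1/d(X_t)}$$
cancel that bias exactly. This is deliberately *not* the classical
lazy-chain approach to uniform extension sampling, whose
$O(n^6 \log n \log(1/\varepsilon))$ mixing bound (and heavy self-loop
probability) makes it impractical here; since we only need averages, the
non-lazy walk converges much faster in practice. Forced pairs come out
exactly 0/1 and jointly requested reciprocal pairs sum to 1 exactly because
they share walk samples. The walk kernel is compiled (Rcpp) and driven by
R's RNG, so `set.seed()` controls it; states are recorded at every step
(thinning would only discard information for averages), and an optional
stopping rule ends the walk when all requested estimates move less than
`tol` between consecutive windows (defaults $10^4$ states, $10^{-3}$).

The initial state comes from the *sequential* variant of peeling — remove
one uniformly chosen minimum-degree node at a time; the reversed removal
order is a valid extension — when the snapshot is available. For a bare DAG
the package falls back to a random topological order drawn by uniform
choice among currently available nodes. Neither initializer is uniform over
extensions (the tests demonstrate the bias on a 4-node example); that is
irrelevant to the ratio estimator, which only needs a valid starting state.

## The LP upper bound

Fixing a density floor $\varepsilon$, the best achievable expected precision
$\theta^*(\varepsilon)$ is the optimum of a fractional 0/1 program over
indicators $x_{u,v}$ ("u before v"): maximize
$\sum p_{u,v} x_{u,v} / \sum x_{u,v}$ subject to antisymmetry
($x_{u,v} + x_{v,u} \le 1$), transitivity
($x_{u,w} \ge x_{u,v} + x_{v,w} - 1$ for all ordered triples), and
$\sum x_{u,v} \ge \varepsilon \binom{n}{2}$. Because the printed numerator
runs over $u < v$ in label order while the denominator runs over all ordered
pairs, the implementation applies the reciprocity $p_{v,u} = 1 - p_{u,v}$
and sums both orientations consistently. Relaxing $x \in [0,1]$ and applying
the Charnes–Cooper substitution $y = t\,x$, $\sum y = 1$ turns the ratio
into a linear program whose optimum upper-bounds every integer assignment —
but is *only* a bound: rounding it into a certified estimator is a separate,
hard problem and out of scope.

Numerical choices worth recording:

* The substitution leaves $t$ unbounded at $\varepsilon = 0$; we cap
  $t \le 4\binom{n}{2}$. Any feasible $x$ with a smaller mass can be scaled
  up into the capped region without changing its objective (scaling down is
  always feasible; scaling up stays feasible while all
  $x_{u,v} \le 1/(2\binom{n}{2})$, which is the only regime the cap
  excludes), so the optimum is unaffected.
* Transitivity contributes $n(n-1)(n-2)$ rows; at $n = 50$ solving with all
  $\sim 1.2 \times 10^5$ rows takes ~30 s per floor, so the default is a
  cutting-plane loop (solve, add violated rows, repeat) that converges in
  ~10 rounds, and `bound_curve()` shares the accumulated cut pool across the
  whole $\varepsilon$ grid in a single solver call.
* The LP itself is solved by HiGHS via the system Python's scipy; a dense
  pure-R simplex backend (`boot::simplex`, full transitivity) covers small
  instances, and the two backends are cross-checked to $10^{-6}$ in the
  tests. The brute-force integer oracle enumerates all labeled posets
  (4231 on five elements) by deciding each pair under incremental transitive
  closure.
* `bound_curve()` caps $n$ at 60: the coefficient estimation plus LP effort
  grows roughly like $O(n^5 \log^3 n)$, and the study scale for the curve is
  $n = 50$.

A subtlety when comparing estimators to the curve: the LP bounds the
*posterior expected* precision given the snapshot, so a single realized
$\theta$ can exceed it by luck. The tests therefore check (i) per-instance
dominance of each estimator's objective evaluated under the LP's own
coefficients, and (ii) seed-averaged $(\delta, \theta)$ points against the
averaged curve, mirroring how such curves are plotted with averaged bold
points.

## Brain networks from correlation matrices

The connectome application starts from a finished region-by-region
correlation matrix (the fMRI processing that produces it is out of scope).
Two builders are provided because the source description mentions both
without tying either to a figure; the choice is an argument (and a CLI
flag):

* `graph_mst_knn()` — a *maximum*-weight spanning tree (correlation is a
  similarity; a minimum tree would connect the least-similar regions first)
  plus each region's $k$ highest-correlation neighbors, $k = 10$ by default.
  Neighbor edges are added symmetrically: an edge is kept when either
  endpoint ranks the other in its top $k$.
* `graph_threshold_connected()` — the largest threshold whose surviving
  edges leave the graph connected, found by binary search over the sorted
  weights; the classical bottleneck equivalence (the threshold equals the
  weakest maximum-spanning-tree edge) is used as an independent oracle in
  the tests.

Signed correlations are used as weights by default with an `use_abs` option,
since the sign convention after Gaussianization is not fixed by the source
material. `rank_regions()` peels the resulting graph and reports bins
numbered oldest-first (bin 1 = highest peel level), the convention used when
mapping arrival batches onto the cortex. On synthetic connectomes grown by
preferential attachment ($n = 300$, $m = 5$) the bin rank correlates with
the true arrival rank at Spearman $\rho > 0.8$.

## What the synthetic generators do and do not show

All quantitative claims validated by this package's tests are statements
about *model-generated* data: PA/UA/Cooper–Frieze multigraphs with known
arrival order, uniformly scrambled labels, and (for the connectome path)
correlation matrices of synthetic provenance. Real networks differ in ways
the generators do not emulate — timestamp ties, deletion of nodes and edges,
communities, degree correlations, and measurement noise in correlation
estimates. Passing tests therefore certify the algorithms and their
agreement with the published simulated results, not performance on any
particular real dataset; the same estimators can be applied to user data
through `read_edge_list()` and the CLI, with ground-truth files enabling the
same scoring.

## Problem sizes and test budgets

The suite reproduces the robustness table at its published size
($n = 5000$, 10 replicates per cell), checks exact recovery at
$n \in \{100, 1000\}$ for $m \in \{1, 3, 25\}$ over 20 seeds, validates the
walk against exhaustive enumeration on 50 random 8-node DAGs at
$k = 2 \times 10^5$ steps, and runs the LP dominance properties at the
curve's study scale $n = 50$ with $k = 10^5$ walk states. These sizes were
chosen to match the published experiments while keeping a full test run in
the minutes range on a single core.

## Known limitations

* Peeling's exactness is a fixed-$m$ PA property; on other models it is a
  well-performing heuristic and the recovered "DAG" may orient some arcs
  incorrectly (which is precisely what the robustness table quantifies).
* `perfect_precision_order()` builds a dense reachability matrix
  ($n \le 4000$ guard); beyond that the closure pair count approaches
  $n^2/2$ and a different representation would be needed.
* The LP bound requires estimated coefficients; with MCMC noise the bound
  inherits an $O(\max_k |\hat p - p|)$ error, which is why dominance checks
  carry a 0.01 slack.
* Non-linear attachment kernels, fitness models, and directed-growth
  variants are out of scope.
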