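#include <Rcpp.h>
using namespace Rcpp;

// Simple random walk on the linear-extension graph G_LE.
//
// States are linear extensions (oldest node first).  Two extensions are
// adjacent iff they differ by one admissible adjacent transposition; a swap
// of positions (i, i+1) is admissible iff the two nodes are not joined by a
// DAG arc (a "perfect pair").  The walk picks uniformly among admissible
// swaps, so its stationary distribution is proportional to the state degree
// d(lambda); the ratio-form accumulators
//   num[pair] = sum_t 1{pos(u) < pos(v)} / d(X_t),   den = sum_t 1 / d(X_t)
// debias that weighting so num/den -> p_{u,v} almost surely.  No lazy
// self-loops are added.
//
// The function advances `steps` states starting from (and accumulating)
// `seq0`, continuing accumulators num0/den0, and returns the state reached
// so callers can chunk the walk (convergence windows) without restarting.
// Uses R's RNG, so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".walk_chunk")]]
List walk_chunk(LogicalMatrix adj, IntegerVector seq0, IntegerMatrix pairs,
                int steps, NumericVector num0, double den0) {
  int n = adj.nrow();
  int P = pairs.nrow();
  if (seq0.size() != n) stop("extension length must equal node count");
  std::vector<int> seq(n), pos(n), adm(n);
  for (int i = 0; i < n; ++i) {
    seq[i] = seq0[i] - 1;
    if (seq[i] < 0 || seq[i] >= n) stop("invalid extension");
    pos[seq[i]] = i;
  }
  std::vector<int> pu(P), pv(P);
  for (int j = 0; j < P; ++j) {
    pu[j] = pairs(j, 0) - 1;
    pv[j] = pairs(j, 1) - 1;
  }
  NumericVector num = clone(num0);
  double den = den0;
  for (int t = 0; t < steps; ++t) {
    int d = 0;
    for (int i = 0; i + 1 < n; ++i) {
      if (!adj(seq[i], seq[i + 1])) adm[d++] = i;
    }
    if (d == 0)
      stop("extension graph state with no admissible transposition; the DAG admits a single extension");
    double w = 1.0 / d;
    den += w;
    for (int j = 0; j < P; ++j) {
      if (pos[pu[j]] < pos[pv[j]]) num[j] += w;
    }
    int r = (int)(unif_rand() * d);
    if (r == d) r = d - 1;
    int i = adm[r];
    std::swap(seq[i], seq[i + 1]);
    pos[seq[i]] = i;
    pos[seq[i + 1]] = i + 1;
  }
  IntegerVector out_seq(n);
  for (int i = 0; i < n; ++i) out_seq[i] = seq[i] + 1;
  return List::create(_["num"] = num, _["den"] = den, _["seq"] = out_seq);
}
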