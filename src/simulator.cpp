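// Structured-coalescent simulation on a species-branch graph with
// unidirectional admixture (gene-flow) events, emitting polarized allelic
// site patterns. Time runs backward from the present (0) toward the root;
// within a branch every lineage pair coalesces at rate lambda; at an
// admixture event each lineage in the target branch independently switches
// to the destination branch with probability beta; when a branch ends its
// lineages move to the parent branch. Lineage survival stops at the MRCA of
// the sample; mutations above it are unobservable as polymorphism.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Event {
  double t;
  int type;  // 0 = leaf entry, 1 = branch end, 2 = admixture
  int a;     // leaf index / branch index / admixture index
};

struct Merge {
  double t;
  int mask1, mask2;
};

struct TreeOut {
  double len[32];   // total branch length subtending each leaf-subset mask
  double total;     // sum over proper non-empty masks
  int nmerge;
  Merge merges[7];
};

inline int popcount(int m) {
  int c = 0;
  while (m) { c += m & 1; m >>= 1; }
  return c;
}

// One gene tree under the model; fills per-mask subtending lengths.
void sim_tree(const std::vector<Event>& ev,
              const IntegerVector& branch_parent,
              const IntegerVector& leaf_branch,
              const NumericVector& leaf_time,
              const IntegerVector& admix_target,
              const IntegerVector& admix_dest,
              const NumericVector& admix_beta,
              double lambda, int n_leaves, TreeOut& out) {
  const int full = (1 << n_leaves) - 1;
  int br[8], mask[8];
  double t0[8];
  int nact = 0, nent = 0;
  for (int i = 0; i < 32; ++i) out.len[i] = 0.0;
  out.nmerge = 0;

  double t = 0.0;
  size_t phase = 0;
  for (;;) {
    double T = (phase < ev.size()) ? ev[phase].t : R_PosInf;
    // coalescence within branches until the next demographic event
    while (nact >= 2) {
      double rtot = 0.0;
      for (int i = 0; i < nact; ++i) {
        for (int j = i + 1; j < nact; ++j) {
          if (br[i] == br[j]) rtot += lambda;
        }
      }
      if (rtot <= 0.0) break;
      double dt = R::rexp(1.0) / rtot;
      if (t + dt > T) break;
      t += dt;
      // choose a coalescing pair proportional to within-branch rates
      double u = unif_rand() * rtot, acc = 0.0;
      int ci = -1, cj = -1;
      for (int i = 0; i < nact && ci < 0; ++i) {
        for (int j = i + 1; j < nact; ++j) {
          if (br[i] == br[j]) {
            acc += lambda;
            if (u <= acc) { ci = i; cj = j; break; }
          }
        }
      }
      if (ci < 0) { ci = 0; cj = 1; }  // numeric guard
      out.len[mask[ci]] += t - t0[ci];
      out.len[mask[cj]] += t - t0[cj];
      if (out.nmerge < 7) {
        out.merges[out.nmerge].t = t;
        out.merges[out.nmerge].mask1 = mask[ci];
        out.merges[out.nmerge].mask2 = mask[cj];
        ++out.nmerge;
      }
      mask[ci] |= mask[cj];
      t0[ci] = t;
      br[cj] = br[nact - 1]; mask[cj] = mask[nact - 1]; t0[cj] = t0[nact - 1];
      --nact;
      if (nent == n_leaves && nact == 1) {
        out.total = 0.0;
        for (int m = 1; m < full; ++m) out.total += out.len[m];
        return;
      }
    }
    if (phase >= ev.size()) break;  // exhausted (cannot happen with >1 leaf)
    t = ev[phase].t;
    const Event& e = ev[phase];
    if (e.type == 0) {
      br[nact] = leaf_branch[e.a];
      mask[nact] = 1 << e.a;
      t0[nact] = leaf_time[e.a];
      ++nact; ++nent;
    } else if (e.type == 1) {
      int p = branch_parent[e.a];
      for (int i = 0; i < nact; ++i) if (br[i] == e.a) br[i] = p;
    } else {
      double beta = admix_beta[e.a];
      if (beta > 0.0) {
        for (int i = 0; i < nact; ++i) {
          if (br[i] == admix_target[e.a] && unif_rand() < beta) {
            br[i] = admix_dest[e.a];
          }
        }
      }
    }
    ++phase;
  }
  out.total = 0.0;
  for (int m = 1; m < full; ++m) out.total += out.len[m];
}

std::vector<Event> build_events(const NumericVector& branch_end,
                                const NumericVector& leaf_time,
                                const NumericVector& admix_time) {
  std::vector<Event> ev;
  for (int i = 0; i < leaf_time.size(); ++i)
    ev.push_back(Event{leaf_time[i], 0, i});
  for (int b = 0; b < branch_end.size(); ++b)
    if (R_finite(branch_end[b])) ev.push_back(Event{branch_end[b], 1, b});
  for (int e = 0; e < admix_time.size(); ++e)
    ev.push_back(Event{admix_time[e], 2, e});
  std::stable_sort(ev.begin(), ev.end(),
                   [](const Event& a, const Event& b) {
                     if (a.t != b.t) return a.t < b.t;
                     return a.type < b.type;  // leaf entries before moves
                   });
  return ev;
}

}  // namespace

// Simulate i.i.d. polarized patterns: each pattern comes from an
// independent gene tree, chosen with probability proportional to its total
// observable branch length (rejection against the fixed cap), with the
// mutation placed uniformly along the tree. This is the exact
// vanishing-mutation-intensity limit of Poisson mutation dropping
// conditioned on the number of patterns. Returns counts over the 15
// pattern classes (5-leaf models only).
// [[Rcpp::export]]
NumericVector sim_pattern_counts_cpp(NumericVector branch_end,
                                     IntegerVector branch_parent,
                                     IntegerVector leaf_branch,
                                     NumericVector leaf_time,
                                     NumericVector admix_time,
                                     IntegerVector admix_target,
                                     IntegerVector admix_dest,
                                     NumericVector admix_beta,
                                     double lambda, int n_patterns,
                                     double cap) {
  if (leaf_time.size() != 5) stop("pattern simulation needs 5 leaves");
  // mask -> pattern index in canonical order (minority rule)
  int idx[32];
  for (int i = 0; i < 32; ++i) idx[i] = -1;
  const int masks[15] = {1, 2, 4, 8, 16, 3, 5, 9, 17, 6, 10, 18, 12, 20, 24};
  for (int k = 0; k < 15; ++k) idx[masks[k]] = k;

  std::vector<Event> ev = build_events(branch_end, leaf_time, admix_time);
  NumericVector counts(15);
  TreeOut out;
  int got = 0;
  long trees = 0;
  while (got < n_patterns) {
    if ((++trees & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    sim_tree(ev, branch_parent, leaf_branch, leaf_time, admix_target,
             admix_dest, admix_beta, lambda, 5, out);
    double u = unif_rand() * cap;
    if (u >= out.total) continue;  // reject; heavy trees always accepted
    double x = unif_rand() * out.total, acc = 0.0;
    int chosen = -1;
    for (int m = 1; m < 31; ++m) {
      acc += out.len[m];
      if (x <= acc) { chosen = m; break; }
    }
    if (chosen < 0) chosen = 30;
    int mm = (popcount(chosen) > 2) ? (~chosen & 31) : chosen;
    counts[idx[mm]] += 1.0;
    ++got;
  }
  return counts;
}

// One gene tree: merge sequence plus per-leaf-subset subtending lengths.
// [[Rcpp::export]]
List sim_gene_tree_cpp(NumericVector branch_end, IntegerVector branch_parent,
                       IntegerVector leaf_branch, NumericVector leaf_time,
                       NumericVector admix_time, IntegerVector admix_target,
                       IntegerVector admix_dest, NumericVector admix_beta,
                       double lambda) {
  int n_leaves = leaf_time.size();
  if (n_leaves < 2 || n_leaves > 5) stop("2 to 5 leaves supported");
  std::vector<Event> ev = build_events(branch_end, leaf_time, admix_time);
  TreeOut out;
  sim_tree(ev, branch_parent, leaf_branch, leaf_time, admix_target,
           admix_dest, admix_beta, lambda, n_leaves, out);
  NumericMatrix merges(out.nmerge, 3);
  for (int i = 0; i < out.nmerge; ++i) {
    merges(i, 0) = out.merges[i].t;
    merges(i, 1) = out.merges[i].mask1;
    merges(i, 2) = out.merges[i].mask2;
  }
  colnames(merges) = CharacterVector::create("time", "mask1", "mask2");
  int full = (1 << n_leaves) - 1;
  NumericVector lens(full - 1);
  CharacterVector nm(full - 1);
  for (int m = 1; m < full; ++m) {
    lens[m - 1] = out.len[m];
    std::string lab;
    for (int i = 0; i < n_leaves; ++i)
      if (m & (1 << i)) lab += std::to_string(i + 1);
    nm[m - 1] = lab;
  }
  lens.names() = nm;
  return List::create(_["merges"] = merges, _["lengths"] = lens,
                      _["total_length"] = out.total);
}
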