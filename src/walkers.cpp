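#include <Rcpp.h>
using namespace Rcpp;

// Step-level simulation of maze-confined random walkers on the heap-indexed
// binary tree (root 0, children 2i+1/2i+2, leaves are the last 2^L ids).
//
// unbiased: uniform over the available neighbours at every node.
// four-bias: arriving via the stem (from the parent), move forward with
// probability psf, else reverse; given forward, take the alternating turn
// with probability psa. Arriving along the bar (from a child), move forward
// with probability pbf, else reverse; given forward, branch into the stem
// with probability pbs, else continue straight into the other child. End
// nodes force reversal. The root has no stem corridor for a confined
// walker, so the stem-branch probability mass is renormalised onto the two
// remaining options.
// geometric left/right label of the branch junction j -> child c: the
// H-tree corridor axes alternate with depth, so the label combines the
// heap parities of j and c with an alternating handedness factor (the
// entrance corridor fixes the convention at the root); -1 = left branch
static inline int edge_gsign(int j, int c, int lev_j) {
  int sc = (c % 2 == 1) ? -1 : 1;
  int sj = (j == 0) ? 1 : ((j % 2 == 1) ? -1 : 1);
  int sig = (lev_j % 2 == 0) ? -1 : 1;
  return sc * sj * sig;
}

static inline int level_of(int i) {
  int lev = 0;
  while (i + 1 >= (2 << lev)) lev++;
  return lev;
}

// [[Rcpp::export]]
IntegerVector walk_sim_cpp(int n_steps, int n_levels, int start,
                           double psf, double psa, double pbf, double pbs,
                           bool unbiased) {
  const int first_leaf = (1 << n_levels) - 1;
  const int n_nodes = (1 << (n_levels + 1)) - 1;
  if (start < 0 || start >= n_nodes) stop("invalid start node");
  IntegerVector out(n_steps + 1);
  int cur = start, prev = -1;
  out[0] = cur;
  for (int s = 1; s <= n_steps; s++) {
    int nxt;
    if (cur >= first_leaf) {                 // end node: forced reversal
      nxt = (cur - 1) / 2;
    } else if (unbiased) {
      int nb[3]; int k = 0;
      if (cur > 0) nb[k++] = (cur - 1) / 2;
      nb[k++] = 2 * cur + 1;
      nb[k++] = 2 * cur + 2;
      nxt = nb[(int)(unif_rand() * k) % k];
    } else {
      int left = 2 * cur + 1, right = 2 * cur + 2;
      int parent = (cur > 0) ? (cur - 1) / 2 : -1;
      if (prev < 0) {                        // no incoming action yet
        int nb[3]; int k = 0;
        if (parent >= 0) nb[k++] = parent;
        nb[k++] = left; nb[k++] = right;
        nxt = nb[(int)(unif_rand() * k) % k];
      } else if (prev == parent) {           // arrived via stem
        if (unif_rand() < psf) {
          int lev = level_of(cur);
          int g_in = edge_gsign(parent, cur, lev - 1);
          bool alternate = (unif_rand() < psa);
          int g_out = alternate ? -g_in : g_in;
          nxt = (edge_gsign(cur, left, lev) == g_out) ? left : right;
        } else {
          nxt = parent;
        }
      } else {                               // arrived along the bar
        int other = (prev == left) ? right : left;
        if (parent < 0) {                    // root: no stem available
          double p_rev = (1.0 - pbf) / (1.0 - pbf * pbs);
          nxt = (unif_rand() < p_rev) ? prev : other;
        } else if (unif_rand() < pbf) {
          nxt = (unif_rand() < pbs) ? parent : other;
        } else {
          nxt = prev;
        }
      }
    }
    prev = cur; cur = nxt;
    out[s] = cur;
  }
  return out;
}
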