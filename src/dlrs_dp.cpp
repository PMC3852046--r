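// Core dynamic program for the gene tree generation probability under the
// duplication-loss + relaxed clock model, over a discretized species tree.
//
// Only the "diagonal" table d[y][u] = s(y, y, u) (probability that a single
// lineage starting at y generates the planted gene subtree at u with the
// event of u at y) is stored. Off-diagonal entries factor through the
// precomputed chain matrix C:
//
//   s(x, y, u) = C[x][y] * rho_len(l_u, t(x) - t(y)) * s(y, y, u),
//
// where C[x][y] is the product of per-segment one-to-one survival factors
// (p11 times the sibling-extinction factor at passed speciation vertices)
// along the S' path from x down to y, and rho_len is the edge-length
// density implied by the iid Gamma rate model (Gamma density of l/t with
// the 1/t change-of-variables factor). Diagonal entries:
//
//   leaf u:        d[sigma(u)][u] = 1
//   speciation y:  d[y][u] = A(v, y) * A(w, y)        (only at y = sigma(u))
//   interior y:    d[y][u] = 2 * lambda * slice(y) * A(v, y) * A(w, y)
//
// with A(v, y) = sum_{y' proper descendant of y} s(y, y', v); sums become
// maxima (with recorded argmax backpointers) for the MAP variant. An
// optional 0/1 mask on the diagonal restricts event placements per gene
// vertex, which yields the probability of a fixed reconciliation.
//
// Each gene-vertex column is rescaled to max 1 with the log scale
// accumulated, so the computation is underflow-safe.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rho_len(double l, double t, double shape, double scale) {
  if (t <= 0.0) return 0.0;
  return R::dgamma(l / t, shape, scale, 0) / t;
}

// [[Rcpp::export]]
List dlrs_dp_cpp(int n, IntegerVector sp_parent, NumericVector sp_time,
                 IntegerVector n_child, IntegerVector is_species,
                 IntegerVector s_post, IntegerVector desc_ptr,
                 IntegerVector desc_idx, NumericVector dupfac,
                 NumericMatrix C, int sp_root,
                 int m, IntegerVector g_parent, IntegerVector g_child1,
                 IntegerVector g_child2, IntegerVector g_post,
                 IntegerVector sigma, NumericVector glen,
                 double shape, double gam_rate,
                 bool use_max, Nullable<IntegerMatrix> mask_) {
  NumericMatrix diag(n, m);
  NumericVector cumlog(m);
  IntegerMatrix bp1, bp2;
  if (use_max) { bp1 = IntegerMatrix(n, m); bp2 = IntegerMatrix(n, m);
                 std::fill(bp1.begin(), bp1.end(), -1);
                 std::fill(bp2.begin(), bp2.end(), -1); }
  bool has_mask = mask_.isNotNull();
  IntegerMatrix mask;
  if (has_mask) mask = IntegerMatrix(mask_);
  double scale = 1.0 / gam_rate;
  // identify the gene root: the child of the planted root
  int g_root = -1;
  for (int u = 0; u < m; ++u)
    if (g_parent[u] >= 0 && g_parent[g_parent[u]] < 0) { g_root = u; break; }
  if (g_root < 0) stop("gene tree has no root below its planted root");

  for (int gi = 0; gi < m; ++gi) {
    int u = g_post[gi];
    if (g_parent[u] < 0) continue;               // planted root: no event
    int v = g_child1[u], w = g_child2[u];
    if (v < 0) {                                 // gene leaf
      int y = sigma[u];
      double val = 1.0;
      if (has_mask && mask(y, u) == 0) val = 0.0;
      diag(y, u) = val;
      cumlog[u] = 0.0;
      continue;
    }
    double best = 0.0;
    for (int si = 0; si < n; ++si) {
      int y = s_post[si];
      bool spv = is_species[y] != 0;
      if (spv && (sigma[u] != y || n_child[y] != 2)) continue;
      if (!spv && dupfac[y] <= 0.0) continue;
      if (has_mask && mask(y, u) == 0) continue;
      double ty = sp_time[y];
      double A[2]; int arg[2];
      int kids[2] = {v, w};
      bool zero = false;
      for (int c = 0; c < 2 && !zero; ++c) {
        int g = kids[c];
        double acc = 0.0; int am = -1;
        for (int di = desc_ptr[y]; di < desc_ptr[y + 1]; ++di) {
          int yp = desc_idx[di];
          double dv = diag(yp, g);
          if (dv <= 0.0) continue;
          double term = C(y, yp) * rho_len(glen[g], ty - sp_time[yp],
                                           shape, scale) * dv;
          if (use_max) { if (term > acc) { acc = term; am = yp; } }
          else acc += term;
        }
        if (acc <= 0.0) zero = true;
        A[c] = acc; arg[c] = am;
      }
      if (zero) continue;
      double val = A[0] * A[1];
      if (!spv) val *= dupfac[y];
      diag(y, u) = val;
      if (use_max) { bp1(y, u) = arg[0]; bp2(y, u) = arg[1]; }
      if (val > best) best = val;
    }
    // rescale the column so downstream products stay in range
    double own = 0.0;
    if (best > 0.0) {
      for (int y = 0; y < n; ++y) if (diag(y, u) > 0.0) diag(y, u) /= best;
      own = std::log(best);
    }
    cumlog[u] = own + cumlog[v] + cumlog[w];
  }

  // close at the planted root of S: the gene root's event is somewhere
  // strictly below it
  NumericVector rootw(n);
  double tot = 0.0, mx = 0.0; int argroot = -1;
  double tp = sp_time[sp_root];
  for (int di = desc_ptr[sp_root]; di < desc_ptr[sp_root + 1]; ++di) {
    int y = desc_idx[di];
    double dv = diag(y, g_root);
    if (dv <= 0.0) continue;
    double wgt = C(sp_root, y) * rho_len(glen[g_root], tp - sp_time[y],
                                         shape, scale) * dv;
    rootw[y] = wgt;
    tot += wgt;
    if (wgt > mx) { mx = wgt; argroot = y; }
  }
  double loggen = (use_max ? (mx > 0.0 ? std::log(mx) : R_NegInf)
                           : (tot > 0.0 ? std::log(tot) : R_NegInf));
  if (loggen != R_NegInf) loggen += cumlog[g_root];

  List out = List::create(_["diag"] = diag, _["cumlog"] = cumlog,
                          _["rootw"] = rootw, _["loggen"] = loggen,
                          _["g_root"] = g_root, _["root_argmax"] = argroot);
  if (use_max) { out["bp1"] = bp1; out["bp2"] = bp2; }
  return out;
}
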