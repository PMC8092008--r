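// Pillar-HMM likelihood core.
//
// Hidden state of the chain along pillars: one track->subgenome
// permutation per genome, 6^G combined states.  Emission of a pillar
// given a combined state: Felsenstein pruning of the 7-state loss chain
// over the species tree, with one-hot tip vectors determined by the
// pillar's presence pattern mapped through the genome's permutation.
//
// The transition kernel between adjacent pillars factorises over genomes:
// each genome's permutation persists with probability 1 - theta_g and is
// redrawn uniformly over all six permutations otherwise (theta_g = 1 at
// an annotated synteny break).  All kernels are symmetric, so the same
// contraction serves the forward and backward passes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NS = 7; // copy-number states

// ---------------------------------------------------------------------
// helpers

struct TreeView {
  int nnode, G, root;
  const int *child1, *child2, *tipGenome, *postorder;
  std::vector<const double *> P; // per node, 7x7 column-major
};

static TreeView make_tree(const IntegerVector &child1,
                          const IntegerVector &child2,
                          const IntegerVector &tipGenome,
                          const IntegerVector &postorder, int root,
                          const List &Pmats, int G) {
  TreeView tv;
  tv.nnode = child1.size();
  tv.G = G;
  tv.root = root;
  tv.child1 = child1.begin();
  tv.child2 = child2.begin();
  tv.tipGenome = tipGenome.begin();
  tv.postorder = postorder.begin();
  tv.P.resize(tv.nnode);
  for (int i = 0; i < tv.nnode; ++i) {
    NumericMatrix m = Pmats[i];
    tv.P[i] = m.begin();
  }
  return tv;
}

// y = P^T-free product: out[x] = sum_y P(x,y) v[y]; P column-major (R)
static inline void matvec(const double *P, const double *v, double *out) {
  for (int x = 0; x < NS; ++x) out[x] = 0.0;
  for (int y = 0; y < NS; ++y) {
    const double vy = v[y];
    if (vy == 0.0) continue;
    const double *col = P + NS * y;
    for (int x = 0; x < NS; ++x) out[x] += col[x] * vy;
  }
}

// per-genome persistence/redraw kernel applied in place along one axis
static inline void apply_kernel(std::vector<double> &a, int S, int stride,
                                double th) {
  const int block = stride * 6;
  const double keep = 1.0 - th;
  for (int b0 = 0; b0 < S; b0 += block) {
    for (int i = 0; i < stride; ++i) {
      const int base = b0 + i;
      double s = 0.0;
      for (int k = 0; k < 6; ++k) s += a[base + k * stride];
      const double add = th * s / 6.0;
      for (int k = 0; k < 6; ++k) {
        const int idx = base + k * stride;
        a[idx] = keep * a[idx] + add;
      }
    }
  }
}

// ---------------------------------------------------------------------
// emissions for every combined state, one column per unique pattern combo

// [[Rcpp::export]]
NumericMatrix cpp_emissions(IntegerMatrix combos, List Pmats,
                            IntegerVector child1, IntegerVector child2,
                            IntegerVector tipGenome, IntegerVector postorder,
                            int root, IntegerMatrix tipTab,
                            NumericVector prior) {
  const int U = combos.nrow();
  const int G = combos.ncol();
  TreeView tv = make_tree(child1, child2, tipGenome, postorder, root, Pmats, G);

  std::vector<int> pow6(G + 1);
  pow6[0] = 1;
  for (int g = 1; g <= G; ++g) pow6[g] = pow6[g - 1] * 6;
  const int S = pow6[G];

  // per-node "up" tables (message at the top of the node's branch) over
  // the permutation combos of the tips below the node
  std::vector<std::vector<double> > up(tv.nnode);
  std::vector<std::vector<int> > below(tv.nnode); // genome ids, digit order
  std::vector<int> ncomb(tv.nnode);
  for (int k = 0; k < tv.nnode; ++k) {
    int node = tv.postorder[k];
    if (tv.child1[node] < 0) {
      below[node].assign(1, tv.tipGenome[node]);
      ncomb[node] = 6;
    } else {
      const std::vector<int> &b1 = below[tv.child1[node]];
      const std::vector<int> &b2 = below[tv.child2[node]];
      below[node] = b1;
      below[node].insert(below[node].end(), b2.begin(), b2.end());
      ncomb[node] = ncomb[tv.child1[node]] * ncomb[tv.child2[node]];
    }
    up[node].assign((size_t)NS * ncomb[node], 0.0);
  }

  // digit position of each genome in the root table
  const std::vector<int> &rb = below[tv.root];
  std::vector<int> rootpow(G);
  {
    int mult = 1;
    for (int j = 0; j < G; ++j) {
      rootpow[rb[j]] = mult;
      mult *= 6;
    }
  }

  NumericMatrix E(S, U);
  std::vector<double> inb(NS);

  for (int u = 0; u < U; ++u) {
    for (int k = 0; k < tv.nnode; ++k) {
      int node = tv.postorder[k];
      const double *P = tv.P[node];
      if (tv.child1[node] < 0) {
        const int patt = combos(u, tv.tipGenome[node]); // 1..7
        double *T = up[node].data();
        for (int p = 0; p < 6; ++p) {
          const int ts = tipTab(patt - 1, p) - 1; // 0..6
          const double *col = P + NS * ts;
          for (int x = 0; x < NS; ++x) T[NS * p + x] = col[x];
        }
      } else {
        const int c1 = tv.child1[node], c2 = tv.child2[node];
        const int k1 = ncomb[c1], k2 = ncomb[c2];
        double *T = up[node].data();
        const double *U1 = up[c1].data();
        const double *U2 = up[c2].data();
        for (int i2 = 0; i2 < k2; ++i2) {
          const double *v2 = U2 + NS * i2;
          for (int i1 = 0; i1 < k1; ++i1) {
            const double *v1 = U1 + NS * i1;
            for (int x = 0; x < NS; ++x) inb[x] = v1[x] * v2[x];
            matvec(P, inb.data(), T + NS * (i1 + (size_t)k1 * i2));
          }
        }
      }
    }
    // dot with the root prior and remap combo digits to canonical z order
    const double *Ur = up[tv.root].data();
    for (int i = 0; i < S; ++i) {
      double lik = 0.0;
      const double *v = Ur + (size_t)NS * i;
      for (int x = 0; x < NS; ++x) lik += prior[x] * v[x];
      int z = 0, rest = i;
      for (int j = 0; j < G; ++j) {
        const int p = rest % 6;
        rest /= 6;
        z += p * pow6[rb[j]];
      }
      E(z, u) = lik;
    }
  }
  return E;
}

// ---------------------------------------------------------------------
// forward log-likelihood

// [[Rcpp::export]]
double cpp_forward(NumericMatrix E, IntegerVector comboIdx,
                   NumericVector theta, IntegerMatrix breaks) {
  const int S = E.nrow();
  const int n = comboIdx.size();
  const int G = theta.size();
  std::vector<int> pow6(G);
  pow6[0] = 1;
  for (int g = 1; g < G; ++g) pow6[g] = pow6[g - 1] * 6;

  std::vector<double> a(S);
  double loglik = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *e = &E(0, comboIdx[i]);
    if (i == 0) {
      for (int z = 0; z < S; ++z) a[z] = e[z] / S;
    } else {
      for (int g = 0; g < G; ++g) {
        const double th = breaks(i, g) ? 1.0 : theta[g];
        if (th > 0.0) apply_kernel(a, S, pow6[g], th);
      }
      for (int z = 0; z < S; ++z) a[z] *= e[z];
    }
    double sc = 0.0;
    for (int z = 0; z < S; ++z) sc += a[z];
    if (!(sc > 0.0) || !std::isfinite(sc)) return R_NegInf;
    loglik += std::log(sc);
    for (int z = 0; z < S; ++z) a[z] /= sc;
  }
  return loglik;
}

// ---------------------------------------------------------------------
// forward-backward posteriors over combined states, one row per pillar

// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix E, IntegerVector comboIdx,
                          NumericVector theta, IntegerMatrix breaks) {
  const int S = E.nrow();
  const int n = comboIdx.size();
  const int G = theta.size();
  std::vector<int> pow6(G);
  pow6[0] = 1;
  for (int g = 1; g < G; ++g) pow6[g] = pow6[g - 1] * 6;

  NumericMatrix post(n, S);
  std::vector<double> a(S);
  double loglik = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *e = &E(0, comboIdx[i]);
    if (i == 0) {
      for (int z = 0; z < S; ++z) a[z] = e[z] / S;
    } else {
      for (int g = 0; g < G; ++g) {
        const double th = breaks(i, g) ? 1.0 : theta[g];
        if (th > 0.0) apply_kernel(a, S, pow6[g], th);
      }
      for (int z = 0; z < S; ++z) a[z] *= e[z];
    }
    double sc = 0.0;
    for (int z = 0; z < S; ++z) sc += a[z];
    if (!(sc > 0.0) || !std::isfinite(sc)) stop("zero likelihood pillar");
    loglik += std::log(sc);
    for (int z = 0; z < S; ++z) {
      a[z] /= sc;
      post(i, z) = a[z]; // scaled alpha for now
    }
  }

  std::vector<double> b(S, 1.0), tmp(S);
  for (int i = n - 2; i >= 0; --i) {
    const double *e = &E(0, comboIdx[i + 1]);
    for (int z = 0; z < S; ++z) tmp[z] = b[z] * e[z];
    for (int g = 0; g < G; ++g) {
      const double th = breaks(i + 1, g) ? 1.0 : theta[g];
      if (th > 0.0) apply_kernel(tmp, S, pow6[g], th); // kernel symmetric
    }
    double sc = 0.0;
    for (int z = 0; z < S; ++z) sc += tmp[z];
    for (int z = 0; z < S; ++z) b[z] = tmp[z] / sc;
    double tot = 0.0;
    for (int z = 0; z < S; ++z) tot += post(i, z) * b[z];
    for (int z = 0; z < S; ++z) post(i, z) = post(i, z) * b[z] / tot;
  }
  return List::create(_["loglik"] = loglik, _["posterior"] = post);
}

// ---------------------------------------------------------------------
// expected branch-endpoint pair counts
//
// W: aggregated posterior weight per (unique pattern combo, combined
// state), i.e. W(u, z) = sum over pillars with combo u of P(z | data).
// Returns a 49 x nnode matrix; column v holds, column-major over
// (state at top of branch, state at node v), the expected number of
// pillars with that endpoint pair on the branch above v.

// [[Rcpp::export]]
NumericMatrix cpp_endpoint_counts(NumericMatrix W, IntegerMatrix combos,
                                  List Pmats, IntegerVector child1,
                                  IntegerVector child2,
                                  IntegerVector tipGenome,
                                  IntegerVector postorder, int root,
                                  IntegerMatrix tipTab,
                                  NumericVector prior) {
  const int U = combos.nrow();
  const int G = combos.ncol();
  TreeView tv = make_tree(child1, child2, tipGenome, postorder, root, Pmats, G);
  const int nnode = tv.nnode;

  NumericMatrix C(NS * NS, nnode);
  std::vector<std::vector<double> > inb(nnode, std::vector<double>(NS)),
      up(nnode, std::vector<double>(NS)), outt(nnode, std::vector<double>(NS));
  std::vector<int> perm(G), ts(G);

  for (int u = 0; u < U; ++u) {
    for (int z = 0; z < W.ncol(); ++z) {
      const double w = W(u, z);
      if (w < 1e-14) continue;
      int rest = z;
      for (int g = 0; g < G; ++g) {
        perm[g] = rest % 6;
        rest /= 6;
        ts[g] = tipTab(combos(u, g) - 1, perm[g]) - 1;
      }
      // inside
      for (int k = 0; k < nnode; ++k) {
        const int node = tv.postorder[k];
        if (tv.child1[node] < 0) {
          for (int x = 0; x < NS; ++x) inb[node][x] = 0.0;
          inb[node][ts[tv.tipGenome[node]]] = 1.0;
        } else {
          const int c1 = tv.child1[node], c2 = tv.child2[node];
          for (int x = 0; x < NS; ++x)
            inb[node][x] = up[c1][x] * up[c2][x];
        }
        matvec(tv.P[node], inb[node].data(), up[node].data());
      }
      double lik = 0.0;
      for (int x = 0; x < NS; ++x) lik += prior[x] * up[tv.root][x];
      if (!(lik > 1e-300)) continue;
      const double wl = w / lik;
      // outside (preorder) and accumulation
      for (int x = 0; x < NS; ++x) outt[tv.root][x] = prior[x];
      for (int k = nnode - 1; k >= 0; --k) {
        const int node = tv.postorder[k];
        const double *P = tv.P[node];
        double *C_v = &C(0, node);
        for (int a = 0; a < NS; ++a) {
          const double oa = outt[node][a];
          if (oa == 0.0) continue;
          const double *col0 = P + 0;
          for (int x = 0; x < NS; ++x) {
            const double val = oa * P[a + NS * x] * inb[node][x];
            if (val != 0.0) C_v[a + NS * x] += wl * val;
          }
          (void)col0;
        }
        if (tv.child1[node] >= 0) {
          const int c1 = tv.child1[node], c2 = tv.child2[node];
          // out at the bottom of node's branch
          double ob[NS];
          for (int x = 0; x < NS; ++x) {
            double s = 0.0;
            for (int a = 0; a < NS; ++a) s += outt[node][a] * P[a + NS * x];
            ob[x] = s;
          }
          for (int x = 0; x < NS; ++x) {
            outt[c1][x] = ob[x] * up[c2][x];
            outt[c2][x] = ob[x] * up[c1][x];
          }
        }
      }
    }
  }
  return C;
}
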