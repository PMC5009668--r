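#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Two-state symmetric pruning likelihood for the genealogy sampler.
//
// children:  2 x (n_leaf - 1) integer matrix (1-based node ids), column j
//            holds the children of internal node n_leaf + j
// int_order: internal node ids in postorder (children before parents)
// flip:      per-node probability that the binary allele differs from the
//            parent allele across the branch above the node
// patterns:  n_leaf x P matrix of 0/1 leaf alleles (site patterns)
// weights:   pattern multiplicities
// Root prior is stationary (1/2, 1/2).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_pruning_loglik(const IntegerMatrix& children,
                          const IntegerVector& int_order,
                          const NumericVector& flip,
                          const IntegerMatrix& patterns,
                          const NumericVector& weights) {
  const int n_leaf = patterns.nrow();
  const int P = patterns.ncol();
  const int n_nodes = 2 * n_leaf - 1;
  const int root = int_order[int_order.size() - 1];
  std::vector<double> L0(n_nodes), L1(n_nodes);
  double total = 0.0;
  for (int p = 0; p < P; ++p) {
    for (int v = 0; v < n_leaf; ++v) {
      const int a = patterns(v, p);
      L0[v] = (a == 0) ? 1.0 : 0.0;
      L1[v] = (a == 1) ? 1.0 : 0.0;
    }
    double scale_log = 0.0;
    for (int k = 0; k < int_order.size(); ++k) {
      const int v = int_order[k] - 1;           // 0-based id
      const int j = v - n_leaf;                 // internal index
      double prod0 = 1.0, prod1 = 1.0;
      for (int cc = 0; cc < 2; ++cc) {
        const int c = children(cc, j) - 1;
        const double f = flip[c];
        const double m0 = (1.0 - f) * L0[c] + f * L1[c];
        const double m1 = (1.0 - f) * L1[c] + f * L0[c];
        prod0 *= m0;
        prod1 *= m1;
      }
      const double s = prod0 + prod1;
      if (s <= 0.0) return R_NegInf;
      L0[v] = prod0 / s;
      L1[v] = prod1 / s;
      scale_log += std::log(s);
    }
    const double site = 0.5 * (L0[root - 1] + L1[root - 1]);
    total += weights[p] * (scale_log + std::log(site));
  }
  return total;
}

// ---------------------------------------------------------------------------
// Multi-tree belief propagation.
//
// The factor graph couples, for each individual i, a symmetric diploid
// insert-size factor f_i(n_i1, n_i2) with the leaves labelled i_1 / i_2 of
// every genealogy in the ensemble; branches carry the clipped-normal
// stepwise transition potential min{1, N(n_child; n_parent, Ne mu_s t)}.
//
// Message schedule per cycle (fixed, deterministic):
//   1. cross-haplotype messages m_{i1->i2}, m_{i2->i1} for all individuals
//      (from the tree-aggregate of the previous cycle's downward messages)
//   2. per tree, in ensemble order: upward sweep (leaves -> root)
//   3. per tree: downward sweep (root -> leaves)
// All messages are renormalized to sum 1 after every update.
// ---------------------------------------------------------------------------

// The stepwise transition potential min{1, N(n_c; n_p, v)} depends only on
// |n_c - n_p|: the edge matrix is symmetric Toeplitz, so a message update
// is a convolution with the clipped kernel.  Kernel entries below 1e-30 of
// the diagonal are truncated to a bandwidth, which keeps the per-edge work
// O(S * band) instead of O(S^2) on the short branches that dominate large
// ensembles.
struct EdgePotential {
  std::vector<double> kern;   // kern[d] = min(1, N(d; 0, v)), d = 0..band
  int band;
};

static EdgePotential make_potential(double variance, int S) {
  EdgePotential e;
  if (variance <= 0.0) {               // identity (zero-length branch)
    e.kern.assign(1, 1.0);
    e.band = 0;
    return e;
  }
  const double amp = 1.0 / std::sqrt(2.0 * M_PI * variance);
  std::vector<double> full(S);
  for (int d = 0; d < S; ++d) {
    const double v = amp * std::exp(-0.5 * d * d / variance);
    full[d] = v > 1.0 ? 1.0 : v;
  }
  int band = S - 1;
  while (band > 0 && full[band] < 1e-30 * full[0]) --band;
  e.kern.assign(full.begin(), full.begin() + band + 1);
  e.band = band;
  return e;
}

// y[j] = sum_k pot(|j - k|) * x[k]; the potential matrix is symmetric so
// the same convolution serves upward and downward updates
static void matvec_sym(const EdgePotential& e, const std::vector<double>& x,
                       std::vector<double>& y) {
  const int S = (int)x.size();
  for (int j = 0; j < S; ++j) {
    const int lo = j - e.band < 0 ? 0 : j - e.band;
    const int hi = j + e.band >= S ? S - 1 : j + e.band;
    double acc = 0.0;
    for (int k = lo; k < j; ++k) acc += e.kern[j - k] * x[k];
    for (int k = j; k <= hi; ++k) acc += e.kern[k - j] * x[k];
    y[j] = acc;
  }
}

// Renormalize to sum one, then floor entries at 1e-150 so that products of
// point-mass-like messages on near-identity branches never underflow to an
// exact zero vector.  Returns the normalization constant so callers can
// track raw message scales.
static double normalize_or_stop(std::vector<double>& v, const char* what,
                                int cycle, int tree, int node) {
  double s = 0.0;
  bool finite = true;
  for (double x : v) {
    if (!R_finite(x)) { finite = false; break; }
    s += x;
  }
  if (!finite || s <= 0.0) {
    stop("non-finite or all-zero %s message (cycle %d, tree %d, node %d)",
         what, cycle + 1, tree + 1, node + 1);
  }
  for (double& x : v) {
    x /= s;
    if (x < 1e-150) x = 1e-150;
  }
  return s;
}

struct TreeSpec {
  int n_leaf;
  std::vector<int> parent;       // -1 for root
  std::vector<int> child1, child2;  // per internal node (index - n_leaf)
  std::vector<int> postorder;    // all node ids, children before parents
  std::vector<int> leaf_indiv;   // per leaf: 0-based individual
  std::vector<int> leaf_hap;     // per leaf: 0 or 1
  std::vector<EdgePotential> epot;  // per node (branch above the node)
  int root;
};

// [[Rcpp::export]]
List cpp_bp_run(const List& trees_spec, const List& factors, int S,
                int loopy_cycles, int mixed_cycles, bool raw_weights) {
  const int G = trees_spec.size();
  const int I = factors.size();
  const double unif = 1.0 / S;

  std::vector<TreeSpec> trees(G);
  for (int g = 0; g < G; ++g) {
    List ts = trees_spec[g];
    TreeSpec& T = trees[g];
    T.n_leaf = as<int>(ts["n_leaf"]);
    IntegerVector par = ts["parent"], post = ts["postorder"];
    IntegerVector li = ts["leaf_indiv"], lh = ts["leaf_hap"];
    IntegerMatrix ch = ts["children"];
    NumericVector var = ts["variance"];
    const int n_nodes = 2 * T.n_leaf - 1;
    T.parent.resize(n_nodes);
    T.epot.resize(n_nodes);
    for (int v = 0; v < n_nodes; ++v) {
      T.parent[v] = par[v] == NA_INTEGER ? -1 : par[v] - 1;
      if (T.parent[v] >= 0) T.epot[v] = make_potential(var[v], S);
    }
    T.child1.resize(T.n_leaf - 1);
    T.child2.resize(T.n_leaf - 1);
    for (int j = 0; j < T.n_leaf - 1; ++j) {
      T.child1[j] = ch(0, j) - 1;
      T.child2[j] = ch(1, j) - 1;
    }
    T.postorder.assign(post.begin(), post.end());
    for (int& v : T.postorder) --v;
    T.leaf_indiv.assign(li.begin(), li.end());
    T.leaf_hap.assign(lh.begin(), lh.end());
    T.root = T.postorder.back();
  }

  std::vector<NumericMatrix> fct(I);
  for (int i = 0; i < I; ++i) fct[i] = as<NumericMatrix>(factors[i]);

  // messages; *_ls hold the log of the raw (pre-normalization) scale of
  // each message, accumulated along its dependency path, so trees can be
  // weighted by raw message mass in the aggregation when requested
  std::vector<std::vector<std::vector<double>>> up(G), down(G);
  std::vector<std::vector<double>> up_ls(G), down_ls(G);
  for (int g = 0; g < G; ++g) {
    const int n_nodes = 2 * trees[g].n_leaf - 1;
    up[g].assign(n_nodes, std::vector<double>(S, unif));
    down[g].assign(n_nodes, std::vector<double>(S, unif));
    up_ls[g].assign(n_nodes, 0.0);
    down_ls[g].assign(n_nodes, 0.0);
  }
  std::vector<std::vector<double>> m12(I, std::vector<double>(S, unif));
  std::vector<std::vector<double>> m21(I, std::vector<double>(S, unif));
  std::vector<std::vector<double>> T1(I, std::vector<double>(S, unif));
  std::vector<std::vector<double>> T2(I, std::vector<double>(S, unif));

  // Tree-aggregate message to each haplotype.  Normalized mode: per-tree
  // downward messages (each normalized) are summed with equal weight and
  // renormalized.  Raw mode: each tree's message is weighted by its raw
  // scale exp(log-scale - max log-scale), the literal unnormalized sum.
  auto aggregate = [&](int cycle) {
    for (int i = 0; i < I; ++i) {
      std::fill(T1[i].begin(), T1[i].end(), 0.0);
      std::fill(T2[i].begin(), T2[i].end(), 0.0);
    }
    std::vector<double> wmax1, wmax2;
    if (raw_weights) {
      // per haplotype, the max log-scale across trees for stable weights
      wmax1.assign(I, R_NegInf);
      wmax2.assign(I, R_NegInf);
      for (int g = 0; g < G; ++g) {
        const TreeSpec& T = trees[g];
        for (int v = 0; v < T.n_leaf; ++v) {
          double& m = (T.leaf_hap[v] == 0) ? wmax1[T.leaf_indiv[v]]
                                           : wmax2[T.leaf_indiv[v]];
          if (down_ls[g][v] > m) m = down_ls[g][v];
        }
      }
    }
    for (int g = 0; g < G; ++g) {
      const TreeSpec& T = trees[g];
      for (int v = 0; v < T.n_leaf; ++v) {
        const int i = T.leaf_indiv[v];
        std::vector<double>& tgt = (T.leaf_hap[v] == 0) ? T1[i] : T2[i];
        double w = 1.0;
        if (raw_weights) {
          const double m = (T.leaf_hap[v] == 0) ? wmax1[i] : wmax2[i];
          w = std::exp(down_ls[g][v] - m);
        }
        for (int n = 0; n < S; ++n) tgt[n] += w * down[g][v][n];
      }
    }
    for (int i = 0; i < I; ++i) {
      normalize_or_stop(T1[i], "tree-aggregate", cycle, -1, i);
      normalize_or_stop(T2[i], "tree-aggregate", cycle, -1, i);
    }
  };

  std::vector<double> buf(S), inmsg(S);

  auto run_cycles = [&](int n_cycles, bool mixed, int cycle0) {
    for (int cyc = 0; cyc < n_cycles; ++cyc) {
      const int cycle = cycle0 + cyc;
      // 1. cross-haplotype messages from current tree aggregates
      aggregate(cycle);
      for (int i = 0; i < I; ++i) {
        const NumericMatrix& f = fct[i];
        for (int n2 = 0; n2 < S; ++n2) {      // m_{i1 -> i2}
          double acc = 0.0;
          if (mixed) {
            for (int n1 = 0; n1 < S; ++n1) {
              const double v = f(n1, n2) * T1[i][n1];
              if (v > acc) acc = v;
            }
          } else {
            for (int n1 = 0; n1 < S; ++n1) acc += f(n1, n2) * T1[i][n1];
          }
          buf[n2] = acc;
        }
        normalize_or_stop(buf, "cross-haplotype", cycle, -1, i);
        m12[i] = buf;
        for (int n1 = 0; n1 < S; ++n1) {      // m_{i2 -> i1}
          double acc = 0.0;
          if (mixed) {
            for (int n2 = 0; n2 < S; ++n2) {
              const double v = f(n1, n2) * T2[i][n2];
              if (v > acc) acc = v;
            }
          } else {
            for (int n2 = 0; n2 < S; ++n2) acc += f(n1, n2) * T2[i][n2];
          }
          buf[n1] = acc;
        }
        normalize_or_stop(buf, "cross-haplotype", cycle, -1, i);
        m21[i] = buf;
      }
      // 2. upward sweeps
      for (int g = 0; g < G; ++g) {
        const TreeSpec& T = trees[g];
        for (int v : T.postorder) {
          if (v == T.root) continue;
          if (v < T.n_leaf) {
            const int i = T.leaf_indiv[v];
            const std::vector<double>& cross =
                (T.leaf_hap[v] == 0) ? m21[i] : m12[i];
            if (mixed) {
              // restrict to the argmax set of cross(n) * tree-aggregate(n)
              const std::vector<double>& agg =
                  (T.leaf_hap[v] == 0) ? T1[i] : T2[i];
              double best = 0.0;
              for (int n = 0; n < S; ++n) {
                const double b = cross[n] * agg[n];
                if (b > best) best = b;
              }
              for (int n = 0; n < S; ++n) {
                const double b = cross[n] * agg[n];
                inmsg[n] = (b >= best * (1.0 - 1e-12)) ? cross[n] : 0.0;
              }
              matvec_sym(T.epot[v], inmsg, buf);
            } else {
              matvec_sym(T.epot[v], cross, buf);
            }
          } else {
            const int j = v - T.n_leaf;
            const std::vector<double>& u1 = up[g][T.child1[j]];
            const std::vector<double>& u2 = up[g][T.child2[j]];
            for (int n = 0; n < S; ++n) inmsg[n] = u1[n] * u2[n];
            matvec_sym(T.epot[v], inmsg, buf);
          }
          const double z = normalize_or_stop(buf, "upward", cycle, g, v);
          up_ls[g][v] = std::log(z) +
            (v < T.n_leaf ? 0.0
                          : up_ls[g][T.child1[v - T.n_leaf]] +
                            up_ls[g][T.child2[v - T.n_leaf]]);
          up[g][v] = buf;
        }
      }
      // 3. downward sweeps
      for (int g = 0; g < G; ++g) {
        const TreeSpec& T = trees[g];
        for (int k = (int)T.postorder.size() - 1; k >= 0; --k) {
          const int v = T.postorder[k];
          if (v < T.n_leaf) continue;
          const int j = v - T.n_leaf;
          const int c1 = T.child1[j], c2 = T.child2[j];
          const bool is_root = (v == T.root);
          for (int pass = 0; pass < 2; ++pass) {
            const int tgt = pass == 0 ? c1 : c2;
            const int sib = pass == 0 ? c2 : c1;
            for (int n = 0; n < S; ++n) {
              inmsg[n] = (is_root ? 1.0 : down[g][v][n]) * up[g][sib][n];
            }
            matvec_sym(T.epot[tgt], inmsg, buf);
            const double z = normalize_or_stop(buf, "downward", cycle, g, tgt);
            down_ls[g][tgt] = std::log(z) + up_ls[g][sib] +
              (is_root ? 0.0 : down_ls[g][v]);
            down[g][tgt] = buf;
          }
        }
      }
    }
  };

  run_cycles(loopy_cycles, false, 0);
  run_cycles(mixed_cycles, true, loopy_cycles);
  aggregate(loopy_cycles + mixed_cycles);   // final tree aggregates for decoding

  NumericMatrix M12(S, I), M21(S, I), A1(S, I), A2(S, I);
  for (int i = 0; i < I; ++i) {
    for (int n = 0; n < S; ++n) {
      M12(n, i) = m12[i][n];
      M21(n, i) = m21[i][n];
      A1(n, i) = T1[i][n];
      A2(n, i) = T2[i][n];
    }
  }
  return List::create(_["m12"] = M12, _["m21"] = M21,
                      _["agg1"] = A1, _["agg2"] = A2);
}
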