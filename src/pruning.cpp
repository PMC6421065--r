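// Felsenstein pruning log-likelihood for a fixed GTR+discrete-Gamma model,
// with analytic gradients with respect to branch lengths.
//
// The transition matrix uses the eigendecomposition of the symmetrized
// reversible rate matrix, supplied from R as P(t) = C1 diag(exp(vals t)) C2,
// so dP/dt = C1 diag(vals exp(vals t)) C2. Gradients use the standard
// two-pass scheme: downward (tipward) partials D from the postorder pass and
// upper partials U from a preorder pass, with per-pattern log scalers
// tracked on both sides so the two passes can be combined exactly even when
// numerical rescaling fires.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void pmat(const double* C1, const double* C2, const double* vals,
                        double t, double* P, bool deriv) {
  // column-major 4x4; P = C1 diag(f(vals t)) C2
  double ev[4];
  for (int k = 0; k < 4; ++k) {
    double e = std::exp(vals[k] * t);
    ev[k] = deriv ? vals[k] * e : e;
  }
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += C1[i + 4 * k] * ev[k] * C2[k + 4 * j];
      P[i + 4 * j] = s;
    }
}

// [[Rcpp::export]]
List pruning_loglik_cpp(IntegerMatrix edge, NumericVector blen, int ntip,
                        IntegerMatrix tipstates, NumericVector pat_weight,
                        NumericVector pi, NumericMatrix C1m, NumericMatrix C2m,
                        NumericVector vals, NumericVector crates,
                        NumericVector cweights, bool want_grad) {
  const int E = edge.nrow();
  const int npat = tipstates.ncol();
  const int K = crates.size();
  int nnode = ntip;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  const int root = edge(E - 1, 0);  // postorder: last edge's parent is the root
  const double* C1 = C1m.begin();
  const double* C2 = C2m.begin();
  const double SCALE_THRESH = 1e-140;

  // per-node child-edge lists and parent-edge index
  std::vector<std::vector<int>> child_edges(nnode + 1);
  std::vector<int> parent_edge(nnode + 1, -1);
  for (int e = 0; e < E; ++e) {
    child_edges[edge(e, 0)].push_back(e);
    parent_edge[edge(e, 1)] = e;
  }

  // storage per category: D for internal nodes, M per edge, sc per node
  // D[c] indexed [(node-1)*4 + i]*npat + p (tips never stored).
  // Buffers are reused across calls: optimizers evaluate this kernel
  // thousands of times and per-call allocation dominates otherwise.
  static std::vector<std::vector<double>> Dc, Mc, scc, llmat;
  if ((int)Dc.size() < K) { Dc.resize(K); Mc.resize(K); scc.resize(K); llmat.resize(K); }
  for (int c = 0; c < K; ++c) {
    Dc[c].assign((size_t)nnode * 4 * npat, 1.0);
    Mc[c].assign((size_t)E * 4 * npat, 0.0);
    scc[c].assign((size_t)(nnode + 1) * npat, 0.0);
    llmat[c].assign(npat, 0.0);
  }

  double P[16];
  for (int c = 0; c < K; ++c) {
    std::vector<double>& D = Dc[c];
    std::vector<double>& M = Mc[c];
    std::vector<double>& sc = scc[c];
    const double rc = crates[c];
    for (int e = 0; e < E; ++e) {
      const int u = edge(e, 0), v = edge(e, 1);
      pmat(C1, C2, vals.begin(), blen[e] * rc, P, false);
      double* Me = &M[(size_t)e * 4 * npat];
      double* Du = &D[(size_t)(u - 1) * 4 * npat];
      if (v <= ntip) {
        for (int p = 0; p < npat; ++p) {
          const int s = tipstates(v - 1, p);
          for (int i = 0; i < 4; ++i) Me[i * npat + p] = P[i + 4 * s];
        }
      } else {
        double* Dv = &D[(size_t)(v - 1) * 4 * npat];
        // finalize v: rescale small partials, fold child scalers forward
        for (int p = 0; p < npat; ++p) {
          double mx = 0.0;
          for (int i = 0; i < 4; ++i)
            if (Dv[i * npat + p] > mx) mx = Dv[i * npat + p];
          if (mx < SCALE_THRESH && mx > 0.0) {
            for (int i = 0; i < 4; ++i) Dv[i * npat + p] /= mx;
            sc[(size_t)v * npat + p] += std::log(mx);
          }
        }
        for (int p = 0; p < npat; ++p)
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j)
              s += P[i + 4 * j] * Dv[j * npat + p];
            Me[i * npat + p] = s;
          }
      }
      for (int p = 0; p < npat; ++p)
        for (int i = 0; i < 4; ++i) Du[i * npat + p] *= Me[i * npat + p];
      double* scu = &sc[(size_t)u * npat];
      const double* scv = &sc[(size_t)v * npat];
      for (int p = 0; p < npat; ++p) scu[p] += scv[p];
    }
    const double* Droot = &D[(size_t)(root - 1) * 4 * npat];
    const double* scroot = &sc[(size_t)root * npat];
    for (int p = 0; p < npat; ++p) {
      double s = 0.0;
      for (int i = 0; i < 4; ++i) s += pi[i] * Droot[i * npat + p];
      llmat[c][p] = std::log(s) + scroot[p];
    }
  }

  // combine categories per pattern (log-sum-exp)
  std::vector<double> mx(npat, -1e308), denom(npat, 0.0);
  double loglik = 0.0;
  for (int p = 0; p < npat; ++p) {
    for (int c = 0; c < K; ++c)
      if (llmat[c][p] > mx[p]) mx[p] = llmat[c][p];
    for (int c = 0; c < K; ++c)
      denom[p] += cweights[c] * std::exp(llmat[c][p] - mx[p]);
    loglik += pat_weight[p] * (std::log(denom[p]) + mx[p]);
  }

  if (!want_grad)
    return List::create(Named("loglik") = loglik);

  NumericVector grad(E);
  double QP[16];
  // preorder pass per category: upper partials U per node, scalers per edge
  for (int c = 0; c < K; ++c) {
    const std::vector<double>& D = Dc[c];
    const std::vector<double>& M = Mc[c];
    const std::vector<double>& sc = scc[c];
    const double rc = crates[c];
    static std::vector<double> U, usc;
    U.assign((size_t)nnode * 4 * npat, 0.0);
    usc.assign((size_t)(nnode + 1) * npat, 0.0);
    double* Ur = &U[(size_t)(root - 1) * 4 * npat];
    for (int p = 0; p < npat; ++p)
      for (int i = 0; i < 4; ++i) Ur[i * npat + p] = pi[i];
    static std::vector<double> Up, G;
    Up.assign(4 * (size_t)npat, 0.0);
    G.assign(npat, 0.0);

    for (int e = E - 1; e >= 0; --e) {  // reverse postorder = preorder
      const int u = edge(e, 0), v = edge(e, 1);
      const double* Uu = &U[(size_t)(u - 1) * 4 * npat];
      // Up = U_u * product of sibling-edge M's; fold sibling scalers
      std::fill(Up.begin(), Up.end(), 0.0);
      for (int p = 0; p < npat; ++p)
        for (int i = 0; i < 4; ++i) Up[i * npat + p] = Uu[i * npat + p];
      double* usce = &usc[(size_t)v * npat];  // keyed by child node
      const double* uscu = &usc[(size_t)u * npat];
      for (int p = 0; p < npat; ++p) usce[p] = uscu[p];
      for (size_t k = 0; k < child_edges[u].size(); ++k) {
        const int w = child_edges[u][k];
        if (w == e) continue;
        const double* Mw = &M[(size_t)w * 4 * npat];
        const int wv = edge(w, 1);
        const double* scw = &sc[(size_t)wv * npat];
        for (int p = 0; p < npat; ++p) {
          for (int i = 0; i < 4; ++i) Up[i * npat + p] *= Mw[i * npat + p];
          }
        for (int p = 0; p < npat; ++p) usce[p] += scw[p];
      }
      // gradient contribution: sum_ij Up_i (dP/db)_ij D_vj
      pmat(C1, C2, vals.begin(), blen[e] * rc, QP, true);
      if (v <= ntip) {
        for (int p = 0; p < npat; ++p) {
          const int s = tipstates(v - 1, p);
          double g = 0.0;
          for (int i = 0; i < 4; ++i) g += Up[i * npat + p] * QP[i + 4 * s];
          G[p] = g;
        }
      } else {
        const double* Dv = &D[(size_t)(v - 1) * 4 * npat];
        for (int p = 0; p < npat; ++p) {
          double g = 0.0;
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j)
              s += QP[i + 4 * j] * Dv[j * npat + p];
            g += Up[i * npat + p] * s;
          }
          G[p] = g;
        }
      }
      const double* scv = &sc[(size_t)v * npat];
      double gsum = 0.0;
      for (int p = 0; p < npat; ++p) {
        const double scale = std::exp(usce[p] + scv[p] - mx[p]);
        gsum += pat_weight[p] * cweights[c] * rc * G[p] * scale / denom[p];
      }
      grad[e] += gsum;
      // push U down to v if v is internal
      if (v > ntip) {
        double* Uv = &U[(size_t)(v - 1) * 4 * npat];
        pmat(C1, C2, vals.begin(), blen[e] * rc, P, false);
        for (int p = 0; p < npat; ++p)
          for (int j = 0; j < 4; ++j) {
            double s = 0.0;
            for (int i = 0; i < 4; ++i)
              s += Up[i * npat + p] * P[i + 4 * j];
            Uv[j * npat + p] = s;
          }
      }
    }
  }
  return List::create(Named("loglik") = loglik, Named("gradient") = grad);
}
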