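#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning log-likelihood for a phylo tree.
//
// edge: phylo edge matrix in postorder (1-based node ids, tips 1..ntip).
// tipStates: ntip x npat integer matrix, 0..3 for A,C,G,T and -1 for
//   missing (gap or ambiguity -> partial likelihood of ones).
// weights: pattern weights (column counts).
// V, Vinv, lambda: eigendecomposition of the normalized GTR rate matrix,
//   Q = V diag(lambda) Vinv.
// rates: per-category relative rates (mean 1); categories are weighted
//   equally and site likelihoods are averaged over them.
//
// Internal-node partials are rescaled per pattern before being folded into
// their parent; category likelihoods are combined on the log scale.
// [[Rcpp::export(name = ".pruneLoglik")]]
double pruneLoglik(IntegerMatrix edge, int ntip, int nnode,
                   IntegerMatrix tipStates, NumericVector weights,
                   NumericVector edgeLen, NumericVector rates,
                   NumericMatrix V, NumericMatrix Vinv,
                   NumericVector lambda, NumericVector freqs) {
  const int nedge = edge.nrow();
  const int npat = tipStates.ncol();
  const int ncat = rates.size();
  const int root = ntip + 1;           // ape convention
  const int ntotal = ntip + nnode;

  std::vector<double> siteLogCat(static_cast<size_t>(ncat) * npat);
  std::vector<double> partial(static_cast<size_t>(ntotal) * 4 * npat);
  std::vector<double> scale(static_cast<size_t>(ntotal) * npat);
  std::vector<char> seen(ntotal);
  double P[4][4];

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);

    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;   // 0-based
      const int chd = edge(e, 1) - 1;
      const double t = edgeLen[e] * rates[c];

      // P(t) = V diag(exp(lambda t)) Vinv
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(lambda[k] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += V(i, k) * ex[k] * Vinv(k, j);
          P[i][j] = s > 0.0 ? s : 0.0;
        }

      double *pp = &partial[static_cast<size_t>(par) * 4 * npat];
      double *ps = &scale[static_cast<size_t>(par) * npat];
      if (!seen[par]) {
        std::fill(pp, pp + 4 * npat, 1.0);
        std::fill(ps, ps + npat, 0.0);
        seen[par] = 1;
      }

      if (chd < ntip) {
        for (int s = 0; s < npat; ++s) {
          const int st = tipStates(chd, s);
          if (st < 0) continue;          // missing: multiply by 1
          for (int i = 0; i < 4; ++i) pp[i * npat + s] *= P[i][st];
        }
      } else {
        double *cp = &partial[static_cast<size_t>(chd) * 4 * npat];
        const double *cs = &scale[static_cast<size_t>(chd) * npat];
        for (int s = 0; s < npat; ++s) {
          // rescale the completed child partial for this pattern
          double m = cp[s];
          for (int i = 1; i < 4; ++i)
            m = std::max(m, cp[i * npat + s]);
          double logm = 0.0;
          if (m > 0.0 && (m < 1e-120 || m > 1e120)) {
            for (int i = 0; i < 4; ++i) cp[i * npat + s] /= m;
            logm = std::log(m);
          }
          double v0 = cp[s], v1 = cp[npat + s], v2 = cp[2 * npat + s],
                 v3 = cp[3 * npat + s];
          for (int i = 0; i < 4; ++i)
            pp[i * npat + s] *=
              P[i][0] * v0 + P[i][1] * v1 + P[i][2] * v2 + P[i][3] * v3;
          ps[s] += cs[s] + logm;
        }
      }
    }

    const double *rp = &partial[static_cast<size_t>(root - 1) * 4 * npat];
    const double *rs = &scale[static_cast<size_t>(root - 1) * npat];
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) lik += freqs[i] * rp[i * npat + s];
      if (lik <= 0.0) lik = 1e-300;
      siteLogCat[static_cast<size_t>(c) * npat + s] = std::log(lik) + rs[s];
    }
  }

  // combine categories (equal weights) by log-sum-exp, then sum over sites
  const double logInvCat = -std::log(static_cast<double>(ncat));
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    double m = siteLogCat[s];
    for (int c = 1; c < ncat; ++c)
      m = std::max(m, siteLogCat[static_cast<size_t>(c) * npat + s]);
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(siteLogCat[static_cast<size_t>(c) * npat + s] - m);
    total += weights[s] * (m + std::log(acc) + logInvCat);
  }
  return total;
}

static double logliKernel(const IntegerMatrix &edge, int ntip, int nnode,
                          const IntegerMatrix &tipStates,
                          const NumericVector &weights,
                          const std::vector<double> &edgeLen,
                          const NumericVector &rates, const NumericMatrix &V,
                          const NumericMatrix &Vinv,
                          const NumericVector &lambda,
                          const NumericVector &freqs) {
  NumericVector el(edgeLen.begin(), edgeLen.end());
  return pruneLoglik(edge, ntip, nnode, tipStates, weights, el, rates, V,
                     Vinv, lambda, freqs);
}

// Coordinate-wise branch-length optimization: golden-section search on each
// edge in turn, cycling until the log-likelihood improves by < tol over a
// full cycle. Returns the optimized lengths and final log-likelihood.
// [[Rcpp::export(name = ".optimizeEdgesC")]]
List optimizeEdges(IntegerMatrix edge, int ntip, int nnode,
                   IntegerMatrix tipStates, NumericVector weights,
                   NumericVector edgeLen, NumericVector rates,
                   NumericMatrix V, NumericMatrix Vinv, NumericVector lambda,
                   NumericVector freqs, double tol, int maxCycles,
                   double maxEdge) {
  const int ne = edge.nrow();
  std::vector<double> el(edgeLen.begin(), edgeLen.end());
  for (int e = 0; e < ne; ++e) if (el[e] <= 0) el[e] = 1e-8;
  auto f = [&](void) {
    return logliKernel(edge, ntip, nnode, tipStates, weights, el, rates, V,
                       Vinv, lambda, freqs);
  };
  double ll = f();
  const double gr = 0.6180339887498949;
  double llprev = ll;
  for (int cycle = 0; cycle < maxCycles; ++cycle) {
    for (int e = 0; e < ne; ++e) {
      const double old = el[e];
      double a = 1e-9, b = maxEdge;
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      el[e] = x1; double f1 = f();
      el[e] = x2; double f2 = f();
      while (b - a > 1e-6) {
        if (f1 >= f2) {
          b = x2; x2 = x1; f2 = f1;
          x1 = b - gr * (b - a);
          el[e] = x1; f1 = f();
        } else {
          a = x1; x1 = x2; f1 = f2;
          x2 = a + gr * (b - a);
          el[e] = x2; f2 = f();
        }
      }
      const double best = (f1 >= f2) ? x1 : x2;
      const double fbest = std::max(f1, f2);
      if (fbest >= ll) { el[e] = best; ll = fbest; }
      else el[e] = old;   // never let the log-likelihood decrease
    }
    double llc = f();
    if (llc > ll) ll = llc;
    if (cycle > 0 && ll - llprev < tol) break;
    llprev = ll;
  }
  return List::create(_["edge_length"] = NumericVector(el.begin(), el.end()),
                      _["loglik"] = ll);
}
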