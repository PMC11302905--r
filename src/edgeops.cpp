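// Fused edge-attention kernels. The per-edge message passing (gather,
// triple-product logits, neighbor softmax, value aggregation) is the hot
// loop of both passes. Loops are column-outer: R matrices are
// column-major, so each inner pass streams one contiguous column (edge
// arrays) or works within one cached node column. Indices in `src`/`dst`
// are 1-based (R).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward: logits zraw[e,h] = (1/sqrt(dh)) * sum_c q[src,c] k[dst,c] B[e,c]
// over head h's column block, clamped to [-clamp, clamp]; softmax per
// (source node, head) over the node's outgoing edges; O = sum_j a * v[dst].
// [[Rcpp::export]]
List edge_attention_fwd_cpp(const NumericMatrix& q, const NumericMatrix& k,
                            const NumericMatrix& v, const NumericMatrix& B,
                            const IntegerVector& src,
                            const IntegerVector& dst, int H, double clamp) {
  const int n = q.nrow(), d = q.ncol(), ne = src.size(), dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix zraw(ne, H), a(ne, H), O(n, d);
  NumericMatrix den(n, H);
  const int* sp = src.begin();
  const int* dp = dst.begin();

  for (int h = 0; h < H; ++h) {
    double* zcol = &zraw(0, h);
    for (int c = h * dh; c < (h + 1) * dh; ++c) {
      const double* qc = &q(0, c);
      const double* kc = &k(0, c);
      const double* Bc = &B(0, c);
      for (int e = 0; e < ne; ++e)
        zcol[e] += qc[sp[e] - 1] * kc[dp[e] - 1] * Bc[e];
    }
    double* acol = &a(0, h);
    double* dcol = &den(0, h);
    for (int e = 0; e < ne; ++e) {
      double z = zcol[e] * scale;
      zcol[e] = z;
      if (z > clamp) z = clamp; else if (z < -clamp) z = -clamp;
      const double ez = std::exp(z);  // safe: z clamped
      acol[e] = ez;
      dcol[sp[e] - 1] += ez;
    }
    for (int e = 0; e < ne; ++e) acol[e] /= dcol[sp[e] - 1];
    for (int c = h * dh; c < (h + 1) * dh; ++c) {
      double* Oc = &O(0, c);
      const double* vc = &v(0, c);
      for (int e = 0; e < ne; ++e)
        Oc[sp[e] - 1] += acol[e] * vc[dp[e] - 1];
    }
  }
  return List::create(_["zraw"] = zraw, _["a"] = a, _["O"] = O);
}

// Reverse-mode counterpart: given dL/dO and the forward cache, produce
// dL/dq, dL/dk, dL/dv (node-shaped) and dL/dB (edge-shaped). Gradients do
// not flow through clamped-out logits.
// [[Rcpp::export]]
List edge_attention_bwd_cpp(const NumericMatrix& dO, const NumericMatrix& a,
                            const NumericMatrix& zraw,
                            const NumericMatrix& q, const NumericMatrix& k,
                            const NumericMatrix& v, const NumericMatrix& B,
                            const IntegerVector& src,
                            const IntegerVector& dst, int H, double clamp) {
  const int n = q.nrow(), d = q.ncol(), ne = src.size(), dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix dq(n, d), dk(n, d), dv(n, d), dB(ne, d);
  std::vector<double> da(ne), S(n), dz(ne);

  for (int h = 0; h < H; ++h) {
    const double* acol = &a(0, h);
    const double* zcol = &zraw(0, h);
    std::fill(da.begin(), da.end(), 0.0);
    std::fill(S.begin(), S.end(), 0.0);
    // da[e] = sum_c dO[src,c] v[dst,c];  dv[dst,c] += a[e] dO[src,c]
    for (int c = h * dh; c < (h + 1) * dh; ++c) {
      const double* dOc = &dO(0, c);
      const double* vc = &v(0, c);
      double* dvc = &dv(0, c);
      for (int e = 0; e < ne; ++e) {
        const double g = dOc[src[e] - 1];
        da[e] += g * vc[dst[e] - 1];
        dvc[dst[e] - 1] += acol[e] * g;
      }
    }
    for (int e = 0; e < ne; ++e) S[src[e] - 1] += acol[e] * da[e];
    for (int e = 0; e < ne; ++e) {
      const double z = zcol[e];
      dz[e] = (z >= clamp || z <= -clamp)
                  ? 0.0
                  : acol[e] * (da[e] - S[src[e] - 1]) * scale;
    }
    for (int c = h * dh; c < (h + 1) * dh; ++c) {
      const double* qc = &q(0, c);
      const double* kc = &k(0, c);
      const double* Bc = &B(0, c);
      double* dqc = &dq(0, c);
      double* dkc = &dk(0, c);
      double* dBc = &dB(0, c);
      for (int e = 0; e < ne; ++e) {
        const int s = src[e] - 1, t = dst[e] - 1;
        const double p = dz[e];
        dqc[s] += p * kc[t] * Bc[e];
        dkc[t] += p * qc[s] * Bc[e];
        dBc[e] = p * qc[s] * kc[t];
      }
    }
  }
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv,
                      _["dB"] = dB);
}
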