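// Hot kernels of the batched graph-attention layers. Each batch folds the
// node (N), time (T) and graph (B) dimensions into one column axis of
// S = B*T independent attention slices. Slices arrive in runs of T sharing
// one graph's neighborhood mask, so each kernel builds the adjacency list
// once per graph block and then loops its slices over edges only; all large
// linear-transform products stay in R's BLAS.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Build receiver -> sender adjacency lists from one mask column
// (pair index p = i + j*N, receiver i, sender j, 0-based).
static void buildLists(const double* mcol, int N,
                       std::vector<int>& deg, std::vector<int>& nbr) {
  for (int i = 0; i < N; ++i) deg[i] = 0;
  for (int i = 0; i < N; ++i) {
    int d = 0;
    for (int j = 0; j < N; ++j) {
      if (mcol[i + j * N] > 0) nbr[i * N + d++] = j;
    }
    deg[i] = d;
  }
}

// Forward: LeakyReLU attention scores, masked softmax per receiver,
// optional attention dropout (drawn from R's RNG, edges only), and
// attention-weighted aggregation with a fused output ReLU.
//
// Z: dh x (N*S); u = aSrc.Z, v = aDst.Z (length N*S); M: (N*N) x S 0/1
// mask; Tn: slices per graph block (S must be a multiple of Tn).
// [[Rcpp::export(name = ".attnHeadForwardCpp")]]
List attnHeadForwardCpp(NumericMatrix Z, NumericVector u, NumericVector v,
                        NumericMatrix M, int N, int Tn, double slope,
                        double dropout, bool training, bool lean) {
  const int C = Z.ncol();
  const int S = C / N;
  const int dh = Z.nrow();
  const int NN = N * N;
  NumericMatrix alpha = lean ? NumericMatrix(0, 0) : NumericMatrix(NN, S);
  NumericMatrix Hagg(dh, C);
  const bool useDrop = training && dropout > 0;
  NumericMatrix dmask = useDrop ? NumericMatrix(NN, S) : NumericMatrix(0, 0);
  const double keepInv = useDrop ? 1.0 / (1.0 - dropout) : 1.0;
  const double* zp = REAL(Z);
  const double* up = REAL(u);
  const double* vp = REAL(v);
  const double* mp = REAL(M);
  double* ap = lean ? nullptr : REAL(alpha);
  double* hp = REAL(Hagg);
  double* dmp = useDrop ? REAL(dmask) : nullptr;
  std::vector<int> deg(N), nbr(N * N);
  std::vector<double> abuf(NN), e(N);

  for (int s = 0; s < S; ++s) {
    if (s % Tn == 0) buildLists(mp + (size_t)s * NN, N, deg, nbr);
    const double* us = up + (size_t)s * N;
    const double* vs = vp + (size_t)s * N;
    double* acol = lean ? abuf.data() : ap + (size_t)s * NN;
    if (lean) std::fill(abuf.begin(), abuf.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const int d = deg[i];
      const int* ni = nbr.data() + i * N;
      double mx = -INFINITY;
      for (int k = 0; k < d; ++k) {
        const double pre = us[i] + vs[ni[k]];
        const double val = pre > 0 ? pre : slope * pre;
        e[k] = val;
        if (val > mx) mx = val;
      }
      double sum = 0.0;
      for (int k = 0; k < d; ++k) {
        e[k] = std::exp(e[k] - mx);
        sum += e[k];
      }
      const double inv = 1.0 / sum;
      for (int k = 0; k < d; ++k) acol[i + ni[k] * N] = e[k] * inv;
    }
    if (useDrop) {
      double* dmc = dmp + (size_t)s * NN;
      for (int i = 0; i < N; ++i) {
        const int d = deg[i];
        const int* ni = nbr.data() + i * N;
        for (int k = 0; k < d; ++k) {
          const int p = i + ni[k] * N;
          const double keep = (R::unif_rand() >= dropout) ? keepInv : 0.0;
          dmc[p] = keep;
        }
      }
    }
    const double* zs = zp + (size_t)s * N * dh;
    double* hs = hp + (size_t)s * N * dh;
    for (int i = 0; i < N; ++i) {
      const int d = deg[i];
      const int* ni = nbr.data() + i * N;
      double* hi = hs + (size_t)i * dh;
      for (int k = 0; k < d; ++k) {
        const int j = ni[k];
        const int p = i + j * N;
        const double w = useDrop
          ? acol[p] * (dmp + (size_t)s * NN)[p] : acol[p];
        if (w != 0.0) {
          const double* zj = zs + (size_t)j * dh;
          for (int dd = 0; dd < dh; ++dd) hi[dd] += w * zj[dd];
        }
      }
      // fused ReLU
      for (int dd = 0; dd < dh; ++dd) {
        if (hi[dd] < 0) hi[dd] = 0;
      }
    }
  }

  if (lean) return List::create(Named("Hrelu") = Hagg);
  List out = List::create(Named("alpha") = alpha, Named("Hrelu") = Hagg);
  if (useDrop) out["dmask"] = dmask;
  return out;
}

// Backward through aggregation, dropout, softmax, the LeakyReLU scores and
// the fused output ReLU of one head. The LeakyReLU derivative is recomputed
// from u and v instead of being cached. Returns the full dZ (aggregation +
// score contributions) and the attention-vector gradients; dW = dZ Hin^T
// and dHin = W^T dZ are large BLAS products done in R.
// [[Rcpp::export(name = ".attnHeadBackwardCpp")]]
List attnHeadBackwardCpp(NumericMatrix Z, NumericMatrix dHrelu,
                         NumericMatrix Hrelu, NumericMatrix alpha,
                         Nullable<NumericMatrix> dmaskR,
                         NumericVector u, NumericVector v,
                         NumericMatrix M, int N, int Tn, double slope,
                         NumericVector aSrc, NumericVector aDst) {
  const int C = Z.ncol();
  const int S = C / N;
  const int dh = Z.nrow();
  const int NN = N * N;
  const bool useDrop = dmaskR.isNotNull();
  NumericMatrix dmask = useDrop ? NumericMatrix(dmaskR.get())
                                : NumericMatrix(0, 0);
  NumericMatrix dZ(dh, C);
  NumericVector daSrc(dh), daDst(dh);
  const double* zp = REAL(Z);
  const double* drp = REAL(dHrelu);
  const double* hrp = REAL(Hrelu);
  const double* apb = REAL(alpha);
  const double* dmp = useDrop ? REAL(dmask) : nullptr;
  const double* up = REAL(u);
  const double* vp = REAL(v);
  const double* mp = REAL(M);
  const double* asp = REAL(aSrc);
  const double* adp = REAL(aDst);
  double* dzp = REAL(dZ);
  double* dasp = REAL(daSrc);
  double* dadp = REAL(daDst);
  std::vector<int> deg(N), nbr(N * N);
  std::vector<double> dA(NN), dU(N), dV(N), dHs(N * dh);

  for (int s = 0; s < S; ++s) {
    if (s % Tn == 0) buildLists(mp + (size_t)s * NN, N, deg, nbr);
    const size_t off = (size_t)s * N * dh;
    const double* zs = zp + off;
    // fused output-ReLU backward: dHagg = dHrelu * (Hrelu > 0)
    for (int d = 0; d < N * dh; ++d) {
      dHs[d] = hrp[off + d] > 0 ? drp[off + d] : 0.0;
    }
    double* dzs = dzp + off;
    const double* acol = apb + (size_t)s * NN;
    const double* dmc = useDrop ? dmp + (size_t)s * NN : nullptr;
    const double* us = up + (size_t)s * N;
    const double* vs = vp + (size_t)s * N;
    // dalphaU[i,j] = dHagg_i . Z_j ; dZ (aggregation) += alphaU * dHagg_i
    for (int i = 0; i < N; ++i) {
      const int d = deg[i];
      const int* ni = nbr.data() + i * N;
      const double* dhi = dHs.data() + (size_t)i * dh;
      for (int k = 0; k < d; ++k) {
        const int j = ni[k];
        const int p = i + j * N;
        const double* zj = zs + (size_t)j * dh;
        double dot = 0.0;
        for (int dd = 0; dd < dh; ++dd) dot += dhi[dd] * zj[dd];
        dA[p] = dot;
        const double au = useDrop ? acol[p] * dmc[p] : acol[p];
        if (au != 0.0) {
          double* dzj = dzs + (size_t)j * dh;
          for (int dd = 0; dd < dh; ++dd) dzj[dd] += au * dhi[dd];
        }
      }
    }
    // dropout + softmax + LeakyReLU backward, per receiver, edges only
    for (int i = 0; i < N; ++i) dU[i] = 0.0;
    for (int j = 0; j < N; ++j) dV[j] = 0.0;
    for (int i = 0; i < N; ++i) {
      const int d = deg[i];
      const int* ni = nbr.data() + i * N;
      double g = 0.0;
      for (int k = 0; k < d; ++k) {
        const int p = i + ni[k] * N;
        double da = dA[p];
        if (useDrop) da *= dmc[p];
        da *= acol[p];
        dA[p] = da;
        g += da;
      }
      for (int k = 0; k < d; ++k) {
        const int j = ni[k];
        const int p = i + j * N;
        const double pre = us[i] + vs[j];
        const double dE = (dA[p] - acol[p] * g) * (pre > 0 ? 1.0 : slope);
        dU[i] += dE;
        dV[j] += dE;
      }
    }
    // score contributions and attention-vector gradients
    for (int i = 0; i < N; ++i) {
      const double dui = dU[i];
      const double dvi = dV[i];
      double* dzi = dzs + (size_t)i * dh;
      const double* zi = zs + (size_t)i * dh;
      for (int dd = 0; dd < dh; ++dd) {
        dzi[dd] += asp[dd] * dui + adp[dd] * dvi;
        dasp[dd] += zi[dd] * dui;
        dadp[dd] += zi[dd] * dvi;
      }
    }
  }
  return List::create(Named("dZ") = dZ, Named("daSrc") = daSrc,
                      Named("daDst") = daDst);
}
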