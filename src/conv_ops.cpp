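#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dense 2D convolution with dilation and zero ('same') padding over an
// (H, W, Cin) array, weights (K, K, Cin, Cout), one bias per output channel.
// Plain single-threaded loops: deterministic across runs and platforms.

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int K = wd[0], Cout = wd[3];
  if (wd[1] != K || wd[2] != Cin)
    stop("weight dims inconsistent with input channels");
  const int half = K / 2;
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();

  for (int co = 0; co < Cout; ++co) {
    double *o = po + static_cast<R_xlen_t>(co) * H * W;
    const double bias = b[co];
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) o[i] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xi = px + static_cast<R_xlen_t>(ci) * H * W;
      for (int kw = 0; kw < K; ++kw) {
        const int dw = (kw - half) * dilation;
        for (int kh = 0; kh < K; ++kh) {
          const int dh = (kh - half) * dilation;
          const double wv =
              pw[kh + K * (kw + K * (ci + Cin * co))];
          if (wv == 0.0) continue;
          const int c0 = std::max(0, -dw), c1 = std::min(W, W - dw);
          const int r0 = std::max(0, -dh), r1 = std::min(H, H - dh);
          for (int c = c0; c < c1; ++c) {
            const double *xcol = xi + static_cast<R_xlen_t>(c + dw) * H + dh;
            double *ocol = o + static_cast<R_xlen_t>(c) * H;
            for (int r = r0; r < r1; ++r) ocol[r] += wv * xcol[r];
          }
        }
      }
    }
  }
  return out;
}

// Gradients of the convolution above. gy has shape (H, W, Cout).
// Returns list(gx, gw, gb).

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int K = wd[0], Cout = wd[3];
  const int half = K / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector gw(static_cast<R_xlen_t>(K) * K * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector gb(Cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();

  for (int co = 0; co < Cout; ++co) {
    const double *g = pg + static_cast<R_xlen_t>(co) * H * W;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) acc += g[i];
    gb[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xi = px + static_cast<R_xlen_t>(ci) * H * W;
      double *gxi = pgx + static_cast<R_xlen_t>(ci) * H * W;
      for (int kw = 0; kw < K; ++kw) {
        const int dw = (kw - half) * dilation;
        for (int kh = 0; kh < K; ++kh) {
          const int dh = (kh - half) * dilation;
          const R_xlen_t widx = kh + K * (kw + K * (ci + static_cast<R_xlen_t>(Cin) * co));
          const double wv = pw[widx];
          const int c0 = std::max(0, -dw), c1 = std::min(W, W - dw);
          const int r0 = std::max(0, -dh), r1 = std::min(H, H - dh);
          double gwacc = 0.0;
          for (int c = c0; c < c1; ++c) {
            const double *xcol = xi + static_cast<R_xlen_t>(c + dw) * H + dh;
            double *gxcol = gxi + static_cast<R_xlen_t>(c + dw) * H + dh;
            const double *gcol = g + static_cast<R_xlen_t>(c) * H;
            for (int r = r0; r < r1; ++r) {
              const double gv = gcol[r];
              gwacc += gv * xcol[r];
              gxcol[r] += wv * gv;
            }
          }
          pgw[widx] = gwacc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Minimal heavy-atom distance between residue pairs. coords is (n_atoms, 3),
// res is the 1-based residue index of each atom, L the residue count.

// [[Rcpp::export(name = ".min_dist_matrix")]]
NumericMatrix min_dist_matrix(NumericMatrix coords, IntegerVector res, int L) {
  const int n = coords.nrow();
  NumericMatrix out(L, L);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < L; ++i) out(i, i) = 0.0;
  for (int a = 0; a < n; ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    const int ra = res[a] - 1;
    for (int bIdx = a + 1; bIdx < n; ++bIdx) {
      const int rb = res[bIdx] - 1;
      if (ra == rb) continue;
      const double dx = xa - coords(bIdx, 0);
      const double dy = ya - coords(bIdx, 1);
      const double dz = za - coords(bIdx, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(ra, rb)) { out(ra, rb) = d; out(rb, ra) = d; }
    }
  }
  return out;
}
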