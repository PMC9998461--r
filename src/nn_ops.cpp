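// Minimal CNN primitives (3x3 same-padding convolution, 2x2 max-pool,
// 2x2 stride-2 transposed convolution) with exact backward passes.
// Layout contract with the R side:
//   feature maps: arma::cube (H rows, W cols, C slices) == R array [H, W, C]
//   3x3 conv weights: arma::mat (9*Cin, Cout), row index r = ci*9 + dj*3 + di
//     with di (row offset) fastest — i.e. matrix(w4d, 9*Cin, Cout) of an R
//     array dim c(3, 3, Cin, Cout).
//   2x2 tconv weights: arma::mat (4*Cin, Cout), r = ci*4 + dj*2 + di.
// im2col is kept in (H*W) x (9*Cin) orientation so that both the patch
// copies and the GEMMs run over contiguous memory.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2colT3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat colT((size_t)H * W, 9 * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int r = ci * 9 + (dj + 1) * 3 + (di + 1);
        double* dst0 = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          std::memcpy(dst0 + (size_t)j * H + i0,
                      x.slice_colptr(ci, jj) + i0 + di,
                      (i1 - i0) * sizeof(double));
        }
      }
  return colT;
}

static void col2imT3(const arma::mat& dcolT, arma::cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int ci = 0; ci < C; ++ci)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int r = ci * 9 + (dj + 1) * 3 + (di + 1);
        const double* src0 = dcolT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double* dst = gx.slice_colptr(ci, jj) + i0 + di;
          const double* src = src0 + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
}

// [[Rcpp::export]]
arma::cube cg_conv3_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat out = im2colT3(x) * w;        // (H*W) x Cout
  out.each_row() += b.t();
  return arma::cube(out.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
List cg_conv3_bwd(const arma::cube& x, const arma::mat& w,
                  const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat colT = im2colT3(x);
  const arma::mat gmat(const_cast<double*>(gout.memptr()),
                       (size_t)H * W, gout.n_slices, false, true);
  arma::mat gw = colT.t() * gmat;         // (9C) x Cout
  arma::vec gb = arma::sum(gmat, 0).t();
  arma::mat dcolT = gmat * w.t();         // (H*W) x (9C)
  arma::cube gx(H, W, C, arma::fill::zeros);
  col2imT3(dcolT, gx);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cg_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector idx((size_t)Ho * Wo * C);   // linear index into x
  size_t k = 0;
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = sl(i2, j2); int bi = i2, bj = j2;
        if (sl(i2 + 1, j2) > best)     { best = sl(i2 + 1, j2);     bi = i2 + 1; bj = j2; }
        if (sl(i2, j2 + 1) > best)     { best = sl(i2, j2 + 1);     bi = i2;     bj = j2 + 1; }
        if (sl(i2 + 1, j2 + 1) > best) { best = sl(i2 + 1, j2 + 1); bi = i2 + 1; bj = j2 + 1; }
        out(i, j, c) = best;
        idx[k++] = (int)((size_t)c * H * W + (size_t)bj * H + bi);
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cg_maxpool2_bwd(const arma::cube& gout, const IntegerVector& idx,
                           int H, int W) {
  const int C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gout.memptr();
  double* p = gx.memptr();
  const size_t n = gout.n_elem;
  for (size_t k = 0; k < n; ++k) p[idx[k]] += g[k];
  return gx;
}

// [[Rcpp::export]]
arma::cube cg_tconv2_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  arma::cube out(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    out.slice(co).fill(b(co));
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wv = w(ci * 4 + dj * 2 + di, co);
          if (wv == 0) continue;
          for (int j = 0; j < W; ++j) {
            const double* src = x.slice_colptr(ci, j);
            double* dst = out.slice_colptr(co, 2 * j + dj) + di;
            for (int i = 0; i < H; ++i) dst[2 * i] += wv * src[i];
          }
        }
  }
  return out;
}

// [[Rcpp::export]]
List cg_tconv2_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  arma::mat gw(4 * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = arma::accu(gout.slice(co));
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wv = w(ci * 4 + dj * 2 + di, co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j) {
            const double* g = gout.slice_colptr(co, 2 * j + dj) + di;
            const double* src = x.slice_colptr(ci, j);
            double* dst = gx.slice_colptr(ci, j);
            for (int i = 0; i < H; ++i) {
              const double gv = g[2 * i];
              acc += gv * src[i];
              dst[i] += wv * gv;
            }
          }
          gw(ci * 4 + dj * 2 + di, co) = acc;
        }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
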