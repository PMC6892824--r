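// Dense 3D conv-net primitives on channels-x-voxels matrices.
//
// Feature maps are arma::mat of size C x N where N = Z*Y*X and the voxel
// (z, y, x) (0-based) sits at linear index  n = z + Z*(y + Y*x),  i.e. the
// same order as an R array with dim = c(Z, Y, X).  Convolutions are expressed
// as im2col + GEMM so the heavy lifting goes through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int lin_idx(int z, int y, int x, int Z, int Y) {
  return z + Z * (y + Y * x);
}

// im2col for a 3x3x3 kernel with 1-voxel zero padding (shape preserving).
// Output: (Cin*27) x N, row c + Cin*k for channel c and kernel offset k,
// k = (dz+1) + 3*(dy+1) + 9*(dx+1) with dz,dy,dx in {-1,0,1}.
// [[Rcpp::export]]
arma::mat nsg_im2col3(const arma::mat& X, int Z, int Y, int Xd) {
  const int Cin = X.n_rows;
  const int N = Z * Y * Xd;
  if ((int)X.n_cols != N) stop("im2col: column count does not match dims");
  arma::mat cols(Cin * 27, N, arma::fill::zeros);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dz = -1; dz <= 1; ++dz) {
        const int k = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
        const int r0 = Cin * k;
        for (int x = 0; x < Xd; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= Xd) continue;
          for (int y = 0; y < Y; ++y) {
            const int ys = y + dy;
            if (ys < 0 || ys >= Y) continue;
            const int z_lo = std::max(0, -dz);
            const int z_hi = std::min(Z, Z - dz);
            if (z_lo >= z_hi) continue;
            // contiguous run in z
            const int n_dst = lin_idx(z_lo, y, x, Z, Y);
            const int n_src = lin_idx(z_lo + dz, ys, xs, Z, Y);
            cols.submat(r0, n_dst, r0 + Cin - 1, n_dst + (z_hi - z_lo) - 1) =
              X.submat(0, n_src, Cin - 1, n_src + (z_hi - z_lo) - 1);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of nsg_im2col3: scatter-add column gradients back to input layout.
// [[Rcpp::export]]
arma::mat nsg_col2im3(const arma::mat& dCols, int Z, int Y, int Xd, int Cin) {
  const int N = Z * Y * Xd;
  if ((int)dCols.n_rows != Cin * 27 || (int)dCols.n_cols != N)
    stop("col2im: bad shape");
  arma::mat dX(Cin, N, arma::fill::zeros);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dz = -1; dz <= 1; ++dz) {
        const int k = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
        const int r0 = Cin * k;
        for (int x = 0; x < Xd; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= Xd) continue;
          for (int y = 0; y < Y; ++y) {
            const int ys = y + dy;
            if (ys < 0 || ys >= Y) continue;
            const int z_lo = std::max(0, -dz);
            const int z_hi = std::min(Z, Z - dz);
            if (z_lo >= z_hi) continue;
            const int n_dst = lin_idx(z_lo, y, x, Z, Y);
            const int n_src = lin_idx(z_lo + dz, ys, xs, Z, Y);
            dX.submat(0, n_src, Cin - 1, n_src + (z_hi - z_lo) - 1) +=
              dCols.submat(r0, n_dst, r0 + Cin - 1, n_dst + (z_hi - z_lo) - 1);
          }
        }
      }
    }
  }
  return dX;
}

// 2x2x2 max pooling, stride 2.  Dims must be even.  Returns pooled map plus
// the flat argmax (0-based column index into the input) per output entry.
// [[Rcpp::export]]
List nsg_maxpool3_fwd(const arma::mat& X, int Z, int Y, int Xd) {
  if (Z % 2 || Y % 2 || Xd % 2) stop("maxpool: dims must be even");
  const int C = X.n_rows;
  const int Zo = Z / 2, Yo = Y / 2, Xo = Xd / 2;
  const int No = Zo * Yo * Xo;
  arma::mat out(C, No);
  arma::umat amax(C, No);
  for (int xo = 0; xo < Xo; ++xo) {
    for (int yo = 0; yo < Yo; ++yo) {
      for (int zo = 0; zo < Zo; ++zo) {
        const int no = lin_idx(zo, yo, xo, Zo, Yo);
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                const int n = lin_idx(2 * zo + dz, 2 * yo + dy, 2 * xo + dx, Z, Y);
                const double v = X(c, n);
                if (v > best) { best = v; bidx = n; }
              }
          out(c, no) = best;
          amax(c, no) = (arma::uword)bidx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::mat nsg_maxpool3_bwd(const arma::mat& dY, const arma::umat& amax, int N) {
  const int C = dY.n_rows;
  arma::mat dX(C, N, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, amax(c, j)) += dY(c, j);
  return dX;
}

// Transpose convolution, kernel 2, stride 2 (doubles every spatial dim).
// W is Cout x (Cin*8); the block for offset o = dz + 2*dy + 4*dx is columns
// [Cin*o, Cin*(o+1)).  Each input voxel populates its 8 children exactly once
// (no output overlap), so forward and backward are straight GEMM + gather.
// [[Rcpp::export]]
arma::mat nsg_upconv3_fwd(const arma::mat& X, const arma::mat& W,
                          const arma::vec& b, int Z, int Y, int Xd) {
  const int Cin = X.n_rows;
  const int Cout = W.n_rows;
  if ((int)W.n_cols != Cin * 8) stop("upconv: W shape mismatch");
  const int Zo = 2 * Z, Yo = 2 * Y;
  const int No = 8 * Z * Y * Xd;
  arma::mat out(Cout, No);
  out.each_col() = b;
  for (int o = 0; o < 8; ++o) {
    const int dz = o & 1, dy = (o >> 1) & 1, dx = (o >> 2) & 1;
    arma::mat Yo_blk = W.cols(Cin * o, Cin * (o + 1) - 1) * X;  // Cout x N
    for (int x = 0; x < Xd; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          const int n = lin_idx(z, y, x, Z, Y);
          const int no = lin_idx(2 * z + dz, 2 * y + dy, 2 * x + dx, Zo, Yo);
          out.col(no) += Yo_blk.col(n);
        }
  }
  return out;
}

// [[Rcpp::export]]
List nsg_upconv3_bwd(const arma::mat& dY, const arma::mat& X,
                     const arma::mat& W, int Z, int Y, int Xd) {
  const int Cin = X.n_rows;
  const int Cout = W.n_rows;
  const int Zo = 2 * Z, Yo = 2 * Y;
  arma::mat dW(Cout, Cin * 8, arma::fill::zeros);
  arma::mat dX(Cin, X.n_cols, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 1);
  for (int o = 0; o < 8; ++o) {
    const int dz = o & 1, dy = (o >> 1) & 1, dx = (o >> 2) & 1;
    arma::mat dYo(Cout, X.n_cols);
    for (int x = 0; x < Xd; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          const int n = lin_idx(z, y, x, Z, Y);
          const int no = lin_idx(2 * z + dz, 2 * y + dy, 2 * x + dx, Zo, Yo);
          dYo.col(n) = dY.col(no);
        }
    dW.cols(Cin * o, Cin * (o + 1) - 1) = dYo * X.t();
    dX += W.cols(Cin * o, Cin * (o + 1) - 1).t() * dYo;
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
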