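// Low-level compute kernels for the V-net experts and the gating network:
// same-padding 2D/3D convolutions with explicit backward passes, and
// ceil-mode 2x max pooling with argmax bookkeeping. Tensors are plain R
// arrays in column-major order, spatial dims first, channels last.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  const int P = K / 2;
  if (wd[1] != K || wd[2] != K || wd[3] != Ci)
    stop("conv3d: weight dims mismatch");
  NumericVector y(static_cast<R_xlen_t>(X) * Y * Z * Co);
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  const R_xlen_t xc = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t yc = xc;
  for (int co = 0; co < Co; ++co) {
    const double bias = b[co];
    double* yco = py + yc * co;
    for (R_xlen_t i = 0; i < yc; ++i) yco[i] = bias;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = px + xc * ci;
      const double* wk = pw + (static_cast<R_xlen_t>(K) * K * K) * (ci + static_cast<R_xlen_t>(Ci) * co);
      for (int kz = 0; kz < K; ++kz) {
        for (int ky = 0; ky < K; ++ky) {
          for (int kx = 0; kx < K; ++kx) {
            const double wv = wk[kx + K * (ky + K * kz)];
            if (wv == 0.0) continue;
            const int dz = kz - P, dy = ky - P, dx = kx - P;
            const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
            const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
            const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
            for (int z = z0; z < z1; ++z) {
              for (int yy = y0; yy < y1; ++yy) {
                const double* xrow = xci + static_cast<R_xlen_t>(X) * ((yy + dy) + static_cast<R_xlen_t>(Y) * (z + dz)) + dx;
                double* yrow = yco + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * z);
                for (int xx = x0; xx < x1; ++xx) yrow[xx] += wv * xrow[xx];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  const int P = K / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pgy = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  const R_xlen_t xc = static_cast<R_xlen_t>(X) * Y * Z;
  for (int co = 0; co < Co; ++co) {
    const double* gyco = pgy + xc * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < xc; ++i) acc += gyco[i];
    gb[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = px + xc * ci;
      double* gxci = pgx + xc * ci;
      const R_xlen_t woff = (static_cast<R_xlen_t>(K) * K * K) * (ci + static_cast<R_xlen_t>(Ci) * co);
      const double* wk = pw + woff;
      double* gwk = pgw + woff;
      for (int kz = 0; kz < K; ++kz) {
        for (int ky = 0; ky < K; ++ky) {
          for (int kx = 0; kx < K; ++kx) {
            const double wv = wk[kx + K * (ky + K * kz)];
            double gwv = 0.0;
            const int dz = kz - P, dy = ky - P, dx = kx - P;
            const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
            const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
            const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
            for (int z = z0; z < z1; ++z) {
              for (int yy = y0; yy < y1; ++yy) {
                const R_xlen_t src = static_cast<R_xlen_t>(X) * ((yy + dy) + static_cast<R_xlen_t>(Y) * (z + dz)) + dx;
                const R_xlen_t dst = static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * z);
                const double* xrow = xci + src;
                double* gxrow = gxci + src;
                const double* gyrow = gyco + dst;
                for (int xx = x0; xx < x1; ++xx) {
                  const double g = gyrow[xx];
                  gwv += xrow[xx] * g;
                  gxrow[xx] += wv * g;
                }
              }
            }
            gwk[kx + K * (ky + K * kz)] += gwv;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  const int P = K / 2;
  NumericVector y(static_cast<R_xlen_t>(X) * Y * Co);
  y.attr("dim") = IntegerVector::create(X, Y, Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  const R_xlen_t xc = static_cast<R_xlen_t>(X) * Y;
  for (int co = 0; co < Co; ++co) {
    double* yco = py + xc * co;
    for (R_xlen_t i = 0; i < xc; ++i) yco[i] = b[co];
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = px + xc * ci;
      const double* wk = pw + (static_cast<R_xlen_t>(K) * K) * (ci + static_cast<R_xlen_t>(Ci) * co);
      for (int ky = 0; ky < K; ++ky) {
        for (int kx = 0; kx < K; ++kx) {
          const double wv = wk[kx + K * ky];
          const int dy = ky - P, dx = kx - P;
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          for (int yy = y0; yy < y1; ++yy) {
            const double* xrow = xci + static_cast<R_xlen_t>(X) * (yy + dy) + dx;
            double* yrow = yco + static_cast<R_xlen_t>(X) * yy;
            for (int xx = x0; xx < x1; ++xx) yrow[xx] += wv * xrow[xx];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  const int P = K / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pgy = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  const R_xlen_t xc = static_cast<R_xlen_t>(X) * Y;
  for (int co = 0; co < Co; ++co) {
    const double* gyco = pgy + xc * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < xc; ++i) acc += gyco[i];
    gb[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xci = px + xc * ci;
      double* gxci = pgx + xc * ci;
      const R_xlen_t woff = (static_cast<R_xlen_t>(K) * K) * (ci + static_cast<R_xlen_t>(Ci) * co);
      for (int ky = 0; ky < K; ++ky) {
        for (int kx = 0; kx < K; ++kx) {
          const double wv = pw[woff + kx + K * ky];
          double gwv = 0.0;
          const int dy = ky - P, dx = kx - P;
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          for (int yy = y0; yy < y1; ++yy) {
            const R_xlen_t src = static_cast<R_xlen_t>(X) * (yy + dy) + dx;
            const R_xlen_t dst = static_cast<R_xlen_t>(X) * yy;
            for (int xx = x0; xx < x1; ++xx) {
              const double g = gyco[dst + xx];
              gwv += xci[src + xx] * g;
              gxci[src + xx] += wv * g;
            }
          }
          pgw[woff + kx + K * ky] += gwv;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Ceil-mode 2x2x2 max pooling over the three spatial dims of (X,Y,Z,C).
// [[Rcpp::export]]
List maxpool3d_fw_cpp(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = (X + 1) / 2, Yo = (Y + 1) / 2, Zo = (Z + 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * Zo * C);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  idx.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double* px = x.begin();
  double* py = y.begin();
  int* pidx = idx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = static_cast<R_xlen_t>(X) * Y * Z * c;
    for (int zo = 0; zo < Zo; ++zo) {
      for (int yo = 0; yo < Yo; ++yo) {
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int dz = 0; dz < 2; ++dz) {
            const int z = 2 * zo + dz;
            if (z >= Z) break;
            for (int dy = 0; dy < 2; ++dy) {
              const int yy = 2 * yo + dy;
              if (yy >= Y) break;
              for (int dx = 0; dx < 2; ++dx) {
                const int xx = 2 * xo + dx;
                if (xx >= X) break;
                const R_xlen_t li = coff + xx + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * z);
                if (px[li] > best) { best = px[li]; bi = li; }
              }
            }
          }
          py[o] = best;
          pidx[o] = static_cast<int>(bi) + 1; // 1-based into x
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double* pgx = gx.begin();
  const double* pgy = gy.begin();
  const int* pidx = idx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pidx[i] - 1] += pgy[i];
  return gx;
}

// Ceil-mode 2x2 max pooling over the two spatial dims of (X,Y,C).
// [[Rcpp::export]]
List maxpool2d_fw_cpp(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], C = xd[2];
  const int Xo = (X + 1) / 2, Yo = (Y + 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * C);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Xo, Yo, C);
  idx.attr("dim") = IntegerVector::create(Xo, Yo, C);
  const double* px = x.begin();
  double* py = y.begin();
  int* pidx = idx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = static_cast<R_xlen_t>(X) * Y * c;
    for (int yo = 0; yo < Yo; ++yo) {
      for (int xo = 0; xo < Xo; ++xo, ++o) {
        double best = R_NegInf;
        R_xlen_t bi = -1;
        for (int dy = 0; dy < 2; ++dy) {
          const int yy = 2 * yo + dy;
          if (yy >= Y) break;
          for (int dx = 0; dx < 2; ++dx) {
            const int xx = 2 * xo + dx;
            if (xx >= X) break;
            const R_xlen_t li = coff + xx + static_cast<R_xlen_t>(X) * yy;
            if (px[li] > best) { best = px[li]; bi = li; }
          }
        }
        py[o] = best;
        pidx[o] = static_cast<int>(bi) + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}
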