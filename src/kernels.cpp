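#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
#include <array>
#include <map>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Tensors are stored channel-first as R numeric vectors with dim (C, X, Y, Z):
// flat index c + C*(x + X*(y + Y*z)).  Convolution weights have dim
// (Cout, Cin, K, K, K): co + Cout*(ci + Cin*(kx + K*(ky + K*kz))).
// All convolutions use "same" zero padding of (K-1)/2.

// im2col: B is (C*K^3) x V column-major, V = X*Y*Z voxels in grid order.
static void im2col(const double *px, int C, int X, int Y, int Z, int K,
                   std::vector<double> &B) {
  const int P = (K - 1) / 2;
  const R_xlen_t V = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t M = static_cast<R_xlen_t>(C) * K * K * K;
  B.assign(M * V, 0.0);
  double *pb = B.data();
  for (int iz = 0; iz < Z; ++iz)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const R_xlen_t v = ix + static_cast<R_xlen_t>(X) * (iy + static_cast<R_xlen_t>(Y) * iz);
        double *col = pb + M * v;
        for (int kz = 0; kz < K; ++kz) {
          const int sz = iz + kz - P; if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < K; ++ky) {
            const int sy = iy + ky - P; if (sy < 0 || sy >= Y) continue;
            for (int kx = 0; kx < K; ++kx) {
              const int sx = ix + kx - P; if (sx < 0 || sx >= X) continue;
              const double *src = px + static_cast<R_xlen_t>(C) * (sx + static_cast<R_xlen_t>(X) * (sy + static_cast<R_xlen_t>(Y) * sz));
              double *dst = col + static_cast<R_xlen_t>(C) * (kx + K * (ky + K * kz));
              for (int ci = 0; ci < C; ++ci) dst[ci] = src[ci];
            }
          }
        }
      }
}

// col2im: scatter-add the (C*K^3) x V gradient back onto the input grid
static void col2im(const std::vector<double> &B, int C, int X, int Y, int Z,
                   int K, double *pgx) {
  const int P = (K - 1) / 2;
  const R_xlen_t M = static_cast<R_xlen_t>(C) * K * K * K;
  const double *pb = B.data();
  for (int iz = 0; iz < Z; ++iz)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const R_xlen_t v = ix + static_cast<R_xlen_t>(X) * (iy + static_cast<R_xlen_t>(Y) * iz);
        const double *col = pb + M * v;
        for (int kz = 0; kz < K; ++kz) {
          const int sz = iz + kz - P; if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < K; ++ky) {
            const int sy = iy + ky - P; if (sy < 0 || sy >= Y) continue;
            for (int kx = 0; kx < K; ++kx) {
              const int sx = ix + kx - P; if (sx < 0 || sx >= X) continue;
              double *dst = pgx + static_cast<R_xlen_t>(C) * (sx + static_cast<R_xlen_t>(X) * (sy + static_cast<R_xlen_t>(Y) * sz));
              const double *src = col + static_cast<R_xlen_t>(C) * (kx + K * (ky + K * kz));
              for (int ci = 0; ci < C; ++ci) dst[ci] += src[ci];
            }
          }
        }
      }
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector bias, int K) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Co = bias.size();
  const int V = X * Y * Z;
  const int M = C * K * K * K;
  NumericVector y(static_cast<R_xlen_t>(Co) * V);
  double *py = y.begin();
  const double one = 1.0, zero = 0.0;
  if (K == 1) {
    F77_CALL(dgemm)("N", "N", &Co, &V, &M, &one, w.begin(), &Co, x.begin(),
                    &M, &zero, py, &Co FCONE FCONE);
  } else {
    std::vector<double> B;
    im2col(x.begin(), C, X, Y, Z, K, B);
    F77_CALL(dgemm)("N", "N", &Co, &V, &M, &one, w.begin(), &Co, B.data(),
                    &M, &zero, py, &Co FCONE FCONE);
  }
  const double *pb = bias.begin();
  for (R_xlen_t v = 0; v < V; ++v) {
    double *yp = py + static_cast<R_xlen_t>(Co) * v;
    for (int co = 0; co < Co; ++co) yp[co] += pb[co];
  }
  y.attr("dim") = IntegerVector::create(Co, X, Y, Z);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, int K, NumericVector gy, int Co) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int V = X * Y * Z;
  const int M = C * K * K * K;
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  const double one = 1.0, zero = 0.0;
  const double *pgy = gy.begin();
  // gb: per-output-channel sums
  double *pgb = gb.begin();
  for (R_xlen_t v = 0; v < V; ++v) {
    const double *gp = pgy + static_cast<R_xlen_t>(Co) * v;
    for (int co = 0; co < Co; ++co) pgb[co] += gp[co];
  }
  if (K == 1) {
    // gw = gy (Co x V) * x^T (V x M);  gx = w^T (M x Co) * gy
    F77_CALL(dgemm)("N", "T", &Co, &M, &V, &one, pgy, &Co, x.begin(), &M,
                    &zero, gw.begin(), &Co FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &M, &V, &Co, &one, w.begin(), &Co, pgy, &Co,
                    &zero, gx.begin(), &M FCONE FCONE);
  } else {
    std::vector<double> B;
    im2col(x.begin(), C, X, Y, Z, K, B);
    F77_CALL(dgemm)("N", "T", &Co, &M, &V, &one, pgy, &Co, B.data(), &M,
                    &zero, gw.begin(), &Co FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &M, &V, &Co, &one, w.begin(), &Co, pgy, &Co,
                    &zero, B.data(), &M FCONE FCONE);
    std::fill(gx.begin(), gx.end(), 0.0);
    col2im(B, C, X, Y, Z, K, gx.begin());
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; spatial extents must be even.  Ties resolve to the
// first element in scan order (deterministic).
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * Xo * Yo * Zo);
  IntegerVector idx(y.size());
  const double *px = x.begin();
  double *py = y.begin(); int *pidx = idx.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; R_xlen_t bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t i = c + static_cast<R_xlen_t>(C) * ((2 * ox + dx) + static_cast<R_xlen_t>(X) * ((2 * oy + dy) + static_cast<R_xlen_t>(Y) * (2 * oz + dz)));
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          const R_xlen_t o = c + static_cast<R_xlen_t>(C) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
          py[o] = best; pidx[o] = static_cast<int>(bi);
        }
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  double *pgx = gx.begin(); const double *pgy = gy.begin();
  const int *pidx = idx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pidx[i]] += pgy[i];
  gx.attr("dim") = xdim;
  return gx;
}

static inline void lin_coeffs(int n_in, int n_out, std::vector<int> &i0,
                              std::vector<int> &i1, std::vector<double> &w1) {
  // half-pixel-centre mapping: out i -> in (i + 0.5) * n_in / n_out - 0.5
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * (static_cast<double>(n_in) / n_out) - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int f = static_cast<int>(std::floor(s));
    if (f > n_in - 2) f = n_in - 2;
    if (f < 0) f = 0;
    i0[i] = f; i1[i] = (n_in >= 2) ? f + 1 : f;
    w1[i] = (n_in >= 2) ? (s - f) : 0.0;
  }
}

// trilinear upsampling to an arbitrary (usually doubled) target shape
// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xdim,
                               IntegerVector outdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = outdim[0], Yo = outdim[1], Zo = outdim[2];
  std::vector<int> x0, x1, y0, y1, z0, z1; std::vector<double> wx, wy, wz;
  lin_coeffs(X, Xo, x0, x1, wx);
  lin_coeffs(Y, Yo, y0, y1, wy);
  lin_coeffs(Z, Zo, z0, z1, wz);
  NumericVector y(static_cast<R_xlen_t>(C) * Xo * Yo * Zo);
  const double *px = x.begin(); double *py = y.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const double wz1 = wz[oz], wy1 = wy[oy], wx1 = wx[ox];
        double *yp = py + static_cast<R_xlen_t>(C) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
        for (int c = 0; c < C; ++c) {
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int sz = dz ? z1[oz] : z0[oz];
            const double fz = dz ? wz1 : 1.0 - wz1;
            if (fz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int sy = dy ? y1[oy] : y0[oy];
              const double fy = dy ? wy1 : 1.0 - wy1;
              if (fy == 0.0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                const int sx = dx ? x1[ox] : x0[ox];
                const double fx = dx ? wx1 : 1.0 - wx1;
                if (fx == 0.0) continue;
                v += fz * fy * fx * px[c + static_cast<R_xlen_t>(C) * (sx + static_cast<R_xlen_t>(X) * (sy + static_cast<R_xlen_t>(Y) * sz))];
              }
            }
          }
          yp[c] = v;
        }
      }
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector gy, IntegerVector xdim,
                               IntegerVector outdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = outdim[0], Yo = outdim[1], Zo = outdim[2];
  std::vector<int> x0, x1, y0, y1, z0, z1; std::vector<double> wx, wy, wz;
  lin_coeffs(X, Xo, x0, x1, wx);
  lin_coeffs(Y, Yo, y0, y1, wy);
  lin_coeffs(Z, Zo, z0, z1, wz);
  NumericVector gx(static_cast<R_xlen_t>(C) * X * Y * Z);
  const double *pgy = gy.begin(); double *pgx = gx.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const double wz1 = wz[oz], wy1 = wy[oy], wx1 = wx[ox];
        const double *gp = pgy + static_cast<R_xlen_t>(C) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
        for (int dz = 0; dz < 2; ++dz) {
          const int sz = dz ? z1[oz] : z0[oz];
          const double fz = dz ? wz1 : 1.0 - wz1;
          if (fz == 0.0) continue;
          for (int dy = 0; dy < 2; ++dy) {
            const int sy = dy ? y1[oy] : y0[oy];
            const double fy = dy ? wy1 : 1.0 - wy1;
            if (fy == 0.0) continue;
            for (int dx = 0; dx < 2; ++dx) {
              const int sx = dx ? x1[ox] : x0[ox];
              const double fx = dx ? wx1 : 1.0 - wx1;
              if (fx == 0.0) continue;
              double *xp = pgx + static_cast<R_xlen_t>(C) * (sx + static_cast<R_xlen_t>(X) * (sy + static_cast<R_xlen_t>(Y) * sz));
              const double f = fz * fy * fx;
              for (int c = 0; c < C; ++c) xp[c] += f * gp[c];
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

static void neighbour_offsets(int conn, const int dim[3],
                              std::vector<std::array<int,3>> &off,
                              bool forward_only) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && man != 1) continue;
        if (forward_only) {
          // lexicographically positive offsets only (half-neighbourhood)
          if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) continue;
        }
        off.push_back({dx, dy, dz});
      }
}

// Connected components of equal nonzero label under 6- or 26-connectivity.
// Returns a component-id volume (0 = background, ids 1..K in discovery order,
// i.e. ordered by smallest flat voxel index), plus per-component class, size
// and first (smallest) flat voxel index (1-based).
// [[Rcpp::export(name = ".cpp_cclabel")]]
List cpp_cclabel(IntegerVector labels, IntegerVector ldim, int connectivity) {
  const int X = ldim[0], Y = ldim[1], Z = ldim[2];
  const int dim[3] = {X, Y, Z};
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, dim, off, false);
  const R_xlen_t n = labels.size();
  IntegerVector comp(n);
  std::vector<int> cls, sz, first;
  const int *pl = labels.begin(); int *pc = comp.begin();
  std::vector<R_xlen_t> stack;
  int K = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (pl[s] == 0 || pc[s] != 0) continue;
    ++K;
    const int lab = pl[s];
    cls.push_back(lab); sz.push_back(0); first.push_back(static_cast<int>(s + 1));
    stack.clear(); stack.push_back(s); pc[s] = K;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      ++sz[K - 1];
      const int vx = static_cast<int>(v % X);
      const int vy = static_cast<int>((v / X) % Y);
      const int vz = static_cast<int>(v / (static_cast<R_xlen_t>(X) * Y));
      for (size_t k = 0; k < off.size(); ++k) {
        const int nx = vx + off[k][0], ny = vy + off[k][1], nz = vz + off[k][2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const R_xlen_t u = nx + static_cast<R_xlen_t>(X) * (ny + static_cast<R_xlen_t>(Y) * nz);
        if (pc[u] == 0 && pl[u] == lab) { pc[u] = K; stack.push_back(u); }
      }
    }
  }
  comp.attr("dim") = ldim;
  return List::create(_["comp"] = comp,
                      _["class"] = IntegerVector(cls.begin(), cls.end()),
                      _["size"] = IntegerVector(sz.begin(), sz.end()),
                      _["first"] = IntegerVector(first.begin(), first.end()));
}

// Counts of touching voxel pairs between distinct nonzero components.
// [[Rcpp::export(name = ".cpp_adjacency_pairs")]]
List cpp_adjacency_pairs(IntegerVector comp, IntegerVector ldim,
                         int connectivity) {
  const int X = ldim[0], Y = ldim[1], Z = ldim[2];
  const int dim[3] = {X, Y, Z};
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, dim, off, true);
  std::map<std::pair<int,int>, double> counts;
  const int *pc = comp.begin();
  for (int vz = 0; vz < Z; ++vz)
    for (int vy = 0; vy < Y; ++vy)
      for (int vx = 0; vx < X; ++vx) {
        const R_xlen_t v = vx + static_cast<R_xlen_t>(X) * (vy + static_cast<R_xlen_t>(Y) * vz);
        const int a = pc[v];
        if (a == 0) continue;
        for (size_t k = 0; k < off.size(); ++k) {
          const int nx = vx + off[k][0], ny = vy + off[k][1], nz = vz + off[k][2];
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
          const int b = pc[nx + static_cast<R_xlen_t>(X) * (ny + static_cast<R_xlen_t>(Y) * nz)];
          if (b == 0 || b == a) continue;
          const std::pair<int,int> key(std::min(a, b), std::max(a, b));
          counts[key] += 1.0;
        }
      }
  const size_t m = counts.size();
  IntegerVector ca(m), cb(m); NumericVector cn(m);
  size_t i = 0;
  for (std::map<std::pair<int,int>, double>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    ca[i] = it->first.first; cb[i] = it->first.second; cn[i] = it->second;
  }
  return List::create(_["a"] = ca, _["b"] = cb, _["pairs"] = cn);
}
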