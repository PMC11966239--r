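// Hot loops of the differentiable pipeline: multi-resolution hash encoding
// and trilinear interpolation, each with backward (parameter-gradient) and
// position-gradient kernels. Everything operates on coordinates normalized
// to the unit cube; the R layer owns the physical (Angstrom) <-> [0,1]^3 map.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// instant-NGP spatial hash primes (pi_1 = 1 keeps x unmixed on purpose).
static const uint32_t HASH_P2 = 2654435761u;
static const uint32_t HASH_P3 = 805459861u;

// Corner (ix,iy,iz) of level with N cells -> row index of its feature table.
// Dense indexing when the full (N+1)^3 lattice fits in the table, otherwise
// the spatial hash (collisions resolved implicitly by gradient averaging).
static inline uint32_t corner_index(uint32_t ix, uint32_t iy, uint32_t iz,
                                    uint32_t nverts, uint32_t tsize) {
  uint64_t dense = (uint64_t)nverts * nverts * nverts;
  if (dense <= (uint64_t)tsize) {
    return ix + nverts * (iy + nverts * iz);
  }
  uint32_t h = ix ^ (iy * HASH_P2) ^ (iz * HASH_P3);
  return h % tsize;
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// points: K x 3 in [0,1]^3 (clamped here); resolutions: per-level cell
// counts N_l; tables: list of (T_l x F) feature matrices.
// Returns K x (L*F) features, level blocks concatenated in order.
// [[Rcpp::export]]
NumericMatrix cpp_hash_encode(NumericMatrix points, IntegerVector resolutions,
                              List tables) {
  const int K = points.nrow();
  const int L = resolutions.size();
  NumericMatrix tab0 = tables[0];
  const int F = tab0.ncol();
  NumericMatrix out(K, L * F);

  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    const uint32_t N = (uint32_t)resolutions[l];
    const uint32_t nverts = N + 1;
    const uint32_t tsize = (uint32_t)tab.nrow();
    for (int k = 0; k < K; ++k) {
      double px = clamp01(points(k, 0)) * N;
      double py = clamp01(points(k, 1)) * N;
      double pz = clamp01(points(k, 2)) * N;
      uint32_t ix = (uint32_t)std::min((double)(N - 1), std::floor(px));
      uint32_t iy = (uint32_t)std::min((double)(N - 1), std::floor(py));
      uint32_t iz = (uint32_t)std::min((double)(N - 1), std::floor(pz));
      double fx = px - ix, fy = py - iy, fz = pz - iz;
      for (int c = 0; c < 8; ++c) {
        uint32_t dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        if (w == 0.0) continue;
        uint32_t row = corner_index(ix + dx, iy + dy, iz + dz, nverts, tsize);
        for (int f = 0; f < F; ++f)
          out(k, l * F + f) += w * tab(row, f);
      }
    }
  }
  return out;
}

// Gradient of the features w.r.t. the table entries: scatters grad_feats
// (K x L*F) into per-level (T_l x F) matrices with the trilinear weights.
// [[Rcpp::export]]
List cpp_hash_encode_backward(NumericMatrix points, IntegerVector resolutions,
                              List tables, NumericMatrix grad_feats) {
  const int K = points.nrow();
  const int L = resolutions.size();
  NumericMatrix tab0 = tables[0];
  const int F = tab0.ncol();
  List grads(L);

  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    const uint32_t N = (uint32_t)resolutions[l];
    const uint32_t nverts = N + 1;
    const uint32_t tsize = (uint32_t)tab.nrow();
    NumericMatrix g(tsize, F);
    for (int k = 0; k < K; ++k) {
      double px = clamp01(points(k, 0)) * N;
      double py = clamp01(points(k, 1)) * N;
      double pz = clamp01(points(k, 2)) * N;
      uint32_t ix = (uint32_t)std::min((double)(N - 1), std::floor(px));
      uint32_t iy = (uint32_t)std::min((double)(N - 1), std::floor(py));
      uint32_t iz = (uint32_t)std::min((double)(N - 1), std::floor(pz));
      double fx = px - ix, fy = py - iy, fz = pz - iz;
      for (int c = 0; c < 8; ++c) {
        uint32_t dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        if (w == 0.0) continue;
        uint32_t row = corner_index(ix + dx, iy + dy, iz + dz, nverts, tsize);
        for (int f = 0; f < F; ++f)
          g(row, f) += w * grad_feats(k, l * F + f);
      }
    }
    grads[l] = g;
  }
  return grads;
}

// Chain rule to the (normalized) input coordinates:
// returns K x 3 with sum_{l,f} grad_feats[k, lf] * d feat / d u.
// The derivative of the clamp is taken as zero outside [0,1].
// [[Rcpp::export]]
NumericMatrix cpp_hash_encode_posgrad(NumericMatrix points,
                                      IntegerVector resolutions, List tables,
                                      NumericMatrix grad_feats) {
  const int K = points.nrow();
  const int L = resolutions.size();
  NumericMatrix tab0 = tables[0];
  const int F = tab0.ncol();
  NumericMatrix out(K, 3);

  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    const uint32_t N = (uint32_t)resolutions[l];
    const uint32_t nverts = N + 1;
    const uint32_t tsize = (uint32_t)tab.nrow();
    for (int k = 0; k < K; ++k) {
      double ux = points(k, 0), uy = points(k, 1), uz = points(k, 2);
      bool inx = (ux > 0.0 && ux < 1.0), iny = (uy > 0.0 && uy < 1.0),
           inz = (uz > 0.0 && uz < 1.0);
      double px = clamp01(ux) * N, py = clamp01(uy) * N, pz = clamp01(uz) * N;
      uint32_t ix = (uint32_t)std::min((double)(N - 1), std::floor(px));
      uint32_t iy = (uint32_t)std::min((double)(N - 1), std::floor(py));
      uint32_t iz = (uint32_t)std::min((double)(N - 1), std::floor(pz));
      double fx = px - ix, fy = py - iy, fz = pz - iz;
      for (int c = 0; c < 8; ++c) {
        uint32_t dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
        double wx = dx ? fx : 1.0 - fx;
        double wy = dy ? fy : 1.0 - fy;
        double wz = dz ? fz : 1.0 - fz;
        double sx = dx ? 1.0 : -1.0, sy = dy ? 1.0 : -1.0,
               sz = dz ? 1.0 : -1.0;
        uint32_t row = corner_index(ix + dx, iy + dy, iz + dz, nverts, tsize);
        double dot = 0.0;
        for (int f = 0; f < F; ++f)
          dot += tab(row, f) * grad_feats(k, l * F + f);
        // d w / d u = N * d w / d p (p = u * N)
        if (inx) out(k, 0) += dot * sx * wy * wz * N;
        if (iny) out(k, 1) += dot * wx * sy * wz * N;
        if (inz) out(k, 2) += dot * wx * wy * sz * N;
      }
    }
  }
  return out;
}

// ---- trilinear interpolation into a (n1,n2,n3,C) array --------------------
// Voxel centers sit at u = (i + 0.5)/n per axis. mode 0: values outside the
// array are zero; mode 1: indices clamp to the border (edge extension).

struct TriCtx {
  int n1, n2, n3, C;
  const double *vol;
};

static inline bool corner_ok(int i, int n, int mode, int &ic) {
  if (i < 0 || i >= n) {
    if (mode == 0) return false;
    ic = i < 0 ? 0 : n - 1;
  } else {
    ic = i;
  }
  return true;
}

// points: K x 3 normalized [0,1]; vol: numeric vector, column-major
// (n1,n2,n3,C). Returns K x C.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear(NumericMatrix points, NumericVector vol,
                            IntegerVector dims, int mode) {
  const int K = points.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const double *v = vol.begin();
  NumericMatrix out(K, C);
  const R_xlen_t chan = (R_xlen_t)n1 * n2 * n3;

  for (int k = 0; k < K; ++k) {
    double px = points(k, 0) * n1 - 0.5;
    double py = points(k, 1) * n2 - 0.5;
    double pz = points(k, 2) * n3 - 0.5;
    int ix = (int)std::floor(px), iy = (int)std::floor(py),
        iz = (int)std::floor(pz);
    double fx = px - ix, fy = py - iy, fz = pz - iz;
    for (int c8 = 0; c8 < 8; ++c8) {
      int dx = c8 & 1, dy = (c8 >> 1) & 1, dz = (c8 >> 2) & 1;
      double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                 (dz ? fz : 1.0 - fz);
      if (w == 0.0) continue;
      int cx, cy, cz;
      if (!corner_ok(ix + dx, n1, mode, cx)) continue;
      if (!corner_ok(iy + dy, n2, mode, cy)) continue;
      if (!corner_ok(iz + dz, n3, mode, cz)) continue;
      R_xlen_t base = cx + (R_xlen_t)n1 * (cy + (R_xlen_t)n2 * cz);
      for (int ch = 0; ch < C; ++ch)
        out(k, ch) += w * v[base + chan * ch];
    }
  }
  return out;
}

// Scatter of grad_out (K x C) back into an array-shaped gradient.
// [[Rcpp::export]]
NumericVector cpp_trilinear_backward(NumericMatrix points,
                                     IntegerVector dims, int mode,
                                     NumericMatrix grad_out) {
  const int K = points.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const R_xlen_t chan = (R_xlen_t)n1 * n2 * n3;
  NumericVector g(chan * C);

  for (int k = 0; k < K; ++k) {
    double px = points(k, 0) * n1 - 0.5;
    double py = points(k, 1) * n2 - 0.5;
    double pz = points(k, 2) * n3 - 0.5;
    int ix = (int)std::floor(px), iy = (int)std::floor(py),
        iz = (int)std::floor(pz);
    double fx = px - ix, fy = py - iy, fz = pz - iz;
    for (int c8 = 0; c8 < 8; ++c8) {
      int dx = c8 & 1, dy = (c8 >> 1) & 1, dz = (c8 >> 2) & 1;
      double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                 (dz ? fz : 1.0 - fz);
      if (w == 0.0) continue;
      int cx, cy, cz;
      if (!corner_ok(ix + dx, n1, mode, cx)) continue;
      if (!corner_ok(iy + dy, n2, mode, cy)) continue;
      if (!corner_ok(iz + dz, n3, mode, cz)) continue;
      R_xlen_t base = cx + (R_xlen_t)n1 * (cy + (R_xlen_t)n2 * cz);
      for (int ch = 0; ch < C; ++ch)
        g[base + chan * ch] += w * grad_out(k, ch);
    }
  }
  return g;
}

// Gradient w.r.t. the normalized query positions (K x 3), summed over
// channels with grad_out weights.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_posgrad(NumericMatrix points, NumericVector vol,
                                    IntegerVector dims, int mode,
                                    NumericMatrix grad_out) {
  const int K = points.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const double *v = vol.begin();
  const R_xlen_t chan = (R_xlen_t)n1 * n2 * n3;
  NumericMatrix out(K, 3);

  for (int k = 0; k < K; ++k) {
    double px = points(k, 0) * n1 - 0.5;
    double py = points(k, 1) * n2 - 0.5;
    double pz = points(k, 2) * n3 - 0.5;
    int ix = (int)std::floor(px), iy = (int)std::floor(py),
        iz = (int)std::floor(pz);
    double fx = px - ix, fy = py - iy, fz = pz - iz;
    for (int c8 = 0; c8 < 8; ++c8) {
      int dx = c8 & 1, dy = (c8 >> 1) & 1, dz = (c8 >> 2) & 1;
      double wx = dx ? fx : 1.0 - fx;
      double wy = dy ? fy : 1.0 - fy;
      double wz = dz ? fz : 1.0 - fz;
      double sx = dx ? 1.0 : -1.0, sy = dy ? 1.0 : -1.0, sz = dz ? 1.0 : -1.0;
      int cx, cy, cz;
      if (!corner_ok(ix + dx, n1, mode, cx)) continue;
      if (!corner_ok(iy + dy, n2, mode, cy)) continue;
      if (!corner_ok(iz + dz, n3, mode, cz)) continue;
      R_xlen_t base = cx + (R_xlen_t)n1 * (cy + (R_xlen_t)n2 * cz);
      double dot = 0.0;
      for (int ch = 0; ch < C; ++ch)
        dot += v[base + chan * ch] * grad_out(k, ch);
      out(k, 0) += dot * sx * wy * wz * n1;
      out(k, 1) += dot * wx * sy * wz * n2;
      out(k, 2) += dot * wx * wy * sz * n3;
    }
  }
  return out;
}
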