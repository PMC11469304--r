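#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// 3D box-neighborhood median filter with clamped (replicated) borders.
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector x, IntegerVector dims, int radius) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  if (radius <= 0) { std::copy(x.begin(), x.end(), out.begin()); return out; }
  const int w = 2 * radius + 1;
  std::vector<double> buf((size_t)w * w * w);
  const double* X = REAL(x);
  double* O = REAL(out);
  for (int z = 0; z < n3; z++)
    for (int y = 0; y < n2; y++)
      for (int xx = 0; xx < n1; xx++) {
        size_t m = 0;
        for (int c = -radius; c <= radius; c++) {
          int zz = clampi(z + c, 0, n3 - 1);
          for (int b = -radius; b <= radius; b++) {
            int yy = clampi(y + b, 0, n2 - 1);
            R_xlen_t base = (R_xlen_t)zz * n1 * n2 + (R_xlen_t)yy * n1;
            for (int a = -radius; a <= radius; a++)
              buf[m++] = X[base + clampi(xx + a, 0, n1 - 1)];
          }
        }
        size_t mid = m / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
        O[(R_xlen_t)z * n1 * n2 + (R_xlen_t)y * n1 + xx] = buf[mid];
      }
  return out;
}

static void conv1d_axis(double* D, int n1, int n2, int n3,
                        const std::vector<double>& k, int axis) {
  int h = ((int)k.size() - 1) / 2;
  int len = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? n1 : (R_xlen_t)n1 * n2);
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  R_xlen_t nlines = ((R_xlen_t)n1 * n2 * n3) / len;
  for (R_xlen_t li = 0; li < nlines; li++) {
    // compute base index of this line
    R_xlen_t base;
    if (axis == 0) {
      base = li * n1;
    } else if (axis == 1) {
      R_xlen_t z = li / n1, x = li % n1;
      base = z * (R_xlen_t)n1 * n2 + x;
    } else {
      base = li;
    }
    for (int i = 0; i < len; i++) line[i] = D[base + (R_xlen_t)i * stride];
    for (int i = 0; i < len; i++) {
      double acc = 0.0;
      for (int j = -h; j <= h; j++)
        acc += k[j + h] * line[clampi(i + j, 0, len - 1)];
      D[base + (R_xlen_t)i * stride] = acc;
    }
  }
}

// Separable 3D Gaussian smoothing (sigma in voxels, replicated borders).
// [[Rcpp::export]]
NumericVector gaussian3d_cpp(NumericVector x, IntegerVector dims,
                             double sigma) {
  NumericVector out = clone(x);
  if (sigma <= 0) return out;
  int h = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int j = -h; j <= h; j++) {
    k[j + h] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += k[j + h];
  }
  for (double& v : k) v /= s;
  conv1d_axis(REAL(out), dims[0], dims[1], dims[2], k, 0);
  conv1d_axis(REAL(out), dims[0], dims[1], dims[2], k, 1);
  conv1d_axis(REAL(out), dims[0], dims[1], dims[2], k, 2);
  return out;
}

// Binary dilation (op = 0) or erosion (op = 1) with the Euclidean ball of
// radius 1 voxel (6-neighborhood cross) applied `iter` times.
// [[Rcpp::export]]
LogicalVector morph3d_cpp(LogicalVector mask, IntegerVector dims, int op,
                          int iter) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; i++) cur[i] = mask[i] ? 1 : 0;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (int it = 0; it < iter; it++) {
    for (int z = 0; z < n3; z++)
      for (int y = 0; y < n2; y++)
        for (int x = 0; x < n1; x++) {
          R_xlen_t idx = (R_xlen_t)z * n1 * n2 + (R_xlen_t)y * n1 + x;
          char v = cur[idx];
          for (int q = 0; q < 6 && ((op == 0 && !v) || (op == 1 && v)); q++) {
            int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
            if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 ||
                zz >= n3)
              continue;  // outside: background for dilation, foreground for
                         // erosion, so closing never eats the volume faces
            char w = cur[(R_xlen_t)zz * n1 * n2 + (R_xlen_t)yy * n1 + xx];
            if (op == 0 && w) v = 1;
            if (op == 1 && !w) v = 0;
          }
          nxt[idx] = v;
        }
    std::swap(cur, nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = cur[i] != 0;
  return out;
}
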