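#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Squared 1D distance transform (lower envelope of parabolas).
// f: input squared distances along the line, d: output. Felzenszwalb &
// Huttenlocher's linear-time algorithm; exact for arbitrary seed costs.
static void dt1d(const double* f, double* d, int* v, double* z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D mask, in voxel units.
// Returns, for every voxel, the distance from its center to the center of
// the nearest TRUE voxel. Seeds must be finite in number (> 0).
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double BIG = 1e15;  // larger than any attainable squared distance
  NumericVector out(n);
  double* D = REAL(out);
  for (R_xlen_t i = 0; i < n; i++) D[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (R_xlen_t off = 0; off < n; off += n1) {
    dt1d(D + off, d.data(), v.data(), z.data(), n1);
    std::copy(d.begin(), d.begin() + n1, D + off);
  }
  // pass along axis 2 (stride n1)
  for (int k = 0; k < n3; k++) {
    R_xlen_t base = (R_xlen_t)k * n1 * n2;
    for (int i = 0; i < n1; i++) {
      for (int j = 0; j < n2; j++) f[j] = D[base + (R_xlen_t)j * n1 + i];
      dt1d(f.data(), d.data(), v.data(), z.data(), n2);
      for (int j = 0; j < n2; j++) D[base + (R_xlen_t)j * n1 + i] = d[j];
    }
  }
  // pass along axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t ij = 0; ij < s3; ij++) {
    for (int k = 0; k < n3; k++) f[k] = D[ij + (R_xlen_t)k * s3];
    dt1d(f.data(), d.data(), v.data(), z.data(), n3);
    for (int k = 0; k < n3; k++) D[ij + (R_xlen_t)k * s3] = d[k];
  }

  for (R_xlen_t i = 0; i < n; i++) D[i] = std::sqrt(D[i]);
  return out;
}
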