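#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D mask under 6- or 26-connectivity.
// Labels are assigned in raster-scan discovery order starting at 1.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(n);
  int* lab = INTEGER(out);
  for (R_xlen_t i = 0; i < n; i++) lab[i] = 0;

  // neighbor offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nb = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; start++) {
    if (!mask[start] || lab[start] != 0) continue;
    next++;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % n1);
      int y = (int)((cur / n1) % n2);
      int z = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int q = 0; q < nb; q++) {
        int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * n1 * n2 + (R_xlen_t)yy * n1 + xx;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return out;
}
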