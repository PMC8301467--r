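#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Trilinear sampling of a 3D array at fractional voxel coordinates.
// coords are 0-based voxel indices (n x 3). Points outside the grid get
// `background`. Array is in R's column-major layout with dims d0,d1,d2.
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector arr, IntegerVector dim,
                                   NumericMatrix coords, double background) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *a = REAL(arr);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < 0 || y < 0 || z < 0 ||
        x > d0 - 1 || y > d1 - 1 || z > d2 - 1) {
      out[k] = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == d0 - 1) i0--;
    if (j0 == d1 - 1) j0--;
    if (k0 == d2 - 1) k0--;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
    const R_xlen_t base = i0 + (R_xlen_t)j0 * s1 + (R_xlen_t)k0 * s2;
    double c000 = a[base],          c100 = a[base + 1];
    double c010 = a[base + s1],     c110 = a[base + 1 + s1];
    double c001 = a[base + s2],     c101 = a[base + 1 + s2];
    double c011 = a[base + s1 + s2], c111 = a[base + 1 + s1 + s2];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling, same conventions as cpp_trilinear_sample.
// [[Rcpp::export]]
NumericVector cpp_nearest_sample(NumericVector arr, IntegerVector dim,
                                 NumericMatrix coords, double background) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *a = REAL(arr);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y), l = (int)std::lround(z);
    if (ISNAN(x) || i < 0 || j < 0 || l < 0 || i >= d0 || j >= d1 || l >= d2) {
      out[k] = background;
      continue;
    }
    out[k] = a[i + (R_xlen_t)j * d0 + (R_xlen_t)l * d0 * d1];
  }
  return out;
}

// 6-connected component labelling of a logical 3D mask (BFS flood fill).
// Returns an integer array: 0 outside the mask, 1..k component ids.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  const int *m = LOGICAL(mask);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (m[start] != 1 || lab[start] != 0) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int i = (int)(v % d0);
      int j = (int)((v / d0) % d1);
      int k = (int)(v / s2);
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0) nb[nn++] = v - 1;
      if (i < d0 - 1) nb[nn++] = v + 1;
      if (j > 0) nb[nn++] = v - s1;
      if (j < d1 - 1) nb[nn++] = v + s1;
      if (k > 0) nb[nn++] = v - s2;
      if (k < d2 - 1) nb[nn++] = v + s2;
      for (int t = 0; t < nn; ++t) {
        R_xlen_t w = nb[t];
        if (m[w] == 1 && lab[w] == 0) {
          lab[w] = next;
          q.push(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
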