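#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact 1D squared distance transform of a sampled function
// (Felzenszwalb & Huttenlocher, lower envelope of parabolas), with a
// per-axis squared grid step w2 so the 3-pass composition yields the
// exact anisotropic Euclidean distance between voxel centers.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + w2 * q * q;
    double s = 0.0;
    while (true) {
      double fv = f[v[k]] + w2 * v[k] * v[k];
      s = (fq - fv) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Squared anisotropic Euclidean distance from every voxel center to the
// nearest TRUE voxel center. dims = c(n1, n2, n3) with the first index
// fastest-varying (R column-major); spacing aligned with dims, in nm.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != N) stop("mask length does not match dims");
  const double BIG = 1e30;

  // work in a raw buffer: SEXP-backed element access in the strided
  // passes defeats optimization
  std::vector<double> g(N);
  for (R_xlen_t i = 0; i < N; ++i) g[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  {
    const double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < n3; ++k) {
      for (int j = 0; j < n2; ++j) {
        R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        for (int i = 0; i < n1; ++i) f[i] = g[base + i];
        dt1d(f, d, v, z, n1, w2);
        for (int i = 0; i < n1; ++i) g[base + i] = d[i];
      }
    }
  }
  // axis 2 (stride n1)
  {
    const double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < n3; ++k) {
      for (int i = 0; i < n1; ++i) {
        R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
        for (int j = 0; j < n2; ++j) f[j] = g[base + (R_xlen_t)n1 * j];
        dt1d(f, d, v, z, n2, w2);
        for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)n1 * j] = d[j];
      }
    }
  }
  // axis 3 (stride n1*n2)
  {
    const double w2 = spacing[2] * spacing[2];
    const R_xlen_t s3 = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        R_xlen_t base = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; ++k) f[k] = g[base + s3 * k];
        dt1d(f, d, v, z, n3, w2);
        for (int k = 0; k < n3; ++k) g[base + s3 * k] = d[k];
      }
    }
  }
  NumericVector out(N);
  std::copy(g.begin(), g.end(), out.begin());
  return out;
}
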