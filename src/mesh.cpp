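#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Marching tetrahedra over the voxel-center lattice. Each cell between 8
// neighboring voxel centers is split into 6 tetrahedra sharing the main
// diagonal; the level surface is linearly interpolated along tet edges.
// Produces a triangle soup: n x 9 matrix (a1,a2,a3, b1,b2,b3, c1,c2,c3)
// of vertex coordinates in nm, axis order matching dims. Voxel (i,j,k)
// (0-based) has center ((i+0.5)*sp1, (j+0.5)*sp2, (k+0.5)*sp3).
//
// Tet decomposition: cube corner index = bit0*axis1 + bit1*axis2 + bit2*axis3,
// all tets share the 0-7 diagonal.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
NumericMatrix mtetra_cpp(NumericVector field, IntegerVector dims,
                         NumericVector spacing, double level) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (field.size() != N) stop("field length does not match dims");
  const double* F = field.begin();
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];

  std::vector<double> tri; // flat triples of triples
  double cpos[8][3];
  double cval[8];

  for (int k = 0; k + 1 < n3; ++k) {
    for (int j = 0; j + 1 < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i + 1 < n1; ++i) {
        // gather cube corners
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          R_xlen_t idx = base + i + di + (R_xlen_t)n1 * (dj + (R_xlen_t)n2 * dk);
          double fv = F[idx];
          cval[c] = fv;
          cpos[c][0] = (i + di + 0.5) * s1;
          cpos[c][1] = (j + dj + 0.5) * s2;
          cpos[c][2] = (k + dk + 0.5) * s3;
          if (fv < level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int a[4];
          int nin = 0;
          int ins[4], outs[4];
          int nout = 0;
          for (int m = 0; m < 4; ++m) {
            a[m] = TETS[t][m];
            if (cval[a[m]] < level) ins[nin++] = a[m];
            else outs[nout++] = a[m];
          }
          if (nin == 0 || nin == 4) continue;

          // edge intersection helper
          auto emit_point = [&](int p, int q, double* out) {
            double fp = cval[p], fq = cval[q];
            double tt = (level - fp) / (fq - fp);
            for (int d = 0; d < 3; ++d)
              out[d] = cpos[p][d] + tt * (cpos[q][d] - cpos[p][d]);
          };

          double P[4][3];
          if (nin == 1 || nin == 3) {
            int lone = (nin == 1) ? ins[0] : outs[0];
            int* oth = (nin == 1) ? outs : ins;
            for (int m = 0; m < 3; ++m) emit_point(lone, oth[m], P[m]);
            for (int m = 0; m < 3; ++m)
              for (int d = 0; d < 3; ++d) tri.push_back(P[m][d]);
          } else { // 2-2 case: quad
            emit_point(ins[0], outs[0], P[0]);
            emit_point(ins[0], outs[1], P[1]);
            emit_point(ins[1], outs[1], P[2]);
            emit_point(ins[1], outs[0], P[3]);
            const int quad[2][3] = {{0, 1, 2}, {0, 2, 3}};
            for (int q = 0; q < 2; ++q)
              for (int m = 0; m < 3; ++m)
                for (int d = 0; d < 3; ++d) tri.push_back(P[quad[q][m]][d]);
          }
        }
      }
    }
  }

  R_xlen_t ntri = (R_xlen_t)tri.size() / 9;
  NumericMatrix out(ntri, 9);
  for (R_xlen_t r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tri[r * 9 + c];
  return out;
}

// Trilinear interpolation of a scalar field (voxel-center samples) at
// arbitrary points given in nm, axis order matching dims. Points outside
// the center lattice are clamped to it.
// [[Rcpp::export]]
NumericVector interp_trilinear_cpp(NumericVector field, IntegerVector dims,
                                   NumericVector spacing, NumericMatrix pts) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (field.size() != N) stop("field length does not match dims");
  const double* F = field.begin();
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);

  for (R_xlen_t p = 0; p < np; ++p) {
    double u[3];
    u[0] = pts(p, 0) / spacing[0] - 0.5;
    u[1] = pts(p, 1) / spacing[1] - 0.5;
    u[2] = pts(p, 2) / spacing[2] - 0.5;
    int i0[3];
    double fr[3];
    int nn[3] = {n1, n2, n3};
    for (int d = 0; d < 3; ++d) {
      if (u[d] < 0) u[d] = 0;
      if (u[d] > nn[d] - 1) u[d] = nn[d] - 1;
      i0[d] = (int)std::floor(u[d]);
      if (i0[d] > nn[d] - 2) i0[d] = nn[d] - 2;
      if (i0[d] < 0) i0[d] = 0;
      fr[d] = u[d] - i0[d];
      if (nn[d] == 1) { i0[d] = 0; fr[d] = 0.0; }
    }
    double acc = 0.0;
    for (int c = 0; c < 8; ++c) {
      int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
      int ii = i0[0] + (n1 > 1 ? di : 0);
      int jj = i0[1] + (n2 > 1 ? dj : 0);
      int kk = i0[2] + (n3 > 1 ? dk : 0);
      double w = (di ? fr[0] : 1 - fr[0]) *
                 (dj ? fr[1] : 1 - fr[1]) *
                 (dk ? fr[2] : 1 - fr[2]);
      if (w == 0.0) continue;
      acc += w * F[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
    }
    out[p] = acc;
  }
  return out;
}
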