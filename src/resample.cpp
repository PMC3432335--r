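#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at continuous 1-based voxel
// coordinates. Coordinates outside [1, dim] take `fill` and are flagged
// invalid so similarity metrics can exclude them.
// [[Rcpp::export]]
List trilinear_sample(NumericVector vol, IntegerVector dims,
                      NumericMatrix coords, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  const double *v = REAL(vol);

  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!(x >= 1.0 && x <= nx && y >= 1.0 && y <= ny && z >= 1.0 && z <= nz)) {
      out[p] = fill;
      inside[p] = false;
      continue;
    }
    int i0 = (int)std::floor(x) - 1;
    int j0 = (int)std::floor(y) - 1;
    int k0 = (int)std::floor(z) - 1;
    if (i0 > nx - 2) i0 = nx - 2;  // exact upper boundary
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    if (i0 < 0) i0 = 0;  // degenerate single-slab axes
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    const int i1 = (nx > 1) ? i0 + 1 : i0;
    const int j1 = (ny > 1) ? j0 + 1 : j0;
    const int k1 = (nz > 1) ? k0 + 1 : k0;
    const double fx = x - 1.0 - i0, fy = y - 1.0 - j0, fz = z - 1.0 - k0;

    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    #define V(i, j, k) v[(R_xlen_t)(i) + (R_xlen_t)nx * (j) + sxy * (k)]
    const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
    #undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
    inside[p] = true;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}
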