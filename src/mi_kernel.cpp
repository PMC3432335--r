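#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fused registration objective: map every fixed-grid voxel center through a
// rigid transform (rotation matrix + offset, world space), sample the moving
// volume trilinearly, bin the paired intensities against precomputed fixed
// bins, and return the plug-in mutual information (bits) of the overlap.
// Voxels mapped outside the moving volume are excluded. Returns MI = 0 when
// nothing overlaps.
// [[Rcpp::export]]
List mi_rigid_kernel(NumericVector moving, IntegerVector mdim,
                     NumericVector morigin, NumericVector mspacing,
                     IntegerVector fdim, NumericVector forigin,
                     NumericVector fspacing, IntegerVector fixed_bins,
                     NumericMatrix R, NumericVector offset, int bins,
                     double mlo, double mwidth) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double *v = REAL(moving);
  const int *fb = INTEGER(fixed_bins);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  const double r11 = R(0, 0), r12 = R(0, 1), r13 = R(0, 2);
  const double r21 = R(1, 0), r22 = R(1, 1), r23 = R(1, 2);
  const double r31 = R(2, 0), r32 = R(2, 1), r33 = R(2, 2);
  const double ox = offset[0], oy = offset[1], oz = offset[2];

  std::vector<double> counts((size_t)bins * bins, 0.0);
  R_xlen_t n = 0, p = 0;

  for (int kk = 0; kk < fz; ++kk) {
    const double wz = forigin[2] + kk * fspacing[2];
    for (int jj = 0; jj < fy; ++jj) {
      const double wy = forigin[1] + jj * fspacing[1];
      for (int ii = 0; ii < fx; ++ii, ++p) {
        const double wx = forigin[0] + ii * fspacing[0];
        // world -> moving world -> continuous 0-based moving voxel coords
        const double mx = (r11 * wx + r12 * wy + r13 * wz + ox - morigin[0]) / mspacing[0];
        const double my = (r21 * wx + r22 * wy + r23 * wz + oy - morigin[1]) / mspacing[1];
        const double mz = (r31 * wx + r32 * wy + r33 * wz + oz - morigin[2]) / mspacing[2];
        if (!(mx >= 0.0 && mx <= nx - 1 && my >= 0.0 && my <= ny - 1 &&
              mz >= 0.0 && mz <= nz - 1)) {
          continue;
        }
        int i0 = (int)mx, j0 = (int)my, k0 = (int)mz;
        if (i0 > nx - 2) i0 = nx - 2;
        if (j0 > ny - 2) j0 = ny - 2;
        if (k0 > nz - 2) k0 = nz - 2;
        if (i0 < 0) i0 = 0;
        if (j0 < 0) j0 = 0;
        if (k0 < 0) k0 = 0;
        const int i1 = (nx > 1) ? i0 + 1 : i0;
        const int j1 = (ny > 1) ? j0 + 1 : j0;
        const int k1 = (nz > 1) ? k0 + 1 : k0;
        const double fxw = mx - i0, fyw = my - j0, fzw = mz - k0;
        #define V(i, j, k) v[(R_xlen_t)(i) + (R_xlen_t)nx * (j) + sxy * (k)]
        const double c00 = V(i0, j0, k0) * (1 - fxw) + V(i1, j0, k0) * fxw;
        const double c10 = V(i0, j1, k0) * (1 - fxw) + V(i1, j1, k0) * fxw;
        const double c01 = V(i0, j0, k1) * (1 - fxw) + V(i1, j0, k1) * fxw;
        const double c11 = V(i0, j1, k1) * (1 - fxw) + V(i1, j1, k1) * fxw;
        #undef V
        const double c0 = c00 * (1 - fyw) + c10 * fyw;
        const double c1 = c01 * (1 - fyw) + c11 * fyw;
        const double val = c0 * (1 - fzw) + c1 * fzw;

        // same operation order as the R binning path: ((x - lo) / w) * bins
        int ib = (mwidth > 0) ? (int)std::floor((val - mlo) / mwidth * bins) : 0;
        if (ib < 0) ib = 0;
        if (ib >= bins) ib = bins - 1;
        const int ia = fb[p] - 1;  // 1-based from R
        counts[(size_t)ia + (size_t)bins * ib] += 1.0;
        ++n;
      }
    }
  }
  if (n == 0) {
    return List::create(_["mi"] = 0.0, _["n"] = 0.0);
  }
  // plug-in entropies in bits
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  double h_joint = 0.0;
  const double inv_n = 1.0 / (double)n;
  const double log2e = 1.0 / std::log(2.0);
  for (int b = 0; b < bins; ++b) {
    for (int a = 0; a < bins; ++a) {
      const double c = counts[(size_t)a + (size_t)bins * b];
      if (c > 0) {
        const double pr = c * inv_n;
        h_joint -= pr * std::log(pr) * log2e;
        pa[a] += pr;
        pb[b] += pr;
      }
    }
  }
  double h_a = 0.0, h_b = 0.0;
  for (int a = 0; a < bins; ++a) {
    if (pa[a] > 0) h_a -= pa[a] * std::log(pa[a]) * log2e;
  }
  for (int b = 0; b < bins; ++b) {
    if (pb[b] > 0) h_b -= pb[b] * std::log(pb[b]) * log2e;
  }
  double mi = h_a + h_b - h_joint;
  if (mi < 0) mi = 0;
  return List::create(_["mi"] = mi, _["n"] = (double)n);
}
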