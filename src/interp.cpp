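#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a multi-channel 3D grid at arbitrary continuous
// positions (1-based voxel coordinates), with clamp-to-edge boundary handling.
// `field` is the column-major data of an (nx, ny, nz, ncomp) array; positions
// outside the grid are clamped onto its boundary faces before interpolation.
// [[Rcpp::export]]
NumericMatrix cpp_sample_trilinear(NumericVector field, IntegerVector dim,
                                   int ncomp, NumericVector px,
                                   NumericVector py, NumericVector pz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = px.size();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, ncomp);
  const double *f = REAL(field);

  for (R_xlen_t i = 0; i < n; ++i) {
    double x = px[i] - 1.0, y = py[i] - 1.0, z = pz[i] - 1.0;  // 0-based
    if (x < 0.0) x = 0.0; else if (x > nx - 1.0) x = nx - 1.0;
    if (y < 0.0) y = 0.0; else if (y > ny - 1.0) y = ny - 1.0;
    if (z < 0.0) z = 0.0; else if (z > nz - 1.0) z = nz - 1.0;

    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
    if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
    if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
    const int x1 = nx > 1 ? x0 + 1 : x0;
    const int y1 = ny > 1 ? y0 + 1 : y0;
    const int z1 = nz > 1 ? z0 + 1 : z0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;

    const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    const double w100 = fx * (1 - fy) * (1 - fz);
    const double w010 = (1 - fx) * fy * (1 - fz);
    const double w110 = fx * fy * (1 - fz);
    const double w001 = (1 - fx) * (1 - fy) * fz;
    const double w101 = fx * (1 - fy) * fz;
    const double w011 = (1 - fx) * fy * fz;
    const double w111 = fx * fy * fz;

    const R_xlen_t i000 = x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    const R_xlen_t i100 = x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    const R_xlen_t i010 = x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0);
    const R_xlen_t i110 = x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z0);
    const R_xlen_t i001 = x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1);
    const R_xlen_t i101 = x1 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z1);
    const R_xlen_t i011 = x0 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1);
    const R_xlen_t i111 = x1 + (R_xlen_t)nx * (y1 + (R_xlen_t)ny * z1);

    for (int c = 0; c < ncomp; ++c) {
      const double *fc = f + (R_xlen_t)c * nvox;
      out(i, c) = w000 * fc[i000] + w100 * fc[i100] + w010 * fc[i010] +
                  w110 * fc[i110] + w001 * fc[i001] + w101 * fc[i101] +
                  w011 * fc[i011] + w111 * fc[i111];
    }
  }
  return out;
}

// Sample a multi-channel grid at (identity + displacement): the workhorse for
// warping and composition. `disp` holds three displacement channels on the
// same grid (voxel units).
// [[Rcpp::export]]
NumericMatrix cpp_sample_displaced(NumericVector field, IntegerVector dim,
                                   int ncomp, NumericVector disp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector px(nvox), py(nvox), pz(nvox);
  const double *d = REAL(disp);
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        px[i] = x + 1.0 + d[i];
        py[i] = y + 1.0 + d[i + nvox];
        pz[i] = z + 1.0 + d[i + 2 * nvox];
      }
  return cpp_sample_trilinear(field, dim, ncomp, px, py, pz);
}
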