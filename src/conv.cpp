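#include <Rcpp.h>
using namespace Rcpp;

// Separable zero-padded convolution of a 3D field with an odd, centred 1D
// kernel, applied along each axis in turn. Values outside the grid are
// treated as zero, which is the "temporarily padded with zeros" boundary of
// the diffusion step; mass leaks through the boundary accordingly.
//
// x is the field in R's column-major layout (first index fastest).
// [[Rcpp::export]]
NumericVector conv3d_separable(NumericVector x, IntegerVector dim,
                               NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int R = (klen - 1) / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("field length does not match dim");
  if (klen % 2 == 0) stop("kernel length must be odd");

  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(n, 0.0);
  const double *k = REAL(kernel);

  // axis 0 (fastest stride)
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = ((R_xlen_t)z * ny + y) * nx;
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        const int j0 = std::max(-R, -i), j1 = std::min(R, nx - 1 - i);
        for (int j = j0; j <= j1; ++j) s += a[base + i + j] * k[j + R];
        b[base + i] = s;
      }
    }
  }
  a.swap(b);

  // axis 1
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = ((R_xlen_t)z * ny + y) * nx;
      const int j0 = std::max(-R, -y), j1 = std::min(R, ny - 1 - y);
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int j = j0; j <= j1; ++j)
          s += a[base + (R_xlen_t)j * nx + i] * k[j + R];
        b[base + i] = s;
      }
    }
  }
  a.swap(b);

  // axis 2 (slowest stride)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    const int j0 = std::max(-R, -z), j1 = std::min(R, nz - 1 - z);
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z * sz + (R_xlen_t)y * nx;
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int j = j0; j <= j1; ++j) s += a[base + (R_xlen_t)j * sz + i] * k[j + R];
        b[base + i] = s;
      }
    }
  }

  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}
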