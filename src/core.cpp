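#include <Rcpp.h>
using namespace Rcpp;

// Density volumes are R arrays with dims (nx, ny, nz), x fastest (column
// major), matching the MRC section layout. Physical coordinate of voxel
// (i,j,k) (0-based) is origin + c(i,j,k) * voxel nm.

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool *outside) {
  // x,y,z in voxel units (0-based, fractional)
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *outside = true;
    return 0.0;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double *p = v + (size_t)k0 * nx * ny + (size_t)j0 * nx + i0;
  size_t sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_render_blobs(IntegerVector dim, double voxel,
                               NumericVector origin, NumericMatrix centers,
                               NumericVector amp, NumericVector sigma,
                               double cutoff_sigma = 3.5) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double *v = REAL(out);
  int n = centers.nrow();
  for (int b = 0; b < n; b++) {
    double cx = (centers(b, 0) - origin[0]) / voxel;
    double cy = (centers(b, 1) - origin[1]) / voxel;
    double cz = (centers(b, 2) - origin[2]) / voxel;
    double s = sigma[b] / voxel;        // sigma in voxels
    double a = amp[b];
    double r = cutoff_sigma * s;
    int i0 = std::max(0, (int)std::ceil(cx - r));
    int i1 = std::min(nx - 1, (int)std::floor(cx + r));
    int j0 = std::max(0, (int)std::ceil(cy - r));
    int j1 = std::min(ny - 1, (int)std::floor(cy + r));
    int k0 = std::max(0, (int)std::ceil(cz - r));
    int k1 = std::min(nz - 1, (int)std::floor(cz + r));
    if (i1 < i0 || j1 < j0 || k1 < k0) continue;
    double inv2s2 = 1.0 / (2.0 * s * s);
    // separable exponentials
    std::vector<double> ex(i1 - i0 + 1), ey(j1 - j0 + 1), ez(k1 - k0 + 1);
    for (int i = i0; i <= i1; i++) ex[i - i0] = std::exp(-(i - cx) * (i - cx) * inv2s2);
    for (int j = j0; j <= j1; j++) ey[j - j0] = std::exp(-(j - cy) * (j - cy) * inv2s2);
    for (int k = k0; k <= k1; k++) ez[k - k0] = std::exp(-(k - cz) * (k - cz) * inv2s2);
    for (int k = k0; k <= k1; k++) {
      double az = a * ez[k - k0];
      for (int j = j0; j <= j1; j++) {
        double ayz = az * ey[j - j0];
        double *row = v + (size_t)k * nx * ny + (size_t)j * nx;
        for (int i = i0; i <= i1; i++) row[i] += ayz * ex[i - i0];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Crop a cubic box from a volume: box voxel b (0-based, centre c=(n-1)/2)
// samples the volume at world = center + R %*% ((b - c) * voxel).
// R is a 3x3 rotation (box frame -> world frame), column major (9 values).
// [[Rcpp::export]]
List cpp_crop(NumericVector vol, IntegerVector dim, double voxel,
              NumericVector origin, NumericVector center, NumericVector rot,
              int box_size) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  int n = box_size;
  double c = (n - 1) / 2.0;
  NumericVector out((size_t)n * n * n);
  double *o = REAL(out);
  bool outside = false;
  int n_out = 0;
  size_t idx = 0;
  for (int k = 0; k < n; k++) {
    double bz = (k - c) * voxel;
    for (int j = 0; j < n; j++) {
      double by = (j - c) * voxel;
      for (int i = 0; i < n; i++) {
        double bx = (i - c) * voxel;
        double wx = center[0] + rot[0] * bx + rot[3] * by + rot[6] * bz;
        double wy = center[1] + rot[1] * bx + rot[4] * by + rot[7] * bz;
        double wz = center[2] + rot[2] * bx + rot[5] * by + rot[8] * bz;
        bool po = false;
        o[idx++] = trilinear(v, nx, ny, nz, (wx - origin[0]) / voxel,
                             (wy - origin[1]) / voxel, (wz - origin[2]) / voxel,
                             &po);
        if (po) { outside = true; n_out++; }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n);
  return List::create(_["data"] = out, _["n_outside"] = n_out);
}

// out(y) = in(A %*% y + s); y, s in nm relative to the box centre.
// A column major (9 values). Used both for building rotated/shifted
// reference banks and for putting particles back into the common frame.
// [[Rcpp::export]]
NumericVector cpp_transform_box(NumericVector box, NumericVector A,
                                NumericVector s, double voxel) {
  IntegerVector dim = box.attr("dim");
  int n = dim[0];
  double c = (n - 1) / 2.0;
  const double *v = REAL(box);
  NumericVector out((size_t)n * n * n);
  double *o = REAL(out);
  size_t idx = 0;
  for (int k = 0; k < n; k++) {
    double yz = (k - c) * voxel;
    for (int j = 0; j < n; j++) {
      double yy = (j - c) * voxel;
      for (int i = 0; i < n; i++) {
        double yx = (i - c) * voxel;
        double px = A[0] * yx + A[3] * yy + A[6] * yz + s[0];
        double py = A[1] * yx + A[4] * yy + A[7] * yz + s[1];
        double pz = A[2] * yx + A[5] * yy + A[8] * yz + s[2];
        bool po = false;
        o[idx++] = trilinear(v, n, n, n, px / voxel + c, py / voxel + c,
                             pz / voxel + c, &po);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// separable Gaussian smoothing of a cubic box, sigma in voxels
// [[Rcpp::export]]
NumericVector cpp_lowpass3(NumericVector box, double sigma) {
  IntegerVector dim = box.attr("dim");
  int n = dim[0];
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double sum = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    sum += k[i + r];
  }
  for (auto &v : k) v /= sum;
  std::vector<double> a(box.begin(), box.end()), b(a.size());
  size_t s[3] = {1, (size_t)n, (size_t)n * n};
  for (int axis = 0; axis < 3; axis++) {
    size_t st = s[axis];
    for (int u = 0; u < n; u++) {
      for (int v = 0; v < n; v++) {
        size_t base;
        if (axis == 0) base = (size_t)u * n + (size_t)v * n * n;
        else if (axis == 1) base = (size_t)u + (size_t)v * n * n;
        else base = (size_t)u + (size_t)v * n;
        for (int i = 0; i < n; i++) {
          double acc = 0;
          int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
          for (int j = lo; j <= hi; j++) acc += a[base + j * st] * k[j - i + r];
          b[base + i * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
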