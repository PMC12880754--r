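#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Low-level 3D grid kernels. All arrays are column-major (R layout),
// linear index = i + nx*(j + ny*k) with 0-based i,j,k. Voxel centre of
// index i (0-based) sits at origin + i*spacing in physical coordinates.

static inline int reflect_idx(int i, int n) {
  // symmetric boundary: ... c b a | a b c ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector binary, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> offs;
  std::vector<int> di, dj, dk;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (binary[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur - (R_xlen_t)k * nx * ny);
      int j = rem / nx;
      int i = rem - j * nx;
      for (int m = 0; m < nn; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (binary[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double> &ker, int r) {
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int q = 0; q < n[b2]; ++q) {
    for (int p = 0; p < n[b1]; ++p) {
      R_xlen_t base = (R_xlen_t)p * stride[b1] + (R_xlen_t)q * stride[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) {
          int ii = reflect_idx(i + d, na);
          acc += ker[d + r] * v[base + (R_xlen_t)ii * sa];
        }
        tmp[base + (R_xlen_t)i * sa] = acc;
      }
    }
  }
  v.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector src, IntegerVector dims,
                                double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) {
    NumericVector out = clone(src);
    out.attr("dim") = dims;
    return out;
  }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) {
    ker[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += ker[d + r];
  }
  for (auto &k : ker) k /= s;

  std::vector<double> v(src.begin(), src.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis)
    blur_axis(v, tmp, nx, ny, nz, axis, ker, r);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

static void boxsum_axis(std::vector<double> &v, std::vector<double> &tmp,
                        int nx, int ny, int nz, int axis, int half) {
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int q = 0; q < n[b2]; ++q) {
    for (int p = 0; p < n[b1]; ++p) {
      R_xlen_t base = (R_xlen_t)p * stride[b1] + (R_xlen_t)q * stride[b2];
      // running window sum, zero outside
      double acc = 0.0;
      for (int i = 0; i <= half && i < na; ++i) acc += v[base + (R_xlen_t)i * sa];
      for (int i = 0; i < na; ++i) {
        tmp[base + (R_xlen_t)i * sa] = acc;
        int add = i + half + 1;
        int rem = i - half;
        if (add < na) acc += v[base + (R_xlen_t)add * sa];
        if (rem >= 0) acc -= v[base + (R_xlen_t)rem * sa];
      }
    }
  }
  v.swap(tmp);
}

// Sum over the axis-aligned cube of edge `edge` (odd) centred at each voxel,
// treating values outside the grid as zero.
// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector src, IntegerVector dims, int edge) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int half = edge / 2;
  std::vector<double> v(src.begin(), src.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis)
    boxsum_axis(v, tmp, nx, ny, nz, axis, half);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &vvec, std::vector<double> &z) {
  int k = 0;
  vvec[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int vk = vvec[k];
      s = ((f[q] + q * (double)q) - (f[vk] + vk * (double)vk)) / (2.0 * (q - vk));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    vvec[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int vk = vvec[k];
    d[q] = (q - vk) * (double)(q - vk) + f[vk];
  }
}

// Euclidean distance (in voxel units) from each voxel to the nearest
// feature voxel (feature != 0). Felzenszwalb-Huttenlocher separable EDT.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> v(n);
  for (R_xlen_t s = 0; s < n; ++s) v[s] = feature[s] != 0 ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> vv(nmax);
  const int ndim[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int na = ndim[axis];
    const R_xlen_t sa = stride[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    for (int q = 0; q < ndim[b2]; ++q) {
      for (int p = 0; p < ndim[b1]; ++p) {
        R_xlen_t base = (R_xlen_t)p * stride[b1] + (R_xlen_t)q * stride[b2];
        for (int i = 0; i < na; ++i) f[i] = v[base + (R_xlen_t)i * sa];
        dt1d(f, d, na, vv, z);
        for (int i = 0; i < na; ++i) v[base + (R_xlen_t)i * sa] = d[i];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = std::sqrt(v[s]);
  out.attr("dim") = dims;
  return out;
}

// Resample `src` (moving volume, physical frame) onto a destination grid in
// the fixed frame under a rigid+isotropic-scale transform that maps moving
// physical coordinates to fixed ones:
//   x_fixed = centreFixed + Rz(theta) * scale * (x_moving - centreMoving) + translation
// For each destination voxel we invert the map and interpolate the source.
// Voxels whose source position falls outside the source support are NA.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector src, IntegerVector sdims,
                                 NumericVector sorigin, double sspacing,
                                 IntegerVector ddims, NumericVector dorigin,
                                 double dspacing, NumericVector centreFixed,
                                 NumericVector centreMoving, double thetaDeg,
                                 double scale, NumericVector translation,
                                 bool nearest) {
  const int snx = sdims[0], sny = sdims[1], snz = sdims[2];
  const int dnx = ddims[0], dny = ddims[1], dnz = ddims[2];
  const R_xlen_t dn = (R_xlen_t)dnx * dny * dnz;
  NumericVector out(dn, NA_REAL);
  const double th = thetaDeg * M_PI / 180.0;
  const double ct = std::cos(-th), st = std::sin(-th); // inverse rotation
  const double inv_s = 1.0 / scale;

  R_xlen_t idx = 0;
  for (int k = 0; k < dnz; ++k) {
    const double zf = dorigin[2] + k * dspacing;
    for (int j = 0; j < dny; ++j) {
      const double yf = dorigin[1] + j * dspacing;
      for (int i = 0; i < dnx; ++i, ++idx) {
        const double xf = dorigin[0] + i * dspacing;
        // fixed -> moving
        double px = xf - translation[0] - centreFixed[0];
        double py = yf - translation[1] - centreFixed[1];
        double pz = zf - translation[2] - centreFixed[2];
        double rx = ct * px - st * py;
        double ry = st * px + ct * py;
        double xm = centreMoving[0] + inv_s * rx;
        double ym = centreMoving[1] + inv_s * ry;
        double zm = centreMoving[2] + inv_s * pz;
        double u = (xm - sorigin[0]) / sspacing;
        double v = (ym - sorigin[1]) / sspacing;
        double w = (zm - sorigin[2]) / sspacing;
        if (nearest) {
          int iu = (int)std::lround(u), iv = (int)std::lround(v),
              iw = (int)std::lround(w);
          if (iu < 0 || iu >= snx || iv < 0 || iv >= sny || iw < 0 || iw >= snz)
            continue;
          out[idx] = src[iu + (R_xlen_t)snx * (iv + (R_xlen_t)sny * iw)];
        } else {
          if (u < 0 || u > snx - 1 || v < 0 || v > sny - 1 || w < 0 ||
              w > snz - 1)
            continue;
          // clamp so samples exactly on the upper support boundary stay valid
          int i0 = std::min((int)std::floor(u), snx - 2);
          int j0 = std::min((int)std::floor(v), sny - 2);
          int k0 = std::min((int)std::floor(w), snz - 2);
          double fu = u - i0, fv = v - j0, fw = w - k0;
          R_xlen_t b = i0 + (R_xlen_t)snx * (j0 + (R_xlen_t)sny * k0);
          const R_xlen_t sx = 1, sy = snx, sz = (R_xlen_t)snx * sny;
          double c00 = src[b] * (1 - fu) + src[b + sx] * fu;
          double c10 = src[b + sy] * (1 - fu) + src[b + sy + sx] * fu;
          double c01 = src[b + sz] * (1 - fu) + src[b + sz + sx] * fu;
          double c11 = src[b + sz + sy] * (1 - fu) + src[b + sz + sy + sx] * fu;
          double c0 = c00 * (1 - fv) + c10 * fv;
          double c1 = c01 * (1 - fv) + c11 * fv;
          out[idx] = c0 * (1 - fw) + c1 * fw;
        }
      }
    }
  }
  out.attr("dim") = ddims;
  return out;
}

// Mean over non-overlapping factor^3 blocks; output dims are floor(dims/factor).
// [[Rcpp::export]]
NumericVector cpp_block_average(NumericVector src, IntegerVector dims,
                                int factor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / factor, oy = ny / factor, oz = nz / factor;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double inv = 1.0 / ((double)factor * factor * factor);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double acc = 0.0;
        for (int c = 0; c < factor; ++c)
          for (int b = 0; b < factor; ++b)
            for (int a = 0; a < factor; ++a) {
              R_xlen_t s = (R_xlen_t)(i * factor + a) +
                           (R_xlen_t)nx * ((j * factor + b) +
                                           (R_xlen_t)ny * (k * factor + c));
              acc += src[s];
            }
        out[i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k)] = acc * inv;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Joint histogram of two equal-length vectors given precomputed 0-based bin
// indices; entries with bin < 0 are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(IntegerVector bx, IntegerVector by, int nbins) {
  NumericMatrix h(nbins, nbins);
  const R_xlen_t n = bx.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    int a = bx[s], b = by[s];
    if (a < 0 || b < 0) continue;
    h(a, b) += 1.0;
  }
  return h;
}

// Parzen-windowed joint histogram: continuous bin coordinates in
// [0, nbins-1], each sample spread over the two adjacent bins per axis
// with linear (first-order B-spline) weights. Smooth in the inputs, which
// keeps the mutual-information surface free of hard-binning artifacts.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist_parzen(NumericVector bx, NumericVector by,
                                    int nbins) {
  NumericMatrix h(nbins, nbins);
  const R_xlen_t n = bx.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    double a = bx[s], b = by[s];
    if (ISNAN(a) || ISNAN(b)) continue;
    int ia = (int)std::floor(a);
    int ib = (int)std::floor(b);
    if (ia >= nbins - 1) ia = nbins - 2;
    if (ib >= nbins - 1) ib = nbins - 2;
    if (ia < 0) ia = 0;
    if (ib < 0) ib = 0;
    double wa = a - ia, wb = b - ib;
    if (wa < 0) wa = 0; if (wa > 1) wa = 1;
    if (wb < 0) wb = 0; if (wb > 1) wb = 1;
    h(ia, ib) += (1 - wa) * (1 - wb);
    h(ia + 1, ib) += wa * (1 - wb);
    h(ia, ib + 1) += (1 - wa) * wb;
    h(ia + 1, ib + 1) += wa * wb;
  }
  return h;
}
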