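#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Rasterize isotropic Gaussian blobs into a 3-D grid.
// dim: nx,ny,nz; voxel: nm; origin: nm position of the centre of voxel (1,1,1);
// centers: N x 3 (nm); sigma, mass: length N. Each blob integrates to `mass`.
// [[Rcpp::export(name = ".cppBlobRaster")]]
NumericVector cppBlobRaster(IntegerVector dim, double voxel, NumericVector origin,
                            NumericMatrix centers, NumericVector sigma,
                            NumericVector mass) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double vv = voxel * voxel * voxel;
  for (int b = 0; b < centers.nrow(); ++b) {
    const double s = sigma[b];
    if (s <= 0) continue;
    const double cx = (centers(b, 0) - origin[0]) / voxel;
    const double cy = (centers(b, 1) - origin[1]) / voxel;
    const double cz = (centers(b, 2) - origin[2]) / voxel;
    const double rad = 4.0 * s / voxel;            // 4 sigma support
    const double amp = mass[b] * vv / std::pow(2.0 * M_PI * s * s, 1.5);
    const double inv2s2 = 1.0 / (2.0 * s * s / (voxel * voxel));
    int i0 = std::max(0, (int)std::floor(cx - rad)),
        i1 = std::min(nx - 1, (int)std::ceil(cx + rad));
    int j0 = std::max(0, (int)std::floor(cy - rad)),
        j1 = std::min(ny - 1, (int)std::ceil(cy + rad));
    int k0 = std::max(0, (int)std::floor(cz - rad)),
        k1 = std::min(nz - 1, (int)std::ceil(cz + rad));
    for (int k = k0; k <= k1; ++k) {
      const double dz = k - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = j - cy, dyz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = i - cx;
          out[base + i] += amp * std::exp(-(dx * dx + dyz) * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static inline double trilerp(const double* v, int nx, int ny, int nz,
                             double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  double fx = x - i, fy = y - j, fz = z - k;
  // neighbour indices clamped to the grid (weight 0 at exact boundaries)
  const int i1 = (i + 1 < nx) ? i + 1 : i;
  const int j1 = (j + 1 < ny) ? j + 1 : j;
  const int k1 = (k + 1 < nz) ? k + 1 : k;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double* p0 = v + (R_xlen_t)k * sxy;
  const double* p1 = v + (R_xlen_t)k1 * sxy;
  const R_xlen_t r0 = (R_xlen_t)j * nx, r1 = (R_xlen_t)j1 * nx;
  double c00 = p0[r0 + i] * (1 - fx) + p0[r0 + i1] * fx;
  double c10 = p0[r1 + i] * (1 - fx) + p0[r1 + i1] * fx;
  double c01 = p1[r0 + i] * (1 - fx) + p1[r0 + i1] * fx;
  double c11 = p1[r1 + i] * (1 - fx) + p1[r1 + i1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

// out(p) = vol(Q p + t) in voxel units about each array's centre; trilinear.
// Q is 3x3 (column-major as an R matrix), t length 3 in voxels of `vol`.
// [[Rcpp::export(name = ".cppResample")]]
NumericVector cppResample(NumericVector vol, IntegerVector outDim,
                          NumericMatrix Q, NumericVector t, double fill) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double gx = (ox - 1) / 2.0, gy = (oy - 1) / 2.0, gz = (oz - 1) / 2.0;
  const double* v = REAL(vol);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    const double pz = k - gz;
    for (int j = 0; j < oy; ++j) {
      const double py = j - gy;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double px = i - gx;
        double x = Q(0, 0) * px + Q(0, 1) * py + Q(0, 2) * pz + t[0] + cx;
        double y = Q(1, 0) * px + Q(1, 1) * py + Q(1, 2) * pz + t[1] + cy;
        double z = Q(2, 0) * px + Q(2, 1) * py + Q(2, 2) * pz + t[2] + cz;
        out[idx] = trilerp(v, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  out.attr("dim") = outDim;
  return out;
}

// Trilinear sampling at arbitrary voxel coordinates (0-based).
// [[Rcpp::export(name = ".cppSample")]]
NumericVector cppSample(NumericVector vol, NumericMatrix pts, double fill) {
  IntegerVector d = vol.attr("dim");
  const double* v = REAL(vol);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = trilerp(v, d[0], d[1], d[2], pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// Single-axis projection about the y (2nd) axis, beam along z (3rd axis).
// For tilt angle theta the volume is viewed rotated by theta about +y:
// P_theta(u, y) = sum_s V(x = cx + u c - s s_, y, z = cz + u s_ + s c) * voxel
// [[Rcpp::export(name = ".cppProjectY")]]
NumericVector cppProjectY(NumericVector vol, NumericVector anglesDeg,
                          double voxel) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], na = anglesDeg.size();
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)nx * ny * na);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  const int ns = (int)std::ceil(std::sqrt((double)nx * nx + (double)nz * nz));
  const double s0 = (ns - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double th = anglesDeg[a] * M_PI / 180.0;
    const double c = std::cos(th), sn = std::sin(th);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const double u = i - cx;
        double acc = 0.0;
        for (int s = 0; s < ns; ++s) {
          const double w = s - s0;
          const double x = cx + u * c - w * sn;
          const double z = cz + u * sn + w * c;
          if (x < 0 || z < 0 || x > nx - 1 || z > nz - 1) continue;
          // bilinear in (x,z) at fixed integer y
          int ix = (int)std::floor(x), iz = (int)std::floor(z);
          if (ix == nx - 1) ix--;
          if (iz == nz - 1) iz--;
          double fx = x - ix, fz = z - iz;
          const R_xlen_t sxy = (R_xlen_t)nx * ny;
          const double* p = v + (R_xlen_t)iz * sxy + (R_xlen_t)j * nx + ix;
          acc += (p[0] * (1 - fx) + p[1] * fx) * (1 - fz) +
                 (p[sxy] * (1 - fx) + p[sxy + 1] * fx) * fz;
        }
        out[(R_xlen_t)a * nx * ny + (R_xlen_t)j * nx + i] = acc * voxel;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, na);
  return out;
}

// Back-projection of (ramp-filtered) projections; inverse of cppProjectY's
// geometry: voxel (x,y,z) reads projection a at u = (x-cx) cos + (z-cz) sin.
// [[Rcpp::export(name = ".cppBackprojectY")]]
NumericVector cppBackprojectY(NumericVector proj, NumericVector anglesDeg,
                              int nz) {
  IntegerVector d = proj.attr("dim");
  const int nu = d[0], ny = d[1], na = d[2];
  const double* p = REAL(proj);
  NumericVector out((R_xlen_t)nu * ny * nz);
  const double cu = (nu - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double scale = M_PI / (2.0 * na);
  for (int a = 0; a < na; ++a) {
    const double th = anglesDeg[a] * M_PI / 180.0;
    const double c = std::cos(th), sn = std::sin(th);
    const double* pa = p + (R_xlen_t)a * nu * ny;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double w = k - cz;
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nu; ++i, ++idx) {
          const double u = cu + (i - cu) * c + w * sn;
          if (u < 0 || u > nu - 1) continue;
          int iu = (int)std::floor(u);
          if (iu == nu - 1) iu--;
          const double fu = u - iu;
          const double* q = pa + (R_xlen_t)j * nu + iu;
          out[idx] += (q[0] * (1 - fu) + q[1] * fu) * scale;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, ny, nz);
  return out;
}

// 6-connected component labelling of a logical 3-D array (BFS).
// [[Rcpp::export(name = ".cppLabel3D")]]
IntegerVector cppLabel3D(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t t = q.front();
      q.pop();
      int i = t % nx, j = (t / nx) % ny, k = t / ((R_xlen_t)nx * ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t u = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[u] && !lab[u]) {
          lab[u] = cur;
          q.push(u);
        }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// Masked dot products of one volume against a stack-free rotated candidate:
// returns c(sum(a*b*m), sum(b*b*m)) for fast normalized scoring.
// [[Rcpp::export(name = ".cppMaskedDots")]]
NumericVector cppMaskedDots(NumericVector a, NumericVector b, NumericVector m) {
  const R_xlen_t n = a.size();
  const double *pa = REAL(a), *pb = REAL(b), *pm = REAL(m);
  double ab = 0, bb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double w = pm[i];
    if (w == 0) continue;
    ab += pa[i] * pb[i] * w;
    bb += pb[i] * pb[i] * w;
  }
  return NumericVector::create(ab, bb);
}

// One-pass sums for weighted Pearson scoring: aw is the pre-weighted,
// pre-centred volume (a * w); returns c(sum(aw*b), sum(w*b), sum(w*b*b)).
// [[Rcpp::export(name = ".cppScoreSums")]]
NumericVector cppScoreSums(NumericVector aw, NumericVector b,
                           NumericVector w) {
  const R_xlen_t n = aw.size();
  const double *pa = REAL(aw), *pb = REAL(b), *pw = REAL(w);
  double ab = 0, sb = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double wi = pw[i];
    if (wi == 0) continue;
    const double bi = pb[i];
    ab += pa[i] * bi;
    sb += wi * bi;
    sbb += wi * bi * bi;
  }
  return NumericVector::create(ab, sb, sbb);
}
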