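#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are passed as numeric arrays with dim (nz, ny, nx), z fastest
// (z = electron-beam direction at 0 deg tilt, y = tilt axis).
// Tilt-series stacks have dim (ny, nx, n_angles), y fastest.
// Internally volumes are transposed to (ny, nz, nx) so the innermost loop
// over y is contiguous for both the volume and the image.

static inline void vol_to_internal(const double* vol, std::vector<double>& t,
                                   int nz, int ny, int nx) {
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        t[(size_t)y + (size_t)ny * ((size_t)z + (size_t)nz * x)] =
            vol[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x)];
}

static inline void internal_to_vol(const std::vector<double>& t, double* vol,
                                   int nz, int ny, int nx) {
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        vol[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x)] =
            t[(size_t)y + (size_t)ny * ((size_t)z + (size_t)nz * x)];
}

// Forward projection: for each tilt angle, rotate the (z, x) plane about the
// tilt axis (parallel to y, at x = centre + axis_offset) by the tilt angle
// with bilinear interpolation and sum along z.  Output values are line
// integrals in length units: sum * voxel_size.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector vdim,
                          NumericVector angles_deg, double axis_offset,
                          double voxel_size) {
  const int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  const int na = angles_deg.size();
  std::vector<double> t((size_t)nz * ny * nx);
  vol_to_internal(REAL(vol), t, nz, ny, nx);
  NumericVector out((size_t)ny * nx * na);
  const double cz = (nz - 1) / 2.0;
  const double cx = (nx - 1) / 2.0 + axis_offset;
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    double* img = REAL(out) + (size_t)a * ny * nx;
    for (int v = 0; v < nx; ++v) {
      double* icol = img + (size_t)ny * v;
      for (int u = 0; u < nz; ++u) {
        const double zs = cz + c * (u - cz) - s * (v - cx);
        const double xs = cx + s * (u - cz) + c * (v - cx);
        const int z0 = (int)std::floor(zs), x0 = (int)std::floor(xs);
        const double fz = zs - z0, fx = xs - x0;
        for (int dz = 0; dz < 2; ++dz) {
          const int zi = z0 + dz;
          if (zi < 0 || zi >= nz) continue;
          const double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dx = 0; dx < 2; ++dx) {
            const int xi = x0 + dx;
            if (xi < 0 || xi >= nx) continue;
            const double w = wz * (dx ? fx : 1.0 - fx);
            if (w == 0.0) continue;
            const double* __restrict__ tcol = &t[(size_t)ny * ((size_t)zi + (size_t)nz * xi)];
            double* __restrict__ ic = icol;
            for (int y = 0; y < ny; ++y) ic[y] += w * tcol[y];
          }
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] *= voxel_size;
  out.attr("dim") = IntegerVector::create(ny, nx, na);
  return out;
}

// Exact adjoint of cpp_project (same interpolation weights, scatter instead
// of gather), including the voxel_size scale.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector imgs, IntegerVector vdim,
                              NumericVector angles_deg, double axis_offset,
                              double voxel_size) {
  const int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  const int na = angles_deg.size();
  std::vector<double> t((size_t)nz * ny * nx, 0.0);
  const double cz = (nz - 1) / 2.0;
  const double cx = (nx - 1) / 2.0 + axis_offset;
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    const double* img = REAL(imgs) + (size_t)a * ny * nx;
    for (int v = 0; v < nx; ++v) {
      const double* icol = img + (size_t)ny * v;
      for (int u = 0; u < nz; ++u) {
        const double zs = cz + c * (u - cz) - s * (v - cx);
        const double xs = cx + s * (u - cz) + c * (v - cx);
        const int z0 = (int)std::floor(zs), x0 = (int)std::floor(xs);
        const double fz = zs - z0, fx = xs - x0;
        for (int dz = 0; dz < 2; ++dz) {
          const int zi = z0 + dz;
          if (zi < 0 || zi >= nz) continue;
          const double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dx = 0; dx < 2; ++dx) {
            const int xi = x0 + dx;
            if (xi < 0 || xi >= nx) continue;
            const double w = wz * (dx ? fx : 1.0 - fx);
            if (w == 0.0) continue;
            double* __restrict__ tcol = &t[(size_t)ny * ((size_t)zi + (size_t)nz * xi)];
            const double* __restrict__ ic = icol;
            for (int y = 0; y < ny; ++y) tcol[y] += w * ic[y];
          }
        }
      }
    }
  }
  NumericVector out((size_t)nz * ny * nx);
  internal_to_vol(t, REAL(out), nz, ny, nx);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] *= voxel_size;
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}

// Translate a 2D image by (dy, dx) pixels with bilinear interpolation;
// out(y, x) = in(y - dy, x - dx), zero outside.
// [[Rcpp::export]]
NumericMatrix cpp_shift_image(NumericMatrix img, double dy, double dx) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    const double xs = x - dx;
    const int x0 = (int)std::floor(xs);
    const double fx = xs - x0;
    for (int y = 0; y < ny; ++y) {
      const double ys = y - dy;
      const int y0 = (int)std::floor(ys);
      const double fy = ys - y0;
      double acc = 0.0;
      for (int ddy = 0; ddy < 2; ++ddy) {
        const int yi = y0 + ddy;
        if (yi < 0 || yi >= ny) continue;
        const double wy = ddy ? fy : 1.0 - fy;
        for (int ddx = 0; ddx < 2; ++ddx) {
          const int xi = x0 + ddx;
          if (xi < 0 || xi >= nx) continue;
          acc += wy * (ddx ? fx : 1.0 - fx) * img(yi, xi);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (dim nz, ny, nx) with
// 6- or 26-connectivity.  Labels are assigned in scan order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector vdim,
                                   int connectivity) {
  const int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  const size_t n = (size_t)nz * ny * nx;
  IntegerVector labels(n);
  std::vector<int> offs_z, offs_y, offs_x;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
          continue;
        offs_z.push_back(dz); offs_y.push_back(dy); offs_x.push_back(dx);
      }
  int next = 0;
  std::vector<size_t> stack;
  const int* m = INTEGER(mask);
  int* lab = INTEGER(labels);
  for (size_t i = 0; i < n; ++i) {
    if (m[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur % nz);
      const int y = (int)((cur / nz) % ny);
      const int x = (int)(cur / ((size_t)nz * ny));
      for (size_t k = 0; k < offs_z.size(); ++k) {
        const int zz = z + offs_z[k], yy = y + offs_y[k], xx = x + offs_x[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        const size_t j = (size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx);
        if (m[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = IntegerVector::create(nz, ny, nx);
  labels.attr("n_labels") = next;
  return labels;
}

// ---- Marching tetrahedra isosurface -------------------------------------
// The cube lattice is decomposed into 6 tetrahedra per cube along the
// Freudenthal (Kuhn) subdivision: for each permutation of the axes, the
// tetrahedron {p, p+e1, p+e1+e2, p+e1+e2+e3}.  This subdivision tiles space
// consistently, so shared tetrahedron faces match across cubes and the
// resulting surface is watertight by construction, with no ambiguous cases.
// Vertices are emitted in 0-based (z, y, x) index coordinates.

struct TetVert { double z, y, x; };

static inline TetVert edge_interp(double iso, const double* vals,
                                  const int* cz, const int* cy, const int* cx,
                                  int a, int b) {
  const double va = vals[a], vb = vals[b];
  const double tt = (iso - va) / (vb - va);
  TetVert v;
  v.z = cz[a] + tt * (cz[b] - cz[a]);
  v.y = cy[a] + tt * (cy[b] - cy[a]);
  v.x = cx[a] + tt * (cx[b] - cx[a]);
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_marching_tets(NumericVector vol, IntegerVector vdim,
                                double iso) {
  const int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  const double* V = REAL(vol);
  // axis permutations for the 6 tetrahedra (axes: 0 = z, 1 = y, 2 = x)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::vector<double> tris;  // 9 doubles per triangle: v0 v1 v2 as (z,y,x)
  tris.reserve(1 << 16);
  const double eps = 1e-9;
  auto val = [&](int z, int y, int x) {
    double v = V[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x)];
    if (v == iso) v = iso + eps;  // avoid degenerate zero-area faces
    return v;
  };
  int cz[4], cy[4], cx[4];
  double tv[4];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        // quick reject on the cube
        double lo = val(z, y, x), hi = lo;
        for (int k = 1; k < 8; ++k) {
          const double v = val(z + (k & 1), y + ((k >> 1) & 1), x + ((k >> 2) & 1));
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (lo > iso || hi < iso) continue;
        for (int p = 0; p < 6; ++p) {
          int dz = 0, dy = 0, dx = 0;
          cz[0] = z; cy[0] = y; cx[0] = x;
          for (int k = 0; k < 3; ++k) {
            const int ax = perms[p][k];
            if (ax == 0) ++dz;
            else if (ax == 1) ++dy;
            else ++dx;
            cz[k + 1] = z + dz; cy[k + 1] = y + dy; cx[k + 1] = x + dx;
          }
          int inside[4], nin = 0;
          for (int k = 0; k < 4; ++k) {
            tv[k] = val(cz[k], cy[k], cx[k]);
            inside[k] = tv[k] > iso;
            nin += inside[k];
          }
          if (nin == 0 || nin == 4) continue;
          // outward reference direction: inside centroid -> outside centroid
          double gi[3] = {0, 0, 0}, go[3] = {0, 0, 0};
          for (int k = 0; k < 4; ++k) {
            double* g = inside[k] ? gi : go;
            g[0] += cz[k]; g[1] += cy[k]; g[2] += cx[k];
          }
          const double dir[3] = {go[0] / (4 - nin) - gi[0] / nin,
                                 go[1] / (4 - nin) - gi[1] / nin,
                                 go[2] / (4 - nin) - gi[2] / nin};
          TetVert tvx[4];
          int ntri = 0;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int k = 0; k < 4; ++k)
              if ((nin == 1) == (inside[k] != 0)) { apex = k; break; }
            int j = 0;
            for (int k = 0; k < 4; ++k) {
              if (k == apex) continue;
              tvx[j++] = edge_interp(iso, tv, cz, cy, cx, apex, k);
            }
            ntri = 1;
          } else {  // nin == 2: quad split into two triangles
            int in_i[2], out_i[2], a = 0, b = 0;
            for (int k = 0; k < 4; ++k)
              if (inside[k]) in_i[a++] = k; else out_i[b++] = k;
            tvx[0] = edge_interp(iso, tv, cz, cy, cx, in_i[0], out_i[0]);
            tvx[1] = edge_interp(iso, tv, cz, cy, cx, in_i[0], out_i[1]);
            tvx[2] = edge_interp(iso, tv, cz, cy, cx, in_i[1], out_i[1]);
            tvx[3] = edge_interp(iso, tv, cz, cy, cx, in_i[1], out_i[0]);
            ntri = 2;
          }
          for (int tr = 0; tr < ntri; ++tr) {
            TetVert a0 = tvx[0], a1, a2;
            if (tr == 0) { a1 = tvx[1]; a2 = tvx[2]; }
            else { a1 = tvx[2]; a2 = tvx[3]; }
            // orient so the normal points from inside (foreground) outward
            const double u[3] = {a1.z - a0.z, a1.y - a0.y, a1.x - a0.x};
            const double w[3] = {a2.z - a0.z, a2.y - a0.y, a2.x - a0.x};
            const double nrm[3] = {u[1] * w[2] - u[2] * w[1],
                                   u[2] * w[0] - u[0] * w[2],
                                   u[0] * w[1] - u[1] * w[0]};
            const double dp = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
            if (dp < 0) std::swap(a1, a2);
            const TetVert vv[3] = {a0, a1, a2};
            for (int k = 0; k < 3; ++k) {
              tris.push_back(vv[k].z);
              tris.push_back(vv[k].y);
              tris.push_back(vv[k].x);
            }
          }
        }
      }
  const int n = (int)(tris.size() / 9);
  NumericMatrix out(n, 9);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 9; ++k) out(i, k) = tris[(size_t)i * 9 + k];
  return out;
}
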