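#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Squared Euclidean distance transform, Felzenszwalb & Huttenlocher lower
// envelope of parabolas, one pass per axis.  `f` holds squared distances so
// far (0 at sites, +Inf elsewhere); updated in place along one axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) k--; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { k++; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; q++) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    double dq = (double)q - v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

// site: TRUE marks distance-zero voxels.  Returns squared distance in voxel
// units to the nearest site voxel centre (+Inf if the volume has no site).
static std::vector<double> edt_sq_impl(const std::vector<char>& site,
                                       int nx, int ny, int nz) {
  const double INF = std::numeric_limits<double>::infinity();
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = site[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      size_t base = (size_t)zz * nx * ny + (size_t)yy * nx;
      for (int xx = 0; xx < nx; xx++) f[xx] = g[base + xx];
      dt1d(f, d, v, z, nx);
      for (int xx = 0; xx < nx; xx++) g[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = (size_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; yy++) f[yy] = g[base + (size_t)yy * nx];
      dt1d(f, d, v, z, ny);
      for (int yy = 0; yy < ny; yy++) g[base + (size_t)yy * nx] = d[yy];
    }
  // pass along z
  size_t nxy = (size_t)nx * ny;
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = (size_t)yy * nx + xx;
      for (int zz = 0; zz < nz; zz++) f[zz] = g[base + (size_t)zz * nxy];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; zz++) g[base + (size_t)zz * nxy] = d[zz];
    }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector site, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> s(n);
  for (size_t i = 0; i < n; i++) s[i] = site[i] == TRUE;
  std::vector<double> g = edt_sq_impl(s, nx, ny, nz);
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}

struct Center { double r; int fx, fy, fz; };

// Local thickness: for every phase voxel, the diameter of the largest
// inscribed sphere that contains it.  Sphere centres live on the half-voxel
// grid (voxel centres, face/edge midpoints and corners) so that structures an
// even number of voxels wide are not penalised; a centre's radius is its
// distance to the nearest background voxel centre minus half a voxel
// (distance from a voxel centre to the phase boundary).  Centres whose sphere
// is contained in a neighbouring centre's sphere are pruned, the rest are
// painted in decreasing radius order.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector phase, IntegerVector dim) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;

  bool any_phase = false, any_bg = false;
  for (size_t i = 0; i < n; i++) {
    if (phase[i] == TRUE) any_phase = true; else any_bg = true;
  }
  if (!any_phase) stop("local thickness of an empty phase is undefined");
  if (!any_bg) stop("phase fills the whole volume: thickness is unbounded");

  // fine grid at half-voxel spacing; fine index 2j corresponds to voxel j
  int fx = 2 * nx - 1, fy = 2 * ny - 1, fz = 2 * nz - 1;
  size_t nf = (size_t)fx * fy * fz;
  std::vector<char> site(nf, 0);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        size_t ci = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (phase[ci] != TRUE)
          site[(size_t)(2 * zz) * fx * fy + (size_t)(2 * yy) * fx + 2 * xx] = 1;
      }
  std::vector<double> d2 = edt_sq_impl(site, fx, fy, fz);

  // candidate centres: radius (voxel units) = dist/2 - 1/2 > 0
  std::vector<double> r(nf);
  for (size_t i = 0; i < nf; i++)
    r[i] = (d2[i] == INF) ? INF : std::sqrt(d2[i]) / 2.0 - 0.5;

  const double eps = 1e-9;
  std::vector<Center> centers;
  centers.reserve(1024);
  for (int cz = 0; cz < fz; cz++)
    for (int cy = 0; cy < fy; cy++)
      for (int cx = 0; cx < fx; cx++) {
        size_t i = (size_t)cz * fx * fy + (size_t)cy * fx + cx;
        double ri = r[i];
        if (!(ri > 0.0) || ri == INF) continue;
        bool dominated = false;
        for (int dz = -1; dz <= 1 && !dominated; dz++)
          for (int dy = -1; dy <= 1 && !dominated; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int ux = cx + dx, uy = cy + dy, uz = cz + dz;
              if (ux < 0 || uy < 0 || uz < 0 || ux >= fx || uy >= fy || uz >= fz)
                continue;
              double ru = r[(size_t)uz * fx * fy + (size_t)uy * fx + ux];
              if (ru == INF) continue;
              double dist = 0.5 * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (ru >= ri + dist - eps && ru > ri + eps) { dominated = true; break; }
            }
        if (!dominated) {
          Center c; c.r = ri; c.fx = cx; c.fy = cy; c.fz = cz;
          centers.push_back(c);
        }
      }

  std::sort(centers.begin(), centers.end(),
            [](const Center& a, const Center& b) { return a.r > b.r; });

  NumericVector lt(n);
  double* plt = REAL(lt);
  for (size_t k = 0; k < centers.size(); k++) {
    double rr = centers[k].r;
    double cx = centers[k].fx / 2.0, cy = centers[k].fy / 2.0,
           cz = centers[k].fz / 2.0;
    double rr2 = rr * rr + eps;
    int x0 = (int)std::ceil(cx - rr - eps), x1 = (int)std::floor(cx + rr + eps);
    int y0 = (int)std::ceil(cy - rr - eps), y1 = (int)std::floor(cy + rr + eps);
    int z0 = (int)std::ceil(cz - rr - eps), z1 = (int)std::floor(cz + rr + eps);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1; if (z1 >= nz) z1 = nz - 1;
    double val = 2.0 * rr;
    for (int pz = z0; pz <= z1; pz++) {
      double dz = pz - cz, dz2 = dz * dz;
      for (int py = y0; py <= y1; py++) {
        double dy = py - cy, dyz2 = dy * dy + dz2;
        if (dyz2 > rr2) continue;
        size_t base = (size_t)pz * nx * ny + (size_t)py * nx;
        for (int px = x0; px <= x1; px++) {
          double dx = px - cx;
          if (dx * dx + dyz2 > rr2) continue;
          size_t pi = base + px;
          if (plt[pi] < val) plt[pi] = val;
        }
      }
    }
  }
  for (size_t i = 0; i < n; i++) if (phase[i] != TRUE) lt[i] = 0.0;
  lt.attr("dim") = dim;
  return lt;
}

// 26-connected component labelling (BFS); returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector phase, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t s = 0; s < n; s++) {
    if (phase[s] != TRUE || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      size_t i = queue.back(); queue.pop_back();
      int xx = (int)(i % nx), yy = (int)((i / nx) % ny), zz = (int)(i / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int ux = xx + dx, uy = yy + dy, uz = zz + dz;
            if (ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz)
              continue;
            size_t ui = (size_t)uz * nx * ny + (size_t)uy * nx + ux;
            if (phase[ui] == TRUE && lab[ui] == 0) {
              lab[ui] = next;
              queue.push_back(ui);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Distance ridge (medial axis): phase voxels whose maximal inscribed sphere is
// not contained in that of any 26-neighbour.
// [[Rcpp::export]]
LogicalVector cpp_dist_ridge(LogicalVector phase, IntegerVector dim) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> site(n);
  for (size_t i = 0; i < n; i++) site[i] = phase[i] != TRUE;
  std::vector<double> d2 = edt_sq_impl(site, nx, ny, nz);
  std::vector<double> dt(n);
  for (size_t i = 0; i < n; i++) dt[i] = (d2[i] == INF) ? INF : std::sqrt(d2[i]);

  const double eps = 1e-9;
  LogicalVector ridge(n);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        size_t i = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (phase[i] != TRUE) { ridge[i] = FALSE; continue; }
        bool dominated = false;
        for (int dz = -1; dz <= 1 && !dominated; dz++)
          for (int dy = -1; dy <= 1 && !dominated; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int ux = xx + dx, uy = yy + dy, uz = zz + dz;
              if (ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz)
                continue;
              size_t ui = (size_t)uz * nx * ny + (size_t)uy * nx + ux;
              if (phase[ui] != TRUE) continue;
              double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (dt[ui] >= dt[i] + dist - eps) { dominated = true; break; }
            }
        ridge[i] = !dominated;
      }
  ridge.attr("dim") = dim;
  return ridge;
}
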