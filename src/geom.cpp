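// Geometry kernels: nearest-neighbour queries, Chamfer distance and a
// perspective z-buffer triangle rasterizer. Point coordinates are mm.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Uniform-grid accelerated exact nearest-neighbour search. Reference points
// are hashed into cubic cells; a query expands rings of cells until the best
// distance found is provably exact.
struct GridIndex {
  std::vector<double> px, py, pz;
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<std::vector<int> > bins;

  explicit GridIndex(const NumericMatrix &ref) {
    const int m = ref.nrow();
    px.resize(m); py.resize(m); pz.resize(m);
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int j = 0; j < m; ++j) {
      px[j] = ref(j,0); py[j] = ref(j,1); pz[j] = ref(j,2);
      xmin = std::min(xmin, px[j]); xmax = std::max(xmax, px[j]);
      ymin = std::min(ymin, py[j]); ymax = std::max(ymax, py[j]);
      zmin = std::min(zmin, pz[j]); zmax = std::max(zmax, pz[j]);
    }
    // aim for a handful of points per occupied cell
    const double vol = std::max(1.0, (xmax-xmin) * (ymax-ymin) * (zmax-zmin));
    cell = std::max(1e-6, std::cbrt(vol / std::max(1, m)) * 2.0);
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = (int)((xmax - xmin) / cell) + 1;
    ny = (int)((ymax - ymin) / cell) + 1;
    nz = (int)((zmax - zmin) / cell) + 1;
    bins.resize((size_t)nx * ny * nz);
    for (int j = 0; j < m; ++j) bins[cell_of(px[j], py[j], pz[j])].push_back(j);
  }

  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  inline size_t cell_of(double x, double y, double z) const {
    const int ix = clampi((int)((x - x0) / cell), nx);
    const int iy = clampi((int)((y - y0) / cell), ny);
    const int iz = clampi((int)((z - z0) / cell), nz);
    return ((size_t)iz * ny + iy) * nx + ix;
  }

  // exact nearest neighbour of (qx,qy,qz): returns index, sets d2
  int query(double qx, double qy, double qz, double &best2) const {
    const int ix = clampi((int)((qx - x0) / cell), nx);
    const int iy = clampi((int)((qy - y0) / cell), ny);
    const int iz = clampi((int)((qz - z0) / cell), nz);
    best2 = std::numeric_limits<double>::max();
    int bj = -1;
    const int rmax = std::max(std::max(nx, ny), nz);
    for (int r = 0; r <= rmax; ++r) {
      if (bj >= 0) {
        // ring r-1 scanned completely; cells at ring r are at least
        // (r-1)*cell away from the query cell
        const double safe = (r - 1) * cell;
        if (safe > 0 && best2 <= safe * safe) break;
      }
      bool any_cell = false;
      for (int dz = -r; dz <= r; ++dz) {
        const int cz = iz + dz;
        if (cz < 0 || cz >= nz) continue;
        for (int dy = -r; dy <= r; ++dy) {
          const int cy = iy + dy;
          if (cy < 0 || cy >= ny) continue;
          for (int dx = -r; dx <= r; ++dx) {
            // only the shell of the cube (interior already scanned)
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            const int cx = ix + dx;
            if (cx < 0 || cx >= nx) continue;
            any_cell = true;
            const std::vector<int> &bin = bins[((size_t)cz * ny + cy) * nx + cx];
            for (size_t k = 0; k < bin.size(); ++k) {
              const int j = bin[k];
              const double ddx = qx - px[j], ddy = qy - py[j], ddz = qz - pz[j];
              const double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
              if (d2 < best2) { best2 = d2; bj = j; }
            }
          }
        }
      }
      if (!any_cell && bj >= 0) break;
    }
    return bj;
  }
};

// Nearest neighbour in `ref` for every row of `query`.
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export(name = ".nn_query_cpp")]]
List nn_query_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow();
  if (ref.nrow() == 0) stop("reference cloud is empty");
  GridIndex g(ref);
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    idx[i] = g.query(query(i,0), query(i,1), query(i,2), d2) + 1;
    dist[i] = std::sqrt(d2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static double mean_nn_dist(const NumericMatrix &a, const GridIndex &g) {
  double acc = 0.0;
  for (int i = 0; i < a.nrow(); ++i) {
    double d2;
    g.query(a(i,0), a(i,1), a(i,2), d2);
    acc += std::sqrt(d2);
  }
  return acc / a.nrow();
}

// Symmetric Chamfer distance: average of the two directed mean
// nearest-neighbour distances.
// [[Rcpp::export(name = ".chamfer_cpp")]]
double chamfer_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() == 0 || b.nrow() == 0) stop("Chamfer distance requires non-empty clouds");
  GridIndex ga(a), gb(b);
  return 0.5 * (mean_nn_dist(a, gb) + mean_nn_dist(b, ga));
}

// Perspective z-buffer rasterizer. `verts` are camera-frame points (mm, z
// forward), `faces` 1-based triangle indices. Pixel (u, v) = (col, row),
// 0-based, pixel centers at integer coordinates: u = fx * x / z + cx.
// Returns an H x W depth matrix in mm, 0 = no hit. Triangles with any vertex
// closer than `near_mm` are dropped (the simulated scenes keep the organ
// far in front of the camera, so no clipping is needed).
// [[Rcpp::export(name = ".rasterize_cpp")]]
NumericMatrix rasterize_cpp(NumericMatrix verts, IntegerMatrix faces,
                            double fx, double fy, double cx, double cy,
                            int width, int height, double near_mm = 10.0) {
  const int nv = verts.nrow(), nf = faces.nrow();
  NumericMatrix depth(height, width);  // zero-initialized = invalid
  std::vector<double> u(nv), v(nv), z(nv);
  for (int i = 0; i < nv; ++i) {
    z[i] = verts(i,2);
    if (z[i] > 0) {
      u[i] = fx * verts(i,0) / z[i] + cx;
      v[i] = fy * verts(i,1) / z[i] + cy;
    }
  }
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f,0) - 1, b = faces(f,1) - 1, c = faces(f,2) - 1;
    if (a < 0 || b < 0 || c < 0 || a >= nv || b >= nv || c >= nv)
      stop("face index out of range");
    if (z[a] < near_mm || z[b] < near_mm || z[c] < near_mm) continue;
    const double area = (u[b]-u[a])*(v[c]-v[a]) - (u[c]-u[a])*(v[b]-v[a]);
    if (std::fabs(area) < 1e-12) continue;
    int u0 = (int)std::ceil(std::min(u[a], std::min(u[b], u[c])));
    int u1 = (int)std::floor(std::max(u[a], std::max(u[b], u[c])));
    int v0 = (int)std::ceil(std::min(v[a], std::min(v[b], v[c])));
    int v1 = (int)std::floor(std::max(v[a], std::max(v[b], v[c])));
    if (u0 < 0) u0 = 0; if (v0 < 0) v0 = 0;
    if (u1 > width - 1) u1 = width - 1;
    if (v1 > height - 1) v1 = height - 1;
    if (u0 > u1 || v0 > v1) continue;
    const double iza = 1.0 / z[a], izb = 1.0 / z[b], izc = 1.0 / z[c];
    for (int pv = v0; pv <= v1; ++pv) {
      for (int pu = u0; pu <= u1; ++pu) {
        const double w0 = ((u[b]-pu)*(v[c]-pv) - (u[c]-pu)*(v[b]-pv)) / area;
        const double w1 = ((u[c]-pu)*(v[a]-pv) - (u[a]-pu)*(v[c]-pv)) / area;
        const double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        const double zi = 1.0 / (w0*iza + w1*izb + w2*izc);  // perspective-correct
        double &cell = depth(pv, pu);
        if (cell == 0.0 || zi < cell) cell = zi;
      }
    }
  }
  return depth;
}
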