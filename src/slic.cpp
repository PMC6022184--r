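#include <Rcpp.h>
#include <queue>
#include <set>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Flattened column-major index for 0-based (x, y, z).
static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// One SLIC assignment sweep. Each centroid scans the cube of half-width
// `win` voxels around its spatial position; a masked voxel takes the
// centroid minimising Dw^2 = (dc/m)^2 + (ds/In)^2, lower centroid index
// winning ties. Masked voxels left unreached are assigned to the globally
// nearest centroid under the same distance.
// centroids: K x 6 matrix (x, y, z, gm, wm, csf), 0-based coordinates.
// [[Rcpp::export]]
List slic_assign_cpp(NumericMatrix centroids,
                     NumericVector gm, NumericVector wm, NumericVector csf,
                     LogicalVector mask, IntegerVector dims,
                     double In, double m, int win) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, K = centroids.nrow();
  IntegerVector labels(n, -1);
  std::vector<double> best(n, R_PosInf);
  const double inv_m2 = 1.0 / (m * m), inv_In2 = 1.0 / (In * In);

  for (int k = 0; k < K; ++k) {
    const double cx = centroids(k, 0), cy = centroids(k, 1), cz = centroids(k, 2);
    const double cg = centroids(k, 3), cw = centroids(k, 4), cc = centroids(k, 5);
    const int x0 = std::max(0, (int)std::ceil(cx) - win);
    const int x1 = std::min(nx - 1, (int)std::floor(cx) + win);
    const int y0 = std::max(0, (int)std::ceil(cy) - win);
    const int y1 = std::min(ny - 1, (int)std::floor(cy) + win);
    const int z0 = std::max(0, (int)std::ceil(cz) - win);
    const int z1 = std::min(nz - 1, (int)std::floor(cz) + win);
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          const int i = vidx(x, y, z, nx, ny);
          if (!mask[i]) continue;
          const double dg = gm[i] - cg, dw = wm[i] - cw, dcf = csf[i] - cc;
          const double dc2 = dg * dg + dw * dw + dcf * dcf;
          const double dx = x - cx, dy = y - cy, dz = z - cz;
          const double ds2 = dx * dx + dy * dy + dz * dz;
          const double d = dc2 * inv_m2 + ds2 * inv_In2;
          if (d < best[i]) { best[i] = d; labels[i] = k; }
        }
  }

  int n_unreached = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = vidx(x, y, z, nx, ny);
        if (!mask[i] || labels[i] >= 0) continue;
        ++n_unreached;
        double bd = R_PosInf; int bk = 0;
        for (int k = 0; k < K; ++k) {
          const double dg = gm[i] - centroids(k, 3), dw = wm[i] - centroids(k, 4),
                       dcf = csf[i] - centroids(k, 5);
          const double dx = x - centroids(k, 0), dy = y - centroids(k, 1),
                       dz = z - centroids(k, 2);
          const double d = (dg * dg + dw * dw + dcf * dcf) * inv_m2 +
                           (dx * dx + dy * dy + dz * dz) * inv_In2;
          if (d < bd) { bd = d; bk = k; }
        }
        labels[i] = bk;
      }

  return List::create(_["labels"] = labels, _["n_unreached"] = n_unreached);
}

// Cluster means (spatial + 3 intensity channels) and sizes for the update
// step. Empty clusters keep NaN means; the caller carries the previous
// centroid forward.
// [[Rcpp::export]]
List slic_update_cpp(IntegerVector labels,
                     NumericVector gm, NumericVector wm, NumericVector csf,
                     IntegerVector dims, int K) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix cent(K, 6);
  IntegerVector size(K);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = vidx(x, y, z, nx, ny);
        const int k = labels[i];
        if (k < 0) continue;
        cent(k, 0) += x; cent(k, 1) += y; cent(k, 2) += z;
        cent(k, 3) += gm[i]; cent(k, 4) += wm[i]; cent(k, 5) += csf[i];
        ++size[k];
      }
  for (int k = 0; k < K; ++k) {
    if (size[k] == 0) {
      for (int j = 0; j < 6; ++j) cent(k, j) = NA_REAL;
    } else {
      for (int j = 0; j < 6; ++j) cent(k, j) /= size[k];
    }
  }
  return List::create(_["centroids"] = cent, _["size"] = size);
}

// Connected components of the label field under 6-connectivity, where a
// component is a maximal connected set of voxels sharing one label.
// Returns per-voxel component ids (0-based, -1 outside), component sizes,
// component labels, and the scan-order first voxel of each component.
// [[Rcpp::export]]
List label_components_cpp(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector comp(n, -1);
  std::vector<int> csize, clabel, cfirst;
  const int dx[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, 1, -1 };
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = vidx(x, y, z, nx, ny);
        if (labels[i] < 0 || comp[i] >= 0) continue;
        const int lab = labels[i];
        comp[i] = next;
        int sz = 0;
        std::queue<std::array<int, 3>> q;
        q.push({x, y, z});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          ++sz;
          for (int d = 0; d < 6; ++d) {
            const int xx = v[0] + dx[d], yy = v[1] + dy[d], zz = v[2] + dz[d];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int j = vidx(xx, yy, zz, nx, ny);
            if (comp[j] < 0 && labels[j] == lab) {
              comp[j] = next;
              q.push({xx, yy, zz});
            }
          }
        }
        csize.push_back(sz);
        clabel.push_back(lab);
        cfirst.push_back(i);
        ++next;
      }
  return List::create(_["comp"] = comp, _["size"] = wrap(csize),
                      _["label"] = wrap(clabel), _["first"] = wrap(cfirst));
}

// 6-adjacency pairs between distinct components (each unordered pair once).
// [[Rcpp::export]]
IntegerMatrix component_adjacency_cpp(IntegerVector comp, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::set<std::pair<int, int>> edges;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = vidx(x, y, z, nx, ny);
        const int a = comp[i];
        if (a < 0) continue;
        if (x + 1 < nx) {
          const int b = comp[vidx(x + 1, y, z, nx, ny)];
          if (b >= 0 && b != a) edges.insert({std::min(a, b), std::max(a, b)});
        }
        if (y + 1 < ny) {
          const int b = comp[vidx(x, y + 1, z, nx, ny)];
          if (b >= 0 && b != a) edges.insert({std::min(a, b), std::max(a, b)});
        }
        if (z + 1 < nz) {
          const int b = comp[vidx(x, y, z + 1, nx, ny)];
          if (b >= 0 && b != a) edges.insert({std::min(a, b), std::max(a, b)});
        }
      }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (const auto &e : edges) { out(r, 0) = e.first; out(r, 1) = e.second; ++r; }
  return out;
}
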