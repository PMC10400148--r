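#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 6-connected multi-source BFS distance (in voxel steps) from a set of
// target labels. Distance is graph distance through any voxel; used to rank
// voxels of a cell by proximity to the bundle sheath.
// [[Rcpp::export]]
IntegerVector bfs_distance_cpp(IntegerVector labels, IntegerVector dims,
                               IntegerVector target_labels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<bool> is_target(64, false);
  for (int t = 0; t < target_labels.size(); ++t)
    is_target[target_labels[t]] = true;
  IntegerVector dist(n, NA_INTEGER);
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (is_target[labels[i]]) { dist[i] = 0; q.push(i); }
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int k = idx / (nx * ny);
    int rem = idx - k * nx * ny;
    int j = rem / nx;
    int i = rem - j * nx;
    int d0 = dist[idx];
    for (int m = 0; m < 6; ++m) {
      int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int nb = ii + nx * (jj + ny * kk);
      if (dist[nb] == NA_INTEGER) { dist[nb] = d0 + 1; q.push(nb); }
    }
  }
  return dist;
}

// Connected components (6-connectivity) of a logical mask. Returns 0 outside
// the mask and 1..n_components inside.
// [[Rcpp::export]]
IntegerVector connected_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector comp(n, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  int next_id = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || comp[s] != 0) continue;
    comp[s] = ++next_id;
    q.push(s);
    while (!q.empty()) {
      int idx = q.front(); q.pop();
      int k = idx / (nx * ny);
      int rem = idx - k * nx * ny;
      int j = rem / nx;
      int i = rem - j * nx;
      for (int m = 0; m < 6; ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int nb = ii + nx * (jj + ny * kk);
        if (mask[nb] && comp[nb] == 0) { comp[nb] = next_id; q.push(nb); }
      }
    }
  }
  return comp;
}

// Diffusive divergence of the finite-volume operator: out[i] = sum over
// faces of g * (x_nb - x_i). Faces to fixed cells use the fixed value.
// [[Rcpp::export]]
NumericVector fv_divergence_cpp(IntegerVector dims, NumericVector gx,
                                NumericVector gy, NumericVector gz,
                                NumericVector x) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny, n = nxy * nz;
  NumericVector out(n, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + j * nx + k * nxy;
        double acc = 0.0;
        if (i > 0) acc += gx[id - 1] * (x[id - 1] - x[id]);
        if (i < nx - 1) acc += gx[id] * (x[id + 1] - x[id]);
        if (j > 0) acc += gy[id - nx] * (x[id - nx] - x[id]);
        if (j < ny - 1) acc += gy[id] * (x[id + nx] - x[id]);
        if (k > 0) acc += gz[id - nxy] * (x[id - nxy] - x[id]);
        if (k < nz - 1) acc += gz[id] * (x[id + nxy] - x[id]);
        out[id] = acc;
      }
  return out;
}
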