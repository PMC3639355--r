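#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 6-connected flood fill over a voxel mask. mask: 1 = traversable.
// seeds: 0-based voxel indices. Returns 0/1 reachability vector.
// [[Rcpp::export]]
IntegerVector cpp_flood_fill(IntegerVector mask, IntegerVector dims,
                             IntegerVector seeds) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nv = nx * ny * nz;
  IntegerVector vis(nv, 0);
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s];
    if (v >= 0 && v < nv && mask[v] && !vis[v]) { vis[v] = 1; q.push(v); }
  }
  int dxs[6] = {1, -1, 0, 0, 0, 0};
  int dys[6] = {0, 0, 1, -1, 0, 0};
  int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int w = (kk * ny + jj) * nx + ii;
      if (mask[w] && !vis[w]) { vis[w] = 1; q.push(w); }
    }
  }
  return vis;
}

// 6-connected component labelling (labels 1..k over mask==1 voxels).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nv = nx * ny * nz;
  IntegerVector lab(nv, 0);
  int next = 0;
  int dxs[6] = {1, -1, 0, 0, 0, 0};
  int dys[6] = {0, 0, 1, -1, 0, 0};
  int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (int v0 = 0; v0 < nv; ++v0) {
    if (!mask[v0] || lab[v0]) continue;
    ++next;
    std::queue<int> q;
    lab[v0] = next; q.push(v0);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int w = (kk * ny + jj) * nx + ii;
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// Does any voxel of component `label` touch a voxel where `other` is 1?
// Returns, for each label 1..max, 1 if adjacent to `other`.
// [[Rcpp::export]]
IntegerVector cpp_touches(IntegerVector lab, IntegerVector other,
                          IntegerVector dims, int nlab) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(nlab, 0);
  int dxs[6] = {1, -1, 0, 0, 0, 0};
  int dys[6] = {0, 0, 1, -1, 0, 0};
  int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (int v = 0; v < lab.size(); ++v) {
    int l = lab[v];
    if (!l || out[l - 1]) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
        out[l - 1] = out[l - 1];  // box edge does not count as solvent
        continue;
      }
      int w = (kk * ny + jj) * nx + ii;
      if (other[w]) { out[l - 1] = 1; break; }
    }
  }
  return out;
}
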