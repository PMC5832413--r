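#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Kendall's tau-a: (concordant - discordant) / (m(m-1)/2).
// Pairs tied in either vector count as neither. O(m^2); m is the number of
// dissimilarity pairs (780 for a 40-condition RDM), so this stays cheap even
// inside searchlight and permutation loops.
// [[Rcpp::export(name = ".tau_a_cpp")]]
double tau_a_cpp(NumericVector x, NumericVector y) {
  const R_xlen_t m = x.size();
  if (y.size() != m) stop("length mismatch");
  long long net = 0;
  for (R_xlen_t i = 0; i < m - 1; ++i) {
    const double xi = x[i], yi = y[i];
    for (R_xlen_t j = i + 1; j < m; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      if (dx != 0.0 && dy != 0.0)
        net += ((dx > 0) == (dy > 0)) ? 1 : -1;
    }
  }
  return (double)net / ((double)m * (m - 1) / 2.0);
}

// tau-a of one fixed vector against each column of a matrix (searchlight /
// permutation inner loop).
// [[Rcpp::export(name = ".tau_a_many_cpp")]]
NumericVector tau_a_many_cpp(NumericVector x, NumericMatrix Y) {
  const int m = Y.nrow(), k = Y.ncol();
  if (x.size() != m) stop("length mismatch");
  NumericVector out(k);
  const double denom = (double)m * (m - 1) / 2.0;
  // precompute sign structure of x pairs
  for (int c = 0; c < k; ++c) {
    long long net = 0;
    for (int i = 0; i < m - 1; ++i) {
      const double xi = x[i], yi = Y(i, c);
      for (int j = i + 1; j < m; ++j) {
        const double dx = x[j] - xi, dy = Y(j, c) - yi;
        if (dx != 0.0 && dy != 0.0)
          net += ((dx > 0) == (dy > 0)) ? 1 : -1;
      }
    }
    out[c] = (double)net / denom;
  }
  return out;
}

struct UnionFind {
  std::vector<int> parent, rank_;
  void init(int n) {
    parent.resize(n); rank_.assign(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        off.push_back({{dx, dy, dz}});
      }
}

// Connected-component labels of a logical 3D array; 0 outside components,
// 1..n_components inside, labeled in scan order of each component's first voxel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector img, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (img.size() != n) stop("dims do not match image length");
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  UnionFind uf; uf.init(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int v = x + nx * (y + ny * z);
        if (!img[v]) continue;
        for (size_t k = 0; k < off.size(); ++k) {
          const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          const int u = xx + nx * (yy + ny * zz);
          if (img[u]) uf.unite(v, u);
        }
      }
  IntegerVector lab(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (!img[v]) continue;
    int r = uf.find(v);
    if (remap[r] == 0) remap[r] = ++next;
    lab[v] = remap[r];
  }
  lab.attr("dim") = dims;
  return lab;
}

// Threshold-free cluster enhancement, one-sided (positive).
// TFCE(v) = sum over thresholds h = dh, 2dh, ... of e_h(v)^E * h^H * dh,
// where e_h(v) is the extent of the supra-threshold component containing v.
// Voxels outside `mask` are ignored entirely.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector img, IntegerVector dims, LogicalVector mask,
                       double E, double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (img.size() != n || mask.size() != n) stop("dims mismatch");
  if (dh <= 0) stop("dh must be > 0");
  NumericVector out(n, 0.0);
  out.attr("dim") = dims;
  double mx = 0.0;
  for (int v = 0; v < n; ++v)
    if (mask[v] && img[v] > mx) mx = img[v];
  if (mx <= 0.0) return out;
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  UnionFind uf;
  std::vector<int> extent(n);
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    uf.init(n);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int v = x + nx * (y + ny * z);
          if (!mask[v] || img[v] < h) continue;
          for (size_t k = 0; k < off.size(); ++k) {
            const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            const int u = xx + nx * (yy + ny * zz);
            if (mask[u] && img[u] >= h) uf.unite(v, u);
          }
        }
    std::fill(extent.begin(), extent.end(), 0);
    for (int v = 0; v < n; ++v)
      if (mask[v] && img[v] >= h) ++extent[uf.find(v)];
    const double hH = std::pow(h, H) * dh;
    for (int v = 0; v < n; ++v)
      if (mask[v] && img[v] >= h)
        out[v] += std::pow((double)extent[uf.find(v)], E) * hH;
  }
  return out;
}
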