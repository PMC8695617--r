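#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, std::vector<int>& size,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (size[a] < size[b]) std::swap(a, b);
  parent[b] = a;
  size[a] += size[b];
}

static std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int,3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// Adjacency (CSR) among in-mask voxels; only "lower" neighbors (j < i) are
// stored so each edge is visited once.
struct MaskGraph {
  std::vector<int> ptr;    // size m + 1
  std::vector<int> adj;    // neighbor mask-positions
  int m;
};

static MaskGraph build_graph(const LogicalVector& mask,
                             const IntegerVector& dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int V = nx * ny * nz;
  std::vector<int> pos(V, -1);
  std::vector<int> vox;
  for (int i = 0; i < V; ++i)
    if (mask[i]) { pos[i] = (int)vox.size(); vox.push_back(i); }
  auto offs = neighbor_offsets(connectivity);
  MaskGraph g;
  g.m = (int)vox.size();
  g.ptr.assign(g.m + 1, 0);
  std::vector<std::vector<int>> tmp(g.m);
  for (int t = 0; t < g.m; ++t) {
    int i = vox[t];
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    for (size_t o = 0; o < offs.size(); ++o) {
      int x2 = x + offs[o][0], y2 = y + offs[o][1], z2 = z + offs[o][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
        continue;
      int j = x2 + nx * (y2 + ny * z2);
      if (j < i && pos[j] >= 0) tmp[t].push_back(pos[j]);
    }
  }
  for (int t = 0; t < g.m; ++t) g.ptr[t + 1] = g.ptr[t] + (int)tmp[t].size();
  g.adj.reserve(g.ptr[g.m]);
  for (int t = 0; t < g.m; ++t)
    g.adj.insert(g.adj.end(), tmp[t].begin(), tmp[t].end());
  return g;
}

// TFCE over mask voxels: vals has one value per mask voxel; adds the
// enhanced values into out (overwritten). Work vectors are caller-provided
// so permutation loops can reuse them.
static void tfce_masked(const std::vector<double>& vals, const MaskGraph& g,
                        double E, double H, double dh, int n_steps,
                        std::vector<double>& out,
                        std::vector<int>& parent, std::vector<int>& csize,
                        std::vector<char>& on) {
  const int m = g.m;
  std::fill(out.begin(), out.end(), 0.0);
  double vmax = 0.0;
  for (int t = 0; t < m; ++t) if (vals[t] > vmax) vmax = vals[t];
  if (vmax <= 0.0) return;
  double step = dh > 0.0 ? dh : vmax / n_steps;
  const long n_thresh = (long)std::floor(vmax / step + 1e-9);
  for (long s = 1; s <= n_thresh; ++s) {
    const double h = s * step;
    int n_on = 0;
    for (int t = 0; t < m; ++t) {
      if (vals[t] >= h) { on[t] = 1; parent[t] = t; csize[t] = 1; ++n_on; }
      else on[t] = 0;
    }
    if (n_on == 0) break;
    for (int t = 0; t < m; ++t) {
      if (!on[t]) continue;
      for (int e = g.ptr[t]; e < g.ptr[t + 1]; ++e) {
        int j = g.adj[e];
        if (on[j]) uf_union(parent, csize, t, j);
      }
    }
    const double hH = std::pow(h, H) * step;
    for (int t = 0; t < m; ++t)
      if (on[t]) out[t] += std::pow((double)csize[uf_find(parent, t)], E) * hH;
  }
}

// Threshold-free cluster enhancement of a full-grid map (column-major).
// Voxels outside the mask are ignored; negative values contribute nothing.
// dh <= 0 means "use max(map)/n_steps".
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dim,
                       LogicalVector mask, double E, double H,
                       double dh, int n_steps, int connectivity) {
  const int V = dim[0] * dim[1] * dim[2];
  NumericVector out(V);
  MaskGraph g = build_graph(mask, dim, connectivity);
  std::vector<double> vals(g.m), enh(g.m);
  std::vector<int> parent(g.m), csize(g.m), vox;
  std::vector<char> on(g.m);
  vox.reserve(g.m);
  for (int i = 0; i < V; ++i)
    if (mask[i]) {
      if (!R_finite(values[i]))
        stop("non-finite value inside the analysis mask");
      vox.push_back(i);
    }
  for (int t = 0; t < g.m; ++t) vals[t] = values[vox[t]];
  tfce_masked(vals, g, E, H, dh, n_steps, enh, parent, csize, on);
  for (int t = 0; t < g.m; ++t) out[vox[t]] = enh[t];
  return out;
}

// Max-TFCE null distribution for sign-flip permutations, computed wholly in
// C++: M is subjects x mask-voxels, signs is n_perms x subjects (+/-1); for
// each permutation the one-sample t map (sd floored at 1e-12) is enhanced
// and its maximum recorded. dh <= 0 means per-map max/n_steps.
// [[Rcpp::export(name = ".signflip_maxima_cpp")]]
NumericVector signflip_maxima_cpp(NumericMatrix M, IntegerVector dim,
                                  LogicalVector mask, NumericMatrix signs,
                                  double E, double H, double dh, int n_steps,
                                  int connectivity) {
  const int n = M.nrow(), m = M.ncol();
  MaskGraph g = build_graph(mask, dim, connectivity);
  if (g.m != m) stop("mask size does not match map columns");
  const int n_perms = signs.nrow();
  if (signs.ncol() != n) stop("signs must be n_perms x subjects");
  NumericVector maxima(n_perms);
  std::vector<double> tv(m), enh(m);
  std::vector<int> parent(m), csize(m);
  std::vector<char> on(m);
  const double sqn = std::sqrt((double)n);
  for (int p = 0; p < n_perms; ++p) {
    for (int j = 0; j < m; ++j) {
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = signs(p, i) * M(i, j);
        s1 += v; s2 += v * v;
      }
      double mu = s1 / n;
      double var = (s2 - n * mu * mu) / (n - 1);
      double sd = var > 0 ? std::sqrt(var) : 0.0;
      if (sd < 1e-12) sd = 1e-12;
      tv[j] = mu / (sd / sqn);
    }
    tfce_masked(tv, g, E, H, dh, n_steps, enh, parent, csize, on);
    double mx = 0.0;
    for (int j = 0; j < m; ++j) if (enh[j] > mx) mx = enh[j];
    maxima[p] = mx;
  }
  return maxima;
}

// Connected-component labeling of a logical 3D array; returns integer
// labels, 0 outside the input mask.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int V = dim[0] * dim[1] * dim[2];
  MaskGraph g = build_graph(mask, dim, connectivity);
  std::vector<int> vox;
  vox.reserve(g.m);
  for (int i = 0; i < V; ++i) if (mask[i]) vox.push_back(i);
  std::vector<int> parent(g.m), csize(g.m, 1);
  for (int t = 0; t < g.m; ++t) parent[t] = t;
  for (int t = 0; t < g.m; ++t)
    for (int e = g.ptr[t]; e < g.ptr[t + 1]; ++e)
      uf_union(parent, csize, t, g.adj[e]);
  IntegerVector out(V);
  std::vector<int> lab(g.m, 0);
  int next = 0;
  for (int t = 0; t < g.m; ++t) {
    int root = uf_find(parent, t);
    if (lab[root] == 0) lab[root] = ++next;
    out[vox[t]] = lab[root];
  }
  return out;
}
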