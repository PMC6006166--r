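#include <Rcpp.h>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &size,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (size[a] < size[b]) std::swap(a, b);
  parent[b] = a;
  size[a] += size[b];
}

// Threshold-free cluster enhancement on a 3D statistic image.
// stat: column-major 3D array (non-mask voxels must be 0); dims: nx,ny,nz;
// thresholds h = dh, 2dh, ... processed from high to low with an
// incremental union-find over 6-connected supra-threshold voxels.
// TFCE(v) = sum_h extent(h,v)^E * h^H * dh for h <= stat(v).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if ((int)stat.size() != n) stop("stat length does not match dims");
  NumericVector out(n);

  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(stat[i])) stop("non-finite statistic value");
    if (stat[i] > mx) mx = stat[i];
  }
  if (mx <= 0.0 || dh <= 0.0) return out;
  int nsteps = (int)std::floor(mx / dh + 1e-12);
  if (nsteps < 1) return out;

  // voxel order by decreasing statistic
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (stat[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  size_t next = 0;
  for (int k = nsteps; k >= 1; --k) {
    double h = k * dh;
    // activate voxels with stat >= h
    while (next < order.size() && stat[order[next]] >= h) {
      int v = order[next++];
      active[v] = 1;
      csize[v] = 1;
      int z = v / (nx * ny), rem = v % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (active[w]) uf_union(parent, csize, v, w);
      }
    }
    double hH = std::pow(h, H) * dh;
    for (size_t j = 0; j < next; ++j) {
      int v = order[j];
      int root = uf_find(parent, v);
      out[v] += std::pow((double)csize[root], E) * hH;
    }
  }
  return out;
}
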