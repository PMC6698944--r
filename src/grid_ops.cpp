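#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Volumes are stored as R arrays with dim = (nz, ny, nx), i.e. the axial
// slice index varies fastest; linear index i = z + nz*(y + ny*x), 0-based.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

struct Offsets {
  std::vector<int> dz, dy, dx;
};

static Offsets make_offsets(int connectivity) {
  Offsets o;
  if (connectivity == 6) {
    int dz[] = {1, -1, 0, 0, 0, 0};
    int dy[] = {0, 0, 1, -1, 0, 0};
    int dx[] = {0, 0, 0, 0, 1, -1};
    for (int i = 0; i < 6; ++i) {
      o.dz.push_back(dz[i]); o.dy.push_back(dy[i]); o.dx.push_back(dx[i]);
    }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          o.dz.push_back(a); o.dy.push_back(b); o.dx.push_back(c);
        }
  }
  return o;
}

// Flood fill from seed voxels through voxels with lo <= intensity <= hi that
// are not barrier voxels. Seeds are 0-based linear indices, already
// validated on the R side.
// [[Rcpp::export(name = ".rg_flood")]]
LogicalVector rg_flood(NumericVector intensity, IntegerVector dim,
                       IntegerVector seeds, double lo, double hi,
                       Nullable<LogicalVector> barrier, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = intensity.size();
  std::vector<char> out(n, 0);
  const int *bar = nullptr;
  LogicalVector barv;
  if (barrier.isNotNull()) {
    barv = barrier.get();
    bar = LOGICAL(barv);
  }
  Offsets off = make_offsets(connectivity);
  const int m = (int) off.dz.size();
  std::queue<int> q;
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    int i = seeds[s];
    if (!out[i]) { out[i] = 1; q.push(i); }
  }
  const double *I = REAL(intensity);
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int x = i / (nz * ny);
    int r = i - x * nz * ny;
    int y = r / nz;
    int z = r - y * nz;
    for (int k = 0; k < m; ++k) {
      int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (out[j]) continue;
      if (bar && bar[j]) continue;
      double v = I[j];
      if (v < lo || v > hi) continue;
      out[j] = 1;
      q.push(j);
    }
  }
  LogicalVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = out[i] != 0;
  res.attr("dim") = dim;
  return res;
}

// Label connected components of a logical mask. Returns integer labels
// (0 = background) and component sizes (sizes[l-1] = size of component l).
// [[Rcpp::export(name = ".cc_label")]]
List cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  const int *M = LOGICAL(mask);
  int *L = INTEGER(labels);
  Offsets off = make_offsets(connectivity);
  const int m = (int) off.dz.size();
  std::vector<double> sizes;
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (M[i0] != 1 || L[i0] != 0) continue;
    ++next;
    double sz = 0;
    L[i0] = next;
    q.push((int) i0);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      ++sz;
      int x = i / (nz * ny);
      int r = i - x * nz * ny;
      int y = r / nz;
      int z = r - y * nz;
      for (int k = 0; k < m; ++k) {
        int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = lin(zz, yy, xx, nz, ny);
        if (M[j] == 1 && L[j] == 0) { L[j] = next; q.push(j); }
      }
    }
    sizes.push_back(sz);
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) over samples
// at physical positions i*h. Parabolas with infinite height are skipped.
static void dt1d(const double *f, double *d, int n, double h,
                 std::vector<int> &v, std::vector<double> &zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int qi = 0; qi < n; ++qi) {
    if (f[qi] == INF) continue;
    double uq = qi * h;
    if (k < 0) {
      k = 0; v[0] = qi; zbuf[0] = -INF; zbuf[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double up = v[k] * h;
      s = ((f[qi] + uq * uq) - (f[v[k]] + up * up)) / (2.0 * (uq - up));
      if (k > 0 && s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = qi;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
  }
  if (k < 0) {
    for (int qi = 0; qi < n; ++qi) d[qi] = INF;
    return;
  }
  int j = 0;
  for (int qi = 0; qi < n; ++qi) {
    double u = qi * h;
    while (zbuf[j + 1] < u) ++j;
    double dq = u - v[j] * h;
    d[qi] = dq * dq + f[v[j]];
  }
}

// Euclidean distance transform: distance (in mm) from every voxel to the
// nearest TRUE voxel of `mask`, with anisotropic spacing. Voxels where no
// TRUE voxel exists get Inf.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  const int *M = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (M[i] == 1) ? 0.0 : INF;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zbuf(nmax + 1);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int base = lin(0, y, x, nz, ny);
      for (int z = 0; z < nz; ++z) f[z] = g[base + z];
      dt1d(f.data(), d.data(), nz, spacing[0], v, zbuf);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      int base = lin(z, 0, x, nz, ny);
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t) y * nz];
      dt1d(f.data(), d.data(), ny, spacing[1], v, zbuf);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t) y * nz] = d[y];
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t) nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      int base = lin(z, y, 0, nz, ny);
      for (int x = 0; x < nx; ++x) f[x] = g[base + (R_xlen_t) x * sx];
      dt1d(f.data(), d.data(), nx, spacing[2], v, zbuf);
      for (int x = 0; x < nx; ++x) g[base + (R_xlen_t) x * sx] = d[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
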