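#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Voxel grids are R arrays with dim = c(nx, ny, nz), column-major:
// linear index = x + nx * (y + ny * z), 0-based here.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (size_t)ny * z);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from each foreground voxel to the nearest background voxel,
// in voxel units. Voxels outside the grid count as background.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  // Outside-the-grid is background, so a foreground voxel on the grid face is
  // at distance 1 from background; seed with (distance to face + 1)^2 capped
  // by running the pass: easiest is to run the 1D transform with virtual
  // background at -1 and n: incorporate via initial values below.
  const double INF = 1e18;
  for (size_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) f[x] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) {
        double edge = std::min((double)(x + 1), (double)(nx - x));
        double v = std::min(d[x], edge * edge);
        out[lin(x, y, z, nx, ny)] = v;
      }
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) f[y] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) {
        double edge = std::min((double)(y + 1), (double)(ny - y));
        double v = std::min(d[y], edge * edge);
        out[lin(x, y, z, nx, ny)] = v;
      }
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      for (int z = 0; z < nz; z++) f[z] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) {
        double edge = std::min((double)(z + 1), (double)(nz - z));
        double v = std::min(d[z], edge * edge);
        out[lin(x, y, z, nx, ny)] = v;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6- or 26-connectivity), BFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man > 1) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
              continue;
            int q = lin(x, y, z, nx, ny);
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Capsule rasterization: mark voxels whose center lies within radius r of
// the segment p1-p2 (coordinates and radii in continuous voxel units,
// 0-based voxel centers).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(LogicalVector vol_in, IntegerVector dim,
                                     NumericMatrix segs) {
  LogicalVector vol = clone(vol_in);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  for (int s = 0; s < segs.nrow(); s++) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r = segs(s, 6);
    double r2 = r * r;
    int lox = std::max(0, (int)std::floor(std::min(x1, x2) - r - 1));
    int loy = std::max(0, (int)std::floor(std::min(y1, y2) - r - 1));
    int loz = std::max(0, (int)std::floor(std::min(z1, z2) - r - 1));
    int hix = std::min(nx - 1, (int)std::ceil(std::max(x1, x2) + r + 1));
    int hiy = std::min(ny - 1, (int)std::ceil(std::max(y1, y2) + r + 1));
    int hiz = std::min(nz - 1, (int)std::ceil(std::max(z1, z2) + r + 1));
    double ax = x2 - x1, ay = y2 - y1, az = z2 - z1;
    double len2 = ax * ax + ay * ay + az * az;
    for (int z = loz; z <= hiz; z++)
      for (int y = loy; y <= hiy; y++)
        for (int x = lox; x <= hix; x++) {
          double px = x - x1, py = y - y1, pz = z - z1;
          double t = len2 > 0 ? (px * ax + py * ay + pz * az) / len2 : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
          if (dx * dx + dy * dy + dz * dz <= r2)
            vol[lin(x, y, z, nx, ny)] = 1;
        }
  }
  return vol;
}

// ---------------------------------------------------------------------------
// Binary erosion / dilation with an arbitrary offset set (rows of `offsets`
// are integer voxel displacements). Outside the grid counts as background.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int c = lin(x, y, z, nx, ny);
        if (!mask[c]) continue;
        bool keep = true;
        for (int k = 0; k < offsets.nrow() && keep; k++) {
          int qx = x + offsets(k, 0), qy = y + offsets(k, 1),
              qz = z + offsets(k, 2);
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz ||
              !mask[lin(qx, qy, qz, nx, ny)])
            keep = false;
        }
        out[c] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int c = lin(x, y, z, nx, ny);
        if (!mask[c]) continue;
        for (int k = 0; k < offsets.nrow(); k++) {
          int qx = x + offsets(k, 0), qy = y + offsets(k, 1),
              qz = z + offsets(k, 2);
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          out[lin(qx, qy, qz, nx, ny)] = 1;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// 3D curve skeletonization: sequential distance-ordered thinning that deletes
// simple points (topology preserved for the 26/6 object/background
// connectivity pair, Malandain-Bertrand characterization) while keeping
// curve endpoints, eating the surface inward in order of the Euclidean
// distance map so the result stays medially centered.
// ---------------------------------------------------------------------------

// Extract the 3x3x3 neighborhood of voxel (x,y,z) into nb[27]
// (index = (dx+1) + 3*(dy+1) + 9*(dz+1)); outside the grid -> 0.
static inline void neighborhood(const uint8_t* img, int nx, int ny, int nz,
                                int x, int y, int z, uint8_t nb[27]) {
  int i = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++, i++) {
        int qx = x + dx, qy = y + dy, qz = z + dz;
        nb[i] = (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny ||
                 qz >= nz)
                    ? 0
                    : img[lin(qx, qy, qz, nx, ny)];
      }
}

static inline void cellOffset(int i, int& dx, int& dy, int& dz) {
  dx = i % 3 - 1;
  dy = (i / 3) % 3 - 1;
  dz = i / 9 - 1;
}

// number of 26-connected components of object voxels in N26 (center excluded)
static int objComponents26(const uint8_t nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comps++;
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      cellOffset(c, cx, cy, cz);
      for (int j = 0; j < 27; j++) {
        if (j == 13 || !nb[j] || seen[j]) continue;
        int jx, jy, jz;
        cellOffset(j, jx, jy, jz);
        int d = std::max(std::abs(jx - cx),
                         std::max(std::abs(jy - cy), std::abs(jz - cz)));
        if (d <= 1) {
          seen[j] = true;
          stack[top++] = j;
        }
      }
    }
  }
  return comps;
}

// number of 6-connected components of background voxels within N18 that are
// 6-adjacent to the center
static int bgComponents6(const uint8_t nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int i = 0; i < 27; i++) {
    int dx, dy, dz;
    cellOffset(i, dx, dy, dz);
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[i] = (i != 13) && man <= 2;
  }
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; i++) {
    int dx, dy, dz;
    cellOffset(i, dx, dy, dz);
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (man != 1 || nb[i] || seen[i]) continue;  // start only from face cells
    comps++;
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      cellOffset(c, cx, cy, cz);
      for (int j = 0; j < 27; j++) {
        if (!in18[j] || nb[j] || seen[j]) continue;
        int jx, jy, jz;
        cellOffset(j, jx, jy, jz);
        int d = std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz);
        if (d == 1) {
          seen[j] = true;
          stack[top++] = j;
        }
      }
    }
  }
  return comps;
}

static inline bool isSimple(const uint8_t nb[27]) {
  return objComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

static inline int objNeighborCount(const uint8_t nb[27]) {
  int cnt = 0;
  for (int i = 0; i < 27; i++)
    if (i != 13 && nb[i]) cnt++;
  return cnt;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<uint8_t> img(n);
  for (size_t i = 0; i < n; i++) img[i] = mask[i] ? 1 : 0;

  NumericVector edt = cpp_edt_sq(mask, dim);

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  uint8_t nb[27];

  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int c = lin(x, y, z, nx, ny);
        if (img[c]) pq.push(QE(edt[c], c));
      }

  while (!pq.empty()) {
    int c = pq.top().second;
    pq.pop();
    if (!img[c]) continue;
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    neighborhood(img.data(), nx, ny, nz, x, y, z, nb);
    if (objNeighborCount(nb) <= 1) continue;  // curve endpoint: keep
    if (!isSimple(nb)) continue;
    img[c] = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          int q = lin(qx, qy, qz, nx, ny);
          if (img[q]) pq.push(QE(edt[q], q));
        }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = img[i] != 0;
  return out;
}
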