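#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 3D arrays are passed as R arrays with dim = (nz, ny, nx), i.e. z runs
// fastest (column-major).  linear index = z + nz*(y + ny*x), 0-based.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Neighbour offsets for 6- or 26-connectivity.
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  if (connectivity == 6) {
    off = {{{-1,0,0}},{{1,0,0}},{{0,-1,0}},{{0,1,0}},{{0,0,-1}},{{0,0,1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) off.push_back({{dz,dy,dx}});
  }
  return off;
}

//' @name cpp_label_components
//' Connected-component labelling of a binary 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask size does not match dims");
  IntegerVector out(n, 0);
  std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || out[i] != 0) continue;
    ++next_label;
    out[i] = next_label;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int q = lin(zz, yy, xx, nz, ny);
        if (mask[q] && out[q] == 0) { out[q] = next_label; stack.push_back(q); }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

struct WsNode {
  double value;   // topographic height (membrane intensity)
  int label;      // label of the marker that queued it
  long order;     // insertion counter, final deterministic tie-break
  int index;
};
struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value > b.value;      // lowest first
    return a.order > b.order;   // FIFO on plateaus: fronts advance fairly
  }
};

//' @name cpp_watershed
//' Marker-controlled watershed (priority flood) on a 3D intensity image.
//' Every voxel receives the label of the marker basin that reaches it
//' first, flooding in order of increasing intensity; ties broken by
//' insertion order (FIFO), so fronts advance fairly across plateaus and
//' the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector image, IntegerVector markers,
                            IntegerVector dims, int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (image.size() != n || markers.size() != n)
    stop("image/markers size does not match dims");
  IntegerVector out(n, 0);
  std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  long counter = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0) {
      out[i] = markers[i];
    }
  }
  // queue unlabelled neighbours of all marker voxels
  for (R_xlen_t i = 0; i < n; ++i) {
    if (out[i] == 0) continue;
    int p = (int)i;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int q = lin(zz, yy, xx, nz, ny);
      if (out[q] == 0)
        pq.push({image[q], out[i], counter++, q});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    if (out[nd.index] != 0) continue;
    out[nd.index] = nd.label;
    int p = nd.index;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int q = lin(zz, yy, xx, nz, ny);
      if (out[q] == 0)
        pq.push({image[q], nd.label, counter++, q});
    }
  }
  out.attr("dim") = dims;
  return out;
}

//' @name cpp_label_boundary
//' Voxels of a label map whose neighbourhood (26 or 6) contains a
//' different label (image borders do not count as boundary).
// [[Rcpp::export]]
LogicalVector cpp_label_boundary(IntegerVector labels, IntegerVector dims,
                                 int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (labels.size() != n) stop("labels size does not match dims");
  LogicalVector out(n, false);
  std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
  for (R_xlen_t i = 0; i < n; ++i) {
    int p = (int)i;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    int lab = labels[i];
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      if (labels[lin(zz, yy, xx, nz, ny)] != lab) { out[i] = true; break; }
    }
  }
  out.attr("dim") = dims;
  return out;
}

//' @name cpp_surface_coverage
//' Per-label surface statistics for watershed-region classification.
//' A voxel is part of its region's surface if any neighbour lies outside
//' the volume or carries a different label.  A surface voxel is
//' membrane-covered if the membrane exceeds `thr` at the voxel itself or
//' at an adjacent different-label voxel (region interfaces own one side
//' of the membrane each).  Returns a (max label) x 2 matrix of
//' (surface voxels, covered surface voxels).
// [[Rcpp::export]]
IntegerMatrix cpp_surface_coverage(IntegerVector labels, NumericVector membrane,
                                   IntegerVector dims, double thr,
                                   int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (labels.size() != n || membrane.size() != n)
    stop("labels/membrane size does not match dims");
  int mx = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (labels[i] > mx) mx = labels[i];
  IntegerMatrix out(mx, 2);
  std::vector<std::array<int,3>> off = neighbour_offsets(connectivity);
  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab <= 0) continue;
    int p = (int)i;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    bool surface = false, covered = membrane[i] > thr;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        surface = true;
        continue;
      }
      int q = lin(zz, yy, xx, nz, ny);
      if (labels[q] != lab) {
        surface = true;
        if (membrane[q] > thr) covered = true;
      }
    }
    if (surface) {
      out(lab - 1, 0) += 1;
      if (covered) out(lab - 1, 1) += 1;
    }
  }
  return out;
}

//' @name cpp_dilate
//' Binary dilation with an arbitrary structuring element given as a
//' matrix of (dz, dy, dx) offsets (one row per element voxel).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask size does not match dims");
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int p = (int)i;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    for (int k = 0; k < m; ++k) {
      int zz = z + offsets(k,0), yy = y + offsets(k,1), xx = x + offsets(k,2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      out[lin(zz, yy, xx, nz, ny)] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}

//' @name cpp_erode
//' Binary erosion with an arbitrary structuring element; voxels outside
//' the volume count as background (so the result shrinks at the border).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask size does not match dims");
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int p = (int)i;
    int z = p % nz, rem = p / nz, y = rem % ny, x = rem / ny;
    bool keep = true;
    for (int k = 0; k < m && keep; ++k) {
      int zz = z + offsets(k,0), yy = y + offsets(k,1), xx = x + offsets(k,2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        keep = false;
      } else if (!mask[lin(zz, yy, xx, nz, ny)]) {
        keep = false;
      }
    }
    if (keep) out[i] = true;
  }
  out.attr("dim") = dims;
  return out;
}
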