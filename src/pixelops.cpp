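#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pixel-grid primitives shared by the detectors. All functions use the
// package-wide convention: matrices are H x W, (row, col) indexing, and
// connectivity is 8-neighbour for foreground structures unless noted.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {-1, 1, 0, 0}; // order irrelevant for BFS

// Label maximal connected components of a logical mask. Labels are assigned
// in raster-scan order of each component's first pixel, starting at 1;
// background is 0. conn must be 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int* DR = (conn == 4) ? DR4 : DR8;
  const int* DC = (conn == 4) ? DC4 : DC8;
  const int nn = (conn == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> qr, qc;
  qr.reserve(H * W); qc.reserve(H * W);
  // raster scan is row-major over rows then cols (row 0 at top)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      qr.clear(); qc.clear();
      qr.push_back(r); qc.push_back(c);
      lab(r, c) = next;
      for (size_t head = 0; head < qr.size(); ++head) {
        const int cr = qr[head], cc = qc[head];
        for (int k = 0; k < nn; ++k) {
          const int nr = cr + DR[k], nc = cc + DC[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            qr.push_back(nr); qc.push_back(nc);
          }
        }
      }
    }
  }
  return lab;
}

// Flood fill the complement of `blocked` from every non-blocked border
// pixel, using 4-connectivity (the duality partner of 8-connected curves).
// Returns TRUE where the outside reaches.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_outside(const LogicalMatrix& blocked) {
  const int H = blocked.nrow(), W = blocked.ncol();
  LogicalMatrix reached(H, W);
  std::vector<int> qr, qc;
  qr.reserve(H * W); qc.reserve(H * W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (r == 0 || r == H - 1 || c == 0 || c == W - 1) {
        if (!blocked(r, c) && !reached(r, c)) {
          reached(r, c) = true;
          qr.push_back(r); qc.push_back(c);
        }
      }
    }
  }
  for (size_t head = 0; head < qr.size(); ++head) {
    const int cr = qr[head], cc = qc[head];
    for (int k = 0; k < 4; ++k) {
      const int nr = cr + DR4[k], nc = cc + DC4[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!blocked(nr, nc) && !reached(nr, nc)) {
        reached(nr, nc) = true;
        qr.push_back(nr); qc.push_back(nc);
      }
    }
  }
  return reached;
}

// Region growing: expand from the seed mask through 8-connected pixels whose
// intensity strictly exceeds `thr`. Seed pixels are always retained, even if
// they fail the intensity test themselves.
// [[Rcpp::export]]
LogicalMatrix cpp_region_grow(const NumericMatrix& gray,
                              const LogicalMatrix& seed, double thr) {
  const int H = gray.nrow(), W = gray.ncol();
  LogicalMatrix out(H, W);
  std::vector<int> qr, qc;
  qr.reserve(H * W); qc.reserve(H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (seed(r, c)) {
        out(r, c) = true;
        qr.push_back(r); qc.push_back(c);
      }
  for (size_t head = 0; head < qr.size(); ++head) {
    const int cr = qr[head], cc = qc[head];
    for (int k = 0; k < 8; ++k) {
      const int nr = cr + DR8[k], nc = cc + DC8[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!out(nr, nc) && gray(nr, nc) > thr) {
        out(nr, nc) = true;
        qr.push_back(nr); qc.push_back(nc);
      }
    }
  }
  return out;
}

// Hysteresis linking for Canny: keep weak pixels 8-connected (through weak
// pixels) to at least one strong pixel. strong is assumed to imply weak.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(const LogicalMatrix& strong,
                             const LogicalMatrix& weak) {
  const int H = strong.nrow(), W = strong.ncol();
  LogicalMatrix out(H, W);
  std::vector<int> qr, qc;
  qr.reserve(H * W); qc.reserve(H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (strong(r, c)) {
        out(r, c) = true;
        qr.push_back(r); qc.push_back(c);
      }
  for (size_t head = 0; head < qr.size(); ++head) {
    const int cr = qr[head], cc = qc[head];
    for (int k = 0; k < 8; ++k) {
      const int nr = cr + DR8[k], nc = cc + DC8[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!out(nr, nc) && weak(nr, nc)) {
        out(nr, nc) = true;
        qr.push_back(nr); qc.push_back(nc);
      }
    }
  }
  return out;
}

// Binary dilation (erode = false) or erosion (erode = true) with an
// arbitrary structuring element given as offset vectors (dr, dc).
// Erosion treats out-of-bounds neighbours as background.
// [[Rcpp::export]]
LogicalMatrix cpp_morph(const LogicalMatrix& mask, const IntegerVector& dr,
                        const IntegerVector& dc, bool erode) {
  const int H = mask.nrow(), W = mask.ncol(), n = dr.size();
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      bool acc = erode;
      for (int k = 0; k < n; ++k) {
        const int nr = r + dr[k], nc = c + dc[k];
        const bool v =
            (nr >= 0 && nr < H && nc >= 0 && nc < W) ? (bool)mask(nr, nc)
                                                     : false;
        if (erode) {
          if (!v) { acc = false; break; }
        } else {
          if (v) { acc = true; break; }
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}
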