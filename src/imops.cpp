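// Raster operators for mask post-processing and the annotation data layer.
// Matrices are R column-major, H x W; masks are 0/1 integer matrices.
#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// ---- resizing ------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericVector cpp_resize_bilinear(NumericVector img, int hin, int win,
                                  int channels, int hout, int wout) {
  NumericVector out((size_t)hout * wout * channels);
  const double sh = (double)hin / hout, sw = (double)win / wout;
  const size_t plane_in = (size_t)hin * win, plane_out = (size_t)hout * wout;
  for (int ch = 0; ch < channels; ++ch) {
    const double* src = img.begin() + ch * plane_in;
    double* dst = out.begin() + ch * plane_out;
    for (int c = 0; c < wout; ++c) {
      double x = (c + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(x);
      double fx = x - x0;
      int x1 = x0 + 1;
      if (x0 < 0) { x0 = 0; x1 = 0; fx = 0; }
      if (x1 >= win) { x1 = win - 1; if (x0 >= win) x0 = win - 1; }
      for (int r = 0; r < hout; ++r) {
        double y = (r + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(y);
        double fy = y - y0;
        int y1 = y0 + 1;
        if (y0 < 0) { y0 = 0; y1 = 0; fy = 0; }
        if (y1 >= hin) { y1 = hin - 1; if (y0 >= hin) y0 = hin - 1; }
        double v00 = src[(size_t)x0 * hin + y0], v01 = src[(size_t)x1 * hin + y0];
        double v10 = src[(size_t)x0 * hin + y1], v11 = src[(size_t)x1 * hin + y1];
        dst[(size_t)c * hout + r] =
            (1 - fy) * ((1 - fx) * v00 + fx * v01) +
            fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_nearest")]]
NumericVector cpp_resize_nearest(NumericVector img, int hin, int win,
                                 int channels, int hout, int wout) {
  NumericVector out((size_t)hout * wout * channels);
  const double sh = (double)hin / hout, sw = (double)win / wout;
  const size_t plane_in = (size_t)hin * win, plane_out = (size_t)hout * wout;
  for (int ch = 0; ch < channels; ++ch) {
    const double* src = img.begin() + ch * plane_in;
    double* dst = out.begin() + ch * plane_out;
    for (int c = 0; c < wout; ++c) {
      int x = (int)std::floor((c + 0.5) * sw);
      if (x >= win) x = win - 1;
      for (int r = 0; r < hout; ++r) {
        int y = (int)std::floor((r + 0.5) * sh);
        if (y >= hin) y = hin - 1;
        dst[(size_t)c * hout + r] = src[(size_t)x * hin + y];
      }
    }
  }
  return out;
}

// box (area-average) resampling: each output pixel is the mean of the input
// region it covers; the right choice when shrinking binary masks
// [[Rcpp::export(name = ".cpp_resize_area")]]
NumericVector cpp_resize_area(NumericVector img, int hin, int win,
                              int channels, int hout, int wout) {
  NumericVector out((size_t)hout * wout * channels);
  const double sh = (double)hin / hout, sw = (double)win / wout;
  const size_t plane_in = (size_t)hin * win, plane_out = (size_t)hout * wout;
  for (int ch = 0; ch < channels; ++ch) {
    const double* src = img.begin() + ch * plane_in;
    double* dst = out.begin() + ch * plane_out;
    for (int c = 0; c < wout; ++c) {
      double x0 = c * sw, x1 = (c + 1) * sw;
      int cx0 = (int)std::floor(x0), cx1 = std::min(win, (int)std::ceil(x1));
      for (int r = 0; r < hout; ++r) {
        double y0 = r * sh, y1 = (r + 1) * sh;
        int cy0 = (int)std::floor(y0), cy1 = std::min(hin, (int)std::ceil(y1));
        double acc = 0.0, wsum = 0.0;
        for (int cc = cx0; cc < cx1; ++cc) {
          double wx = std::min(x1, (double)cc + 1) - std::max(x0, (double)cc);
          for (int rr = cy0; rr < cy1; ++rr) {
            double wy =
                std::min(y1, (double)rr + 1) - std::max(y0, (double)rr);
            acc += wx * wy * src[(size_t)cc * hin + rr];
            wsum += wx * wy;
          }
        }
        dst[(size_t)c * hout + r] = wsum > 0 ? acc / wsum : 0.0;
      }
    }
  }
  return out;
}

// ---- morphology ----------------------------------------------------------

static std::vector<std::pair<int, int> > disk_offsets(int radius) {
  std::vector<std::pair<int, int> > off;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) off.push_back({dr, dc});
  return off;
}

// [[Rcpp::export(name = ".cpp_dilate")]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  auto off = disk_offsets(radius);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int v = 0;
      for (auto& o : off) {
        int rr = r + o.first, cc = c + o.second;
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) {
          v = 1;
          break;
        }
      }
      out(r, c) = v;
    }
  return out;
}

// out-of-bounds treated as foreground so closing stays extensive at borders
// [[Rcpp::export(name = ".cpp_erode")]]
IntegerMatrix cpp_erode(IntegerMatrix mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  auto off = disk_offsets(radius);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int v = 1;
      for (auto& o : off) {
        int rr = r + o.first, cc = c + o.second;
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && !mask(rr, cc)) {
          v = 0;
          break;
        }
      }
      out(r, c) = v;
    }
  return out;
}

// fill interior holes: background 4-connected to the border stays background
// [[Rcpp::export(name = ".cpp_fill_holes")]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix reach(H, W);  // background reachable from border
  std::queue<std::pair<int, int> > q;
  auto push = [&](int r, int c) {
    if (r >= 0 && r < H && c >= 0 && c < W && !mask(r, c) && !reach(r, c)) {
      reach(r, c) = 1;
      q.push({r, c});
    }
  };
  for (int r = 0; r < H; ++r) { push(r, 0); push(r, W - 1); }
  for (int c = 0; c < W; ++c) { push(0, c); push(H - 1, c); }
  while (!q.empty()) {
    auto p = q.front();
    q.pop();
    push(p.first - 1, p.second);
    push(p.first + 1, p.second);
    push(p.first, p.second - 1);
    push(p.first, p.second + 1);
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) out(r, c) = (mask(r, c) || !reach(r, c)) ? 1 : 0;
  return out;
}

// ---- connected components ------------------------------------------------

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      lab(r0, c0) = ++next;
      stack.push_back(c0 * H + r0);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int k = 0; k < nd; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc) &&
              !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(cc * H + rr);
          }
        }
      }
    }
  lab.attr("n_components") = next;
  return lab;
}

// ---- contour tracing along pixel cracks ----------------------------------
// Directed boundary edges with foreground on the left; at saddle corners the
// right turn is preferred, which keeps diagonally-touching pixels in one loop.
// Corner (i, j) in 0-based crack coordinates maps to R coords (i+0.5, j+0.5).

// [[Rcpp::export(name = ".cpp_trace_contours")]]
List cpp_trace_contours(IntegerMatrix lab, int n_components) {
  int H = lab.nrow(), W = lab.ncol();
  List out(n_components);
  // directions: 0=E(0,+1) 1=S(+1,0) 2=W(0,-1) 3=N(-1,0)
  static const int DR[4] = {0, 1, 0, -1};
  static const int DC[4] = {1, 0, -1, 0};
  for (int comp = 1; comp <= n_components; ++comp) {
    // collect directed edges keyed by start corner: edge_dir[corner] bitmask
    std::vector<std::pair<int, int> > starts;  // (corner, dir)
    std::vector<unsigned char> edges((size_t)(H + 1) * (W + 1), 0);
    auto corner = [&](int i, int j) { return i * (W + 1) + j; };
    long n_edges = 0;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        if (lab(r, c) != comp) continue;
        bool top = (r == 0) || lab(r - 1, c) != comp;
        bool bottom = (r == H - 1) || lab(r + 1, c) != comp;
        bool left = (c == 0) || lab(r, c - 1) != comp;
        bool right = (c == W - 1) || lab(r, c + 1) != comp;
        if (top) { edges[corner(r, c + 1)] |= 1 << 2; ++n_edges; }        // W
        if (bottom) { edges[corner(r + 1, c)] |= 1 << 0; ++n_edges; }     // E
        if (left) { edges[corner(r, c)] |= 1 << 1; ++n_edges; }           // S
        if (right) { edges[corner(r + 1, c + 1)] |= 1 << 3; ++n_edges; }  // N
      }
    // walk loops; keep the longest as the outer contour
    std::vector<double> best_r, best_c;
    for (int c = 0; c <= W && n_edges > 0; ++c)
      for (int r = 0; r <= H && n_edges > 0; ++r) {
        int start = corner(r, c);
        while (edges[start]) {
          int dir = 0;
          while (!(edges[start] & (1 << dir))) ++dir;
          std::vector<double> pr, pc;
          int cur = start, d = dir;
          do {
            edges[cur] &= ~(1 << d);
            --n_edges;
            int ci = cur / (W + 1), cj = cur % (W + 1);
            pr.push_back(ci + 0.5);
            pc.push_back(cj + 0.5);
            cur = corner(ci + DR[d], cj + DC[d]);
            // prefer right turn, then straight, then left turn
            int cand[3] = {(d + 1) & 3, d, (d + 3) & 3};
            int nd = -1;
            for (int k = 0; k < 3; ++k)
              if (edges[cur] & (1 << cand[k])) { nd = cand[k]; break; }
            if (nd < 0) break;  // loop closed (back at start with no edges)
            d = nd;
          } while (true);
          if (pr.size() > best_r.size()) { best_r = pr; best_c = pc; }
        }
      }
    NumericMatrix poly((int)best_r.size(), 2);
    for (size_t k = 0; k < best_r.size(); ++k) {
      poly(k, 0) = best_r[k];
      poly(k, 1) = best_c[k];
    }
    colnames(poly) = CharacterVector::create("row", "col");
    out[comp - 1] = poly;
  }
  return out;
}

// ---- polygon rasterization (even-odd scanline, pixel centers) ------------

// polys: list of n x 2 matrices (row, col), R 1-based pixel-center coords.
// [[Rcpp::export(name = ".cpp_rasterize_polygons")]]
IntegerMatrix cpp_rasterize_polygons(List polys, int H, int W) {
  IntegerMatrix out(H, W);
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix poly = polys[p];
    int n = poly.nrow();
    if (n < 3) stop("polygon with fewer than 3 vertices");
    double rmin = poly(0, 0), rmax = poly(0, 0);
    for (int k = 1; k < n; ++k) {
      rmin = std::min(rmin, poly(k, 0));
      rmax = std::max(rmax, poly(k, 0));
    }
    int r0 = std::max(1, (int)std::ceil(rmin));
    int r1 = std::min(H, (int)std::floor(rmax));
    std::vector<double> xs;
    for (int r = r0; r <= r1; ++r) {
      xs.clear();
      double y = r;
      for (int k = 0; k < n; ++k) {
        int k2 = (k + 1) % n;
        double y1 = poly(k, 0), y2 = poly(k2, 0);
        double x1 = poly(k, 1), x2 = poly(k2, 1);
        if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y))
          xs.push_back(x1 + (y - y1) / (y2 - y1) * (x2 - x1));
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        int c0 = std::max(1, (int)std::ceil(xs[k]));
        int c1 = std::min(W, (int)std::floor(xs[k + 1]));
        // half-open [x_left, x_right): pixel centre exactly on the right
        // crossing stays outside, matching the scanline convention
        if (xs[k + 1] == (double)c1 && c1 >= c0) --c1;
        for (int c = c0; c <= c1; ++c) out(r - 1, c - 1) = 1;
      }
    }
  }
  return out;
}
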