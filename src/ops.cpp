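#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are column-major H x W x C arrays (R array layout).
// im2col lowers a stride-1 "same" convolution with odd kernel k to a GEMM:
// rows index output pixels (h fastest), columns index (ky, kx, c).

// [[Rcpp::export]]
NumericMatrix pa_im2col(NumericVector x, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericMatrix out(H * W, k * k * C);
  double *po = out.begin();
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        int col = ky + k * kx + k * k * c;
        double *dst = po + (R_xlen_t)col * H * W;
        for (int w = 0; w < W; ++w) {
          int sw = w + kx - pad;
          if (sw < 0 || sw >= W) continue;
          const double *srccol = px + (R_xlen_t)c * H * W + (R_xlen_t)sw * H;
          int h0 = std::max(0, pad - ky);
          int h1 = std::min(H, H + pad - ky);
          for (int h = h0; h < h1; ++h)
            dst[h + H * w] = srccol[h + ky - pad];
        }
      }
    }
  }
  return out;
}

// Adjoint of pa_im2col: accumulate column gradients back onto the input grid.

// [[Rcpp::export]]
NumericVector pa_col2im(NumericMatrix cols, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C);
  double *po = out.begin();
  const double *pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        int col = ky + k * kx + k * k * c;
        const double *src = pc + (R_xlen_t)col * H * W;
        for (int w = 0; w < W; ++w) {
          int sw = w + kx - pad;
          if (sw < 0 || sw >= W) continue;
          double *dstcol = po + (R_xlen_t)c * H * W + (R_xlen_t)sw * H;
          int h0 = std::max(0, pad - ky);
          int h1 = std::min(H, H + pad - ky);
          for (int h = h0; h < h1; ++h)
            dstcol[h + ky - pad] += src[h + H * w];
        }
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling; H and W must be even. Returns pooled map and the
// 1-based linear argmax indices needed by the backward pass.

// [[Rcpp::export]]
List pa_maxpool2(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t base = (R_xlen_t)c * H * W;
        double best = -1e300; R_xlen_t bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            R_xlen_t i = base + (R_xlen_t)(2 * wo + dx) * H + (2 * ho + dy);
            if (px[i] > best) { best = px[i]; bi = i; }
          }
        }
        R_xlen_t o = (R_xlen_t)c * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        out[o] = best; idx[o] = (int)(bi + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pa_maxpool2_bwd(NumericVector dout, IntegerVector idx,
                              int H, int W, int C) {
  NumericVector dx((R_xlen_t)H * W * C);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[idx[i] - 1] += dout[i];
  return dx;
}

// Nearest-neighbour 2x upsampling of an H x W x C map.

// [[Rcpp::export]]
NumericVector pa_upsample2(NumericVector x, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  const double *px = x.begin(); double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        po[(R_xlen_t)c * Ho * Wo + (R_xlen_t)wo * Ho + ho] =
          px[(R_xlen_t)c * H * W + (R_xlen_t)(wo / 2) * H + ho / 2];
  return out;
}

// Adjoint of nearest 2x upsampling: sum each 2x2 block.

// [[Rcpp::export]]
NumericVector pa_upsample2_bwd(NumericVector dout, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)H * W * C);
  const double *pd = dout.begin(); double *po = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        po[(R_xlen_t)c * H * W + (R_xlen_t)(wo / 2) * H + ho / 2] +=
          pd[(R_xlen_t)c * Ho * Wo + (R_xlen_t)wo * Ho + ho];
  return dx;
}

static bool on_segment(double px, double py, double x1, double y1,
                       double x2, double y2) {
  double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  if (std::fabs(cross) > 1e-9) return false;
  if (px < std::min(x1, x2) - 1e-9 || px > std::max(x1, x2) + 1e-9) return false;
  if (py < std::min(y1, y2) - 1e-9 || py > std::max(y1, y2) + 1e-9) return false;
  return true;
}

// Even-odd rasterization of one polygon onto an H x W pixel grid.
// Pixel (ix, iy) is tested at the point (ix, iy), 0-based, x rightward /
// y downward; points on a polygon edge count as inside.
// verts: n x 2 matrix of (x, y). Returns H x W logical matrix.

// [[Rcpp::export]]
LogicalMatrix pa_polygon_mask(NumericMatrix verts, int H, int W) {
  int n = verts.nrow();
  LogicalMatrix out(H, W);
  double xmin = verts(0, 0), xmax = xmin, ymin = verts(0, 1), ymax = ymin;
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, verts(i, 0)); xmax = std::max(xmax, verts(i, 0));
    ymin = std::min(ymin, verts(i, 1)); ymax = std::max(ymax, verts(i, 1));
  }
  int x0 = std::max(0, (int)std::floor(xmin)), x1 = std::min(W - 1, (int)std::ceil(xmax));
  int y0 = std::max(0, (int)std::floor(ymin)), y1 = std::min(H - 1, (int)std::ceil(ymax));
  for (int iy = y0; iy <= y1; ++iy) {
    for (int ix = x0; ix <= x1; ++ix) {
      double px = ix, py = iy;
      bool inside = false, boundary = false;
      for (int i = 0; i < n && !boundary; ++i) {
        int j = (i + 1) % n;
        double xa = verts(i, 0), ya = verts(i, 1);
        double xb = verts(j, 0), yb = verts(j, 1);
        if (on_segment(px, py, xa, ya, xb, yb)) { boundary = true; break; }
        if ((ya > py) != (yb > py)) {
          double xi = xa + (py - ya) / (yb - ya) * (xb - xa);
          if (px < xi) inside = !inside;
        }
      }
      if (inside || boundary) out(iy, ix) = true;
    }
  }
  return out;
}
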