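// Sub-window evaluation of the per-coefficient remapped Laplacian bands.
//
// For the band coefficient at pyramid level lv (0-based) and level position
// (x, y), only a bounded full-resolution neighbourhood of the input can
// influence the value: each blur-decimate step has a 5-tap footprint, so the
// required radius is O(2^lv).  The window start is snapped to the global
// 2^(lv+1) decimation grid so the sub-window's sample lattice coincides with
// the full image's, and the window is clipped to the image; where clipping
// happens at a true image border the reflect-101 padding of the sub-window
// reproduces the full-image padding exactly, so the centre coefficient
// equals the exhaustive reference up to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double W5[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};

// Small column-major matrix buffer.
struct Mat {
  int nr, nc;
  std::vector<double> v;
  Mat() : nr(0), nc(0) {}
  Mat(int r, int c) : nr(r), nc(c), v((size_t)r * c, 0.0) {}
  double& at(int r, int c) { return v[(size_t)c * nr + r]; }
  double at(int r, int c) const { return v[(size_t)c * nr + r]; }
};

// reflect-101 index into [0, n-1]
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  int m = i % p;
  if (m < 0) m += p;
  return (m < n) ? m : p - m;
}

// separable 5-tap convolution with reflect-101 boundaries, kernel scale s
static Mat conv5(const Mat& x, double s) {
  Mat tmp(x.nr, x.nc), out(x.nr, x.nc);
  for (int c = 0; c < x.nc; ++c)
    for (int r = 0; r < x.nr; ++r) {
      double acc = 0.0;
      for (int d = -2; d <= 2; ++d) acc += W5[d + 2] * x.at(refl(r + d, x.nr), c);
      tmp.at(r, c) = acc;
    }
  for (int c = 0; c < x.nc; ++c)
    for (int r = 0; r < x.nr; ++r) {
      double acc = 0.0;
      for (int d = -2; d <= 2; ++d) acc += W5[d + 2] * tmp.at(r, refl(c + d, x.nc));
      out.at(r, c) = acc * s;
    }
  return out;
}

// blur then keep samples 0, 2, 4, ... (ceil-halving)
static Mat pyr_down(const Mat& x) {
  Mat g = conv5(x, 1.0);
  Mat out((x.nr + 1) / 2, (x.nc + 1) / 2);
  for (int c = 0; c < out.nc; ++c)
    for (int r = 0; r < out.nr; ++r) out.at(r, c) = g.at(2 * r, 2 * c);
  return out;
}

// zero-insertion upsample to (th, tw), convolved with 4x kernel (2x per axis)
static Mat pyr_up(const Mat& x, int th, int tw) {
  Mat y(th, tw);
  for (int c = 0; c < x.nc; ++c)
    for (int r = 0; r < x.nr; ++r) y.at(2 * r, 2 * c) = x.at(r, c);
  return conv5(y, 4.0);
}

// [[Rcpp::export(name = "local_laplacian_bands")]]
List local_laplacian_bands(NumericMatrix image, List gauss_levels,
                           List sigma_fields, List mf_fields) {
  const int n_levels = gauss_levels.size();
  const int H = image.nrow(), W = image.ncol();
  List bands(n_levels - 1);

  for (int lv = 0; lv < n_levels - 1; ++lv) {
    NumericMatrix gl = gauss_levels[lv];
    NumericMatrix sf = sigma_fields[lv];
    NumericMatrix mf = mf_fields[lv];
    const int lh = gl.nrow(), lw = gl.ncol();
    NumericMatrix out(lh, lw);
    const int step = 1 << lv;          // full-res stride of one level-lv pixel
    const int snap = step * 2;         // decimation lattice down to level lv+1
    const int rad = 10 * step + 4;     // safe footprint radius (full res)

    for (int y = 0; y < lw; ++y) {
      const int cy = step * y;         // 0-based full-res centre column
      int sc = cy - rad; if (sc < 0) sc = 0; sc -= sc % snap;
      int ec = cy + rad; if (ec > W - 1) ec = W - 1;
      const int wc = ec - sc + 1;
      for (int x = 0; x < lh; ++x) {
        const int cx = step * x;
        int sr = cx - rad; if (sr < 0) sr = 0; sr -= sr % snap;
        int er = cx + rad; if (er > H - 1) er = H - 1;
        const int wr = er - sr + 1;

        const double g = gl(x, y);
        const double s2 = 2.0 * sf(x, y) * sf(x, y);
        const double m = mf(x, y);

        // remapped sub-window
        Mat win(wr, wc);
        for (int c = 0; c < wc; ++c)
          for (int r = 0; r < wr; ++r) {
            const double i0 = image(sr + r, sc + c);
            const double d = i0 - g;
            win.at(r, c) = i0 - m * d * std::exp(-d * d / s2);
          }

        // down to level lv, band = G_lv - u(G_{lv+1})
        Mat glv = win;
        for (int j = 0; j < lv; ++j) glv = pyr_down(glv);
        Mat gnext = pyr_down(glv);
        Mat up = pyr_up(gnext, glv.nr, glv.nc);

        const int lx = (cx - sr) >> lv;   // centre in level-lv local coords
        const int ly = (cy - sc) >> lv;
        out(x, y) = glv.at(lx, ly) - up.at(lx, ly);
      }
    }
    bands[lv] = out;
  }
  return bands;
}
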