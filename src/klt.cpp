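// Pyramidal Lucas-Kanade point propagation with forward-backward rejection.
// Matrices are R numeric matrices (column-major); coordinates are 0-based
// (row, col) with pixel centres at integer positions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// lightweight view over an R matrix (column-major)
struct MatView {
  const double *p;
  int nr, nc;
  explicit MatView(const NumericMatrix &m) : p(m.begin()), nr(m.nrow()), nc(m.ncol()) {}
  inline double at(int r, int c) const { return p[r + (size_t)c * nr]; }
};

static inline double bilinear(const MatView &img, double r, double c) {
  const int nr = img.nr, nc = img.nc;
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)r, c0 = (int)c;
  if (r0 > nr - 2) r0 = nr - 2 < 0 ? 0 : nr - 2;
  if (c0 > nc - 2) c0 = nc - 2 < 0 ? 0 : nc - 2;
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return img.at(r0, c0) * (1 - fr) * (1 - fc) + img.at(r1, c0) * fr * (1 - fc) +
         img.at(r0, c1) * (1 - fr) * fc + img.at(r1, c1) * fr * fc;
}

// sample a (W+2) x (W+2) padded window centred at (pr, pc), column-major
static void sample_window(const MatView &img, double pr, double pc, int wh,
                          std::vector<double> &buf) {
  const int Wp = 2 * wh + 3;
  // fast path: fully interior windows use fixed-weight bilinear rows
  if (pr - wh - 1 >= 0 && pc - wh - 1 >= 0 &&
      pr + wh + 2 <= img.nr - 1 && pc + wh + 2 <= img.nc - 1) {
    const int rb = (int)(pr - wh - 1), cb = (int)(pc - wh - 1);
    const double fr = (pr - wh - 1) - rb, fc = (pc - wh - 1) - cb;
    const double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
                 w01 = (1 - fr) * fc, w11 = fr * fc;
    for (int j = 0; j < Wp; ++j) {
      const double *c0 = img.p + (size_t)(cb + j) * img.nr + rb;
      const double *c1 = c0 + img.nr;
      double *out = &buf[(size_t)j * Wp];
      for (int i = 0; i < Wp; ++i)
        out[i] = w00 * c0[i] + w10 * c0[i + 1] + w01 * c1[i] + w11 * c1[i + 1];
    }
  } else {
    for (int j = 0; j < Wp; ++j)
      for (int i = 0; i < Wp; ++i)
        buf[(size_t)j * Wp + i] = bilinear(img, pr + i - wh - 1, pc + j - wh - 1);
  }
}

// 2x2 block-mean decimation (sufficient smoothing for LK pyramids)
static NumericMatrix downsample2(const NumericMatrix &img) {
  int nr = img.nrow() / 2, nc = img.ncol() / 2;
  if (nr < 1) nr = 1;
  if (nc < 1) nc = 1;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int r0 = 2 * i, c0 = 2 * j;
      int r1 = r0 + 1 < img.nrow() ? r0 + 1 : r0;
      int c1 = c0 + 1 < img.ncol() ? c0 + 1 : c0;
      out(i, j) = 0.25 * (img(r0, c0) + img(r1, c0) + img(r0, c1) + img(r1, c1));
    }
  }
  return out;
}

static std::vector<NumericMatrix> build_pyramid(const NumericMatrix &img, int levels) {
  std::vector<NumericMatrix> pyr;
  pyr.push_back(img);
  for (int l = 1; l < levels; ++l) {
    const NumericMatrix &prev = pyr.back();
    if (prev.nrow() < 8 || prev.ncol() < 8) break;
    pyr.push_back(downsample2(prev));
  }
  return pyr;
}

// Track one point from pyramid I to pyramid J. Returns success flag and
// writes the new position into (r_out, c_out).
static bool track_point(const std::vector<MatView> &pyrI,
                        const std::vector<MatView> &pyrJ,
                        double r0, double c0, int win_half, int max_iter,
                        double eps, double &r_out, double &c_out) {
  const int levels = (int)pyrI.size();
  double gr = 0.0, gc = 0.0;  // displacement guess carried across levels

  for (int L = levels - 1; L >= 0; --L) {
    const MatView &I = pyrI[L];
    const MatView &J = pyrJ[L];
    const double scale = (double)(1 << L);
    const double pr = r0 / scale, pc = c0 / scale;

    int wh = win_half;
    int mindim = I.nr < I.nc ? I.nr : I.nc;
    if (2 * wh + 3 > mindim) wh = (mindim - 3) / 2;
    if (wh < 2) wh = 2;
    const int W = 2 * wh + 1, n = W * W, Wp = W + 2;

    // one padded sample of the template window; gradients by central
    // differences inside the buffer
    std::vector<double> buf((size_t)Wp * Wp), Iv(n), Gr(n), Gc(n), Jbuf((size_t)Wp * Wp);
    sample_window(I, pr, pc, wh, buf);
    double S11 = 0, S12 = 0, S22 = 0;
    int k = 0;
    for (int j = 1; j <= W; ++j) {
      for (int i = 1; i <= W; ++i, ++k) {
        Iv[k] = buf[(size_t)j * Wp + i];
        Gr[k] = 0.5 * (buf[(size_t)j * Wp + i + 1] - buf[(size_t)j * Wp + i - 1]);
        Gc[k] = 0.5 * (buf[(size_t)(j + 1) * Wp + i] - buf[(size_t)(j - 1) * Wp + i]);
        S11 += Gr[k] * Gr[k];
        S12 += Gr[k] * Gc[k];
        S22 += Gc[k] * Gc[k];
      }
    }
    const double det = S11 * S22 - S12 * S12;
    const double tr = S11 + S22;
    const double min_eig = 0.5 * (tr - std::sqrt(tr * tr - 4.0 * det));
    if (!(det > 0) || min_eig / n < 1e-8) return false;

    double vr = 0.0, vc = 0.0;
    for (int it = 0; it < max_iter; ++it) {
      double b1 = 0, b2 = 0;
      sample_window(J, pr + gr + vr, pc + gc + vc, wh, Jbuf);
      k = 0;
      for (int j = 1; j <= W; ++j) {
        for (int i = 1; i <= W; ++i, ++k) {
          double e = Iv[k] - Jbuf[(size_t)j * Wp + i];
          b1 += e * Gr[k];
          b2 += e * Gc[k];
        }
      }
      const double d_r = (S22 * b1 - S12 * b2) / det;
      const double d_c = (S11 * b2 - S12 * b1) / det;
      vr += d_r;
      vc += d_c;
      if (std::fabs(d_r) < eps && std::fabs(d_c) < eps) break;
      if (std::fabs(vr) > 2.0 * mindim || std::fabs(vc) > 2.0 * mindim) return false;
    }
    if (L > 0) {
      gr = 2.0 * (gr + vr);
      gc = 2.0 * (gc + vc);
    } else {
      gr += vr;
      gc += vc;
    }
  }
  r_out = r0 + gr;
  c_out = c0 + gc;
  const MatView &base = pyrI[0];
  if (r_out < 0 || c_out < 0 || r_out > base.nr - 1.0 || c_out > base.nc - 1.0)
    return false;
  return true;
}

// [[Rcpp::export(name = ".klt_propagate_cpp")]]
List klt_propagate_cpp(NumericMatrix prev, NumericMatrix next_, NumericMatrix pts,
                       int levels = 3, int win_half = 15, int max_iter = 20,
                       double eps = 0.01, double fb_err = 2.0) {
  if (prev.nrow() != next_.nrow() || prev.ncol() != next_.ncol())
    stop("frame shapes differ");
  std::vector<NumericMatrix> pyrI_m = build_pyramid(prev, levels);
  std::vector<NumericMatrix> pyrJ_m = build_pyramid(next_, levels);
  std::vector<MatView> pyrI(pyrI_m.begin(), pyrI_m.end());
  std::vector<MatView> pyrJ(pyrJ_m.begin(), pyrJ_m.end());
  const int n = pts.nrow();
  NumericMatrix out(n, 2);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    double r1, c1;
    bool fwd = track_point(pyrI, pyrJ, pts(i, 0), pts(i, 1), win_half, max_iter,
                           eps, r1, c1);
    bool good = fwd;
    if (fwd && fb_err > 0) {
      double rb, cb;
      bool bwd = track_point(pyrJ, pyrI, r1, c1, win_half, max_iter, eps, rb, cb);
      double d = std::sqrt((rb - pts(i, 0)) * (rb - pts(i, 0)) +
                           (cb - pts(i, 1)) * (cb - pts(i, 1)));
      good = bwd && d <= fb_err;
    }
    ok[i] = good;
    out(i, 0) = good ? r1 : NA_REAL;
    out(i, 1) = good ? c1 : NA_REAL;
  }
  return List::create(_["points"] = out, _["status"] = ok);
}
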