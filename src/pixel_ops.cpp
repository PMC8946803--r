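// Pixel-level kernels for the imaging pipeline.  These are single-pass,
// allocation-light versions of operations that would otherwise create many
// large temporaries in R (frames are multi-megapixel).

#include <Rcpp.h>
using namespace Rcpp;

// Gather the 25 bands out of the 5x5 mosaic: band b at (i,j) comes from
// mosaic (5i + roff_b, 5j + coff_b).  Returns an R x C x nb array.
// [[Rcpp::export(name = ".demosaic_core")]]
NumericVector demosaic_core(const NumericMatrix& frame,
                            const IntegerVector& roff,
                            const IntegerVector& coff, int R, int C) {
  const int nb = roff.size();
  NumericVector cube(static_cast<R_xlen_t>(R) * C * nb);
  for (int b = 0; b < nb; ++b) {
    const R_xlen_t base = static_cast<R_xlen_t>(R) * C * b;
    for (int j = 0; j < C; ++j) {
      const int fc = 5 * j + coff[b];
      for (int i = 0; i < R; ++i) {
        cube[base + j * R + i] = frame(5 * i + roff[b], fc);
      }
    }
  }
  cube.attr("dim") = IntegerVector::create(R, C, nb);
  return cube;
}

// Scatter a cube back into mosaic layout (inverse of demosaic on exact grids).
// [[Rcpp::export(name = ".remosaic_core")]]
NumericMatrix remosaic_core(const NumericVector& cube,
                            const IntegerVector& roff,
                            const IntegerVector& coff, int R, int C) {
  const int nb = roff.size();
  NumericMatrix frame(5 * R, 5 * C);
  for (int b = 0; b < nb; ++b) {
    const R_xlen_t base = static_cast<R_xlen_t>(R) * C * b;
    for (int j = 0; j < C; ++j) {
      const int fc = 5 * j + coff[b];
      for (int i = 0; i < R; ++i) {
        frame(5 * i + roff[b], fc) = cube[base + j * R + i];
      }
    }
  }
  return frame;
}

// (raw - dark) / (white - dark) with denominator guard; flags pixels whose
// denominator fails on any band.
// [[Rcpp::export(name = ".calibrate_core")]]
List calibrate_core(const NumericVector& raw, const NumericVector& white,
                    const NumericVector& dark, double eps,
                    R_xlen_t npx, int nb) {
  NumericVector out(npx * nb);
  LogicalVector invalid(npx);
  for (int b = 0; b < nb; ++b) {
    const R_xlen_t base = npx * b;
    for (R_xlen_t p = 0; p < npx; ++p) {
      const double den = white[base + p] - dark[base + p];
      if (den <= eps) {
        out[base + p] = 0.0;
        invalid[p] = TRUE;
      } else {
        out[base + p] = (raw[base + p] - dark[base + p]) / den;
      }
    }
  }
  return List::create(_["data"] = out, _["invalid"] = invalid);
}

// Per-pixel max and mean over bands (for glare/background thresholding).
// [[Rcpp::export(name = ".band_stats_core")]]
List band_stats_core(const NumericVector& cube, R_xlen_t npx, int nb) {
  NumericVector mx(npx, R_NegInf), mn(npx, 0.0);
  for (int b = 0; b < nb; ++b) {
    const R_xlen_t base = npx * b;
    for (R_xlen_t p = 0; p < npx; ++p) {
      const double v = cube[base + p];
      if (v > mx[p]) mx[p] = v;
      mn[p] += v;
    }
  }
  for (R_xlen_t p = 0; p < npx; ++p) mn[p] /= nb;
  return List::create(_["max"] = mx, _["mean"] = mn);
}

// Binary erosion of V by a (2m+1)^2 square (outside the image = 0), via an
// integral image.
// [[Rcpp::export(name = ".erode_core")]]
LogicalMatrix erode_core(const LogicalMatrix& V, int m) {
  const int R = V.nrow(), C = V.ncol();
  std::vector<double> S(static_cast<size_t>(R + 1) * (C + 1), 0.0);
  auto at = [&](int i, int j) -> double& {
    return S[static_cast<size_t>(j) * (R + 1) + i];
  };
  for (int j = 1; j <= C; ++j)
    for (int i = 1; i <= R; ++i)
      at(i, j) = (V(i - 1, j - 1) ? 1.0 : 0.0) +
                 at(i - 1, j) + at(i, j - 1) - at(i - 1, j - 1);
  const double full = static_cast<double>(2 * m + 1) * (2 * m + 1);
  LogicalMatrix out(R, C);
  for (int j = 1; j <= C; ++j) {
    if (j - m < 1 || j + m > C) continue;
    for (int i = 1; i <= R; ++i) {
      if (i - m < 1 || i + m > R) continue;
      const double cnt = at(i + m, j + m) - at(i - m - 1, j + m) -
                         at(i + m, j - m - 1) + at(i - m - 1, j - m - 1);
      out(i - 1, j - 1) = (cnt == full);
    }
  }
  return out;
}

// Even-odd point-in-polygon, vectorized over points.
// [[Rcpp::export(name = ".pip_core")]]
LogicalVector pip_core(const NumericVector& px, const NumericVector& py,
                       const NumericMatrix& poly) {
  const int n = px.size(), nv = poly.nrow();
  LogicalVector inside(n);
  for (int t = 0; t < n; ++t) {
    bool in = false;
    int j = nv - 1;
    for (int i = 0; i < nv; ++i) {
      const double xi = poly(i, 0), yi = poly(i, 1);
      const double xj = poly(j, 0), yj = poly(j, 1);
      if ((yi > py[t]) != (yj > py[t]) &&
          px[t] < (xj - xi) * (py[t] - yi) / (yj - yi) + xi) {
        in = !in;
      }
      j = i;
    }
    inside[t] = in;
  }
  return inside;
}

// Evaluate a fitted 2-D thin-plate spline (kernel r^2 log r) at pts.
// [[Rcpp::export(name = ".tps_eval_core")]]
NumericMatrix tps_eval_core(const NumericMatrix& pts,
                            const NumericMatrix& centers,
                            const NumericMatrix& W, const NumericMatrix& A) {
  const int n = pts.nrow(), m = centers.nrow();
  NumericMatrix out(n, 2);
  for (int t = 0; t < n; ++t) {
    const double x = pts(t, 0), y = pts(t, 1);
    double o0 = A(0, 0) + A(1, 0) * x + A(2, 0) * y;
    double o1 = A(0, 1) + A(1, 1) * x + A(2, 1) * y;
    for (int k = 0; k < m; ++k) {
      const double dx = x - centers(k, 0), dy = y - centers(k, 1);
      const double r2 = dx * dx + dy * dy;
      if (r2 > 0.0) {
        const double u = 0.5 * r2 * std::log(r2);  // r^2 log r
        o0 += u * W(k, 0);
        o1 += u * W(k, 1);
      }
    }
    out(t, 0) = o0;
    out(t, 1) = o1;
  }
  return out;
}

// RGB (0..255) -> HSV with H in [0,180) half-degrees, S and V in [0,255].
// [[Rcpp::export(name = ".rgb_to_hsv_core")]]
NumericMatrix rgb_to_hsv_core(const NumericVector& r, const NumericVector& g,
                              const NumericVector& b) {
  const int n = r.size();
  NumericMatrix out(n, 3);
  for (int t = 0; t < n; ++t) {
    const double mx = std::max(r[t], std::max(g[t], b[t]));
    const double mnv = std::min(r[t], std::min(g[t], b[t]));
    const double d = mx - mnv;
    double h = 0.0;
    if (d > 0.0) {
      if (mx == r[t]) h = (g[t] - b[t]) / d;  // in [-1, 1], no wrap needed
      else if (mx == g[t]) h = (b[t] - r[t]) / d + 2.0;
      else h = (r[t] - g[t]) / d + 4.0;
      h *= 60.0;
      if (h < 0.0) h += 360.0;
    }
    out(t, 0) = h / 2.0;
    out(t, 1) = (mx > 0.0) ? d / mx * 255.0 : 0.0;
    out(t, 2) = mx;
  }
  return out;
}

// Assemble the raw mosaic signal: wsig(i,j) * refl(p, b) scattered to the
// band's mosaic offset, plus the dark-current offset everywhere.
// [[Rcpp::export(name = ".mosaic_render_core")]]
NumericMatrix mosaic_render_core(const NumericMatrix& refl,
                                 const NumericMatrix& wsig,
                                 const IntegerVector& roff,
                                 const IntegerVector& coff, double dark) {
  const int R = wsig.nrow(), C = wsig.ncol(), nb = roff.size();
  NumericMatrix frame(5 * R, 5 * C);
  std::fill(frame.begin(), frame.end(), dark);
  for (int b = 0; b < nb; ++b) {
    for (int j = 0; j < C; ++j) {
      const int fc = 5 * j + coff[b];
      for (int i = 0; i < R; ++i) {
        frame(5 * i + roff[b], fc) = wsig(i, j) * refl(j * R + i, b) + dark;
      }
    }
  }
  return frame;
}

// Replicate each entry of m into a 5x5 block (mosaic expansion of a
// superpixel field), plus a scalar offset.
// [[Rcpp::export(name = ".expand5_core")]]
NumericMatrix expand5_core(const NumericMatrix& m, double add) {
  const int R = m.nrow(), C = m.ncol();
  NumericMatrix out(5 * R, 5 * C);
  for (int j = 0; j < 5 * C; ++j)
    for (int i = 0; i < 5 * R; ++i)
      out(i, j) = m(i / 5, j / 5) + add;
  return out;
}

// Add sensor read noise and optionally quantize to [0, sat] integer counts.
// Operates in place on a freshly created frame; uses R's RNG.
// [[Rcpp::export(name = ".finish_frame_core")]]
NumericMatrix finish_frame_core(NumericMatrix m, double noise_sd, double sat,
                                bool quantize) {
  const R_xlen_t n = m.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    double v = m[t];
    if (noise_sd > 0.0) v += R::rnorm(0.0, noise_sd);
    if (quantize) {
      v = std::round(v);
      if (v < 0.0) v = 0.0;
      if (v > sat) v = sat;
    }
    m[t] = v;
  }
  return m;
}
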