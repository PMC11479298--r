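#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel grid convention (shared with the R side): 0-based continuous
// coordinates, pixel (row i, col j) covers [i, i+1) x [j, j+1) with its
// centre at (y = i + 0.5, x = j + 0.5).

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Render anti-aliased filled disks onto a grey background matrix.
// Coverage per pixel is estimated on a 16x16 subpixel grid (only boundary
// pixels pay for it); the pixel value is the coverage-weighted blend of the
// existing value and the disk grey level.
// [[Rcpp::export]]
NumericMatrix render_disks_cpp(NumericMatrix bg, NumericVector cy,
                               NumericVector cx, NumericVector radius_px,
                               NumericVector grey) {
  NumericMatrix img = clone(bg);
  const int h = img.nrow(), w = img.ncol();
  const int np = cy.size();
  const double sub = 16.0, inv = 1.0 / (sub * sub);
  for (int p = 0; p < np; ++p) {
    const double yc = cy[p], xc = cx[p], r = radius_px[p], g = grey[p];
    const double r2 = r * r;
    const int i0 = std::max(0, (int)std::floor(yc - r - 1.0));
    const int i1 = std::min(h - 1, (int)std::ceil(yc + r + 1.0));
    const int j0 = std::max(0, (int)std::floor(xc - r - 1.0));
    const int j1 = std::min(w - 1, (int)std::ceil(xc + r + 1.0));
    for (int i = i0; i <= i1; ++i) {
      for (int j = j0; j <= j1; ++j) {
        // quick accept/reject via pixel-centre distance
        const double dyc = i + 0.5 - yc, dxc = j + 0.5 - xc;
        const double dc = std::sqrt(dyc * dyc + dxc * dxc);
        double cov;
        if (dc <= r - 0.75) {
          cov = 1.0;
        } else if (dc >= r + 0.75) {
          continue;
        } else {
          int inside = 0;
          for (int si = 0; si < (int)sub; ++si) {
            const double y = i + (si + 0.5) / sub;
            const double dy = y - yc;
            for (int sj = 0; sj < (int)sub; ++sj) {
              const double x = j + (sj + 0.5) / sub;
              const double dx = x - xc;
              if (dy * dy + dx * dx <= r2) ++inside;
            }
          }
          cov = inside * inv;
          if (cov == 0.0) continue;
        }
        img(i, j) = (1.0 - cov) * img(i, j) + cov * g;
      }
    }
  }
  return img;
}

// Separable Gaussian blur, kernel truncated at 4 sigma, reflected borders.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  // horizontal pass: accumulate whole columns (column-major friendly)
  for (int j = 0; j < w; ++j) {
    double* out_col = &tmp(0, j);
    for (int t = -rad; t <= rad; ++t) {
      const double kv = k[t + rad];
      const double* in_col = &img(0, reflect_idx(j + t, w));
      for (int i = 0; i < h; ++i) out_col[i] += kv * in_col[i];
    }
  }
  // vertical pass: contiguous within each column
  for (int j = 0; j < w; ++j) {
    const double* in_col = &tmp(0, j);
    double* out_col = &out(0, j);
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      if (i >= rad && i < h - rad) {
        for (int t = -rad; t <= rad; ++t) acc += k[t + rad] * in_col[i + t];
      } else {
        for (int t = -rad; t <= rad; ++t)
          acc += k[t + rad] * in_col[reflect_idx(i + t, h)];
      }
      out_col[i] = acc;
    }
  }
  return out;
}

// Local mean over a block x block window (block odd), reflected borders,
// computed with a summed-area table over the reflect-padded image.
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix img, int block) {
  const int h = img.nrow(), w = img.ncol();
  const int r = block / 2;
  const int ph = h + 2 * r, pw = w + 2 * r;
  // column-major summed-area table with a zero top row / left column
  const size_t sh = ph + 1;
  std::vector<double> sat(sh * (size_t)(pw + 1), 0.0);
  for (int j = 0; j < pw; ++j) {
    const double* in_col = &img(0, reflect_idx(j - r, w));
    const double* prev = &sat[(size_t)j * sh];
    double* cur = &sat[(size_t)(j + 1) * sh];
    double colsum = 0.0;
    for (int i = 0; i < ph; ++i) {
      colsum += in_col[reflect_idx(i - r, h)];
      cur[i + 1] = prev[i + 1] + colsum;
    }
  }
  NumericMatrix out(h, w);
  const double area = (double)block * block;
  for (int j = 0; j < w; ++j) {
    const double* left = &sat[(size_t)j * sh];
    const double* right = &sat[(size_t)(j + block) * sh];
    double* out_col = &out(0, j);
    for (int i = 0; i < h; ++i) {
      out_col[i] =
          (right[i + block] - right[i] - left[i + block] + left[i]) / area;
    }
  }
  return out;
}

// 8-connected component labelling of a binary image. Labels are assigned in
// raster-scan order of each component's first pixel, so the output is
// deterministic.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix bin) {
  const int h = bin.nrow(), w = bin.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (bin(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i * w + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int ci = cur / w, cj = cur % w;
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
            if (bin(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni * w + nj);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Per-label pixel count and centroid (0-based continuous coordinates).
// [[Rcpp::export]]
List label_stats_cpp(IntegerMatrix lab, int n_labels) {
  NumericVector area(n_labels), sy(n_labels), sx(n_labels);
  const int h = lab.nrow(), w = lab.ncol();
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      const int l = lab(i, j);
      if (l > 0) {
        area[l - 1] += 1.0;
        sy[l - 1] += i + 0.5;
        sx[l - 1] += j + 0.5;
      }
    }
  for (int l = 0; l < n_labels; ++l) {
    if (area[l] > 0) {
      sy[l] /= area[l];
      sx[l] /= area[l];
    }
  }
  return List::create(_["area"] = area, _["cy"] = sy, _["cx"] = sx);
}

static inline double cubic_kernel(double s, double a) {
  s = std::fabs(s);
  if (s <= 1.0) return ((a + 2.0) * s - (a + 3.0)) * s * s + 1.0;
  if (s < 2.0) return ((a * s - 5.0 * a) * s + 8.0 * a) * s - 4.0 * a;
  return 0.0;
}

// Bicubic (cubic-convolution) resampling over the 4x4 nearest neighbours,
// kernel parameter a, replicated borders, centre-aligned coordinate mapping.
// [[Rcpp::export]]
NumericMatrix bicubic_cpp(NumericMatrix img, int out_h, int out_w, double a) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)h / out_h, sx = (double)w / out_w;
  std::vector<double> wx(4), wy(4);
  for (int oi = 0; oi < out_h; ++oi) {
    const double y = (oi + 0.5) * sy - 0.5;
    const int iy = (int)std::floor(y);
    const double ty = y - iy;
    for (int t = 0; t < 4; ++t) wy[t] = cubic_kernel(ty - (t - 1), a);
    for (int oj = 0; oj < out_w; ++oj) {
      const double x = (oj + 0.5) * sx - 0.5;
      const int ix = (int)std::floor(x);
      const double tx = x - ix;
      for (int t = 0; t < 4; ++t) wx[t] = cubic_kernel(tx - (t - 1), a);
      double acc = 0.0;
      for (int t = 0; t < 4; ++t) {
        const int si = std::min(h - 1, std::max(0, iy + t - 1));
        double rowacc = 0.0;
        for (int u = 0; u < 4; ++u) {
          const int sj = std::min(w - 1, std::max(0, ix + u - 1));
          rowacc += wx[u] * img(si, sj);
        }
        acc += wy[t] * rowacc;
      }
      out(oi, oj) = acc;
    }
  }
  return out;
}

// Rec. 601 luma from an h x w x 3 array (flattened column-major), rounded to
// the nearest integer digital number.
// [[Rcpp::export]]
NumericMatrix luma601_cpp(NumericVector arr, int h, int w) {
  NumericMatrix out(h, w);
  const size_t plane = (size_t)h * w;
  for (size_t p = 0; p < plane; ++p) {
    const double g =
        0.299 * arr[p] + 0.587 * arr[p + plane] + 0.114 * arr[p + 2 * plane];
    out[p] = std::round(g);
  }
  return out;
}

// Sequential random placement of disk centres with a minimum edge-to-edge
// gap, using R's RNG (so withr::with_seed controls determinism) and a uniform
// spatial grid for neighbour queries. Returns an n x 2 matrix (cy, cx) or
// throws if the attempt budget is exhausted.
// [[Rcpp::export]]
NumericMatrix place_centers_cpp(double h, double w, NumericVector r_px,
                                double min_gap, double max_attempts) {
  const int n = r_px.size();
  NumericMatrix out(n, 2);
  if (n == 0) return out;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r_px[i]);
  const double cell = std::max(1.0, 2.0 * rmax + min_gap);
  const int gh = std::max(1, (int)std::ceil(h / cell));
  const int gw = std::max(1, (int)std::ceil(w / cell));
  std::vector<std::vector<int>> grid((size_t)gh * gw);
  GetRNGstate();
  double attempts = 0.0;
  for (int i = 0; i < n; ++i) {
    const double margin = r_px[i] + 1.0;
    if (2.0 * margin >= h || 2.0 * margin >= w) {
      PutRNGstate();
      stop("particle %d (radius %.2f px) cannot fit inside the image", i + 1,
           r_px[i]);
    }
    bool placed = false;
    while (!placed) {
      if (++attempts > max_attempts) {
        PutRNGstate();
        stop("particle placement infeasible: exceeded %.0f attempts "
             "(density too high for min_gap_px = %.2f)",
             max_attempts, min_gap);
      }
      const double cy = margin + unif_rand() * (h - 2.0 * margin);
      const double cx = margin + unif_rand() * (w - 2.0 * margin);
      bool ok = true;
      if (min_gap > 0.0) {
        const int gi = std::min(gh - 1, (int)(cy / cell));
        const int gj = std::min(gw - 1, (int)(cx / cell));
        for (int di = -1; di <= 1 && ok; ++di) {
          for (int dj = -1; dj <= 1 && ok; ++dj) {
            const int ni = gi + di, nj = gj + dj;
            if (ni < 0 || ni >= gh || nj < 0 || nj >= gw) continue;
            for (int k : grid[(size_t)ni * gw + nj]) {
              const double dy = cy - out(k, 0), dx = cx - out(k, 1);
              const double need = r_px[i] + r_px[k] + min_gap;
              if (dy * dy + dx * dx < need * need) {
                ok = false;
                break;
              }
            }
          }
        }
      }
      if (ok) {
        out(i, 0) = cy;
        out(i, 1) = cx;
        const int gi = std::min(gh - 1, (int)(cy / cell));
        const int gj = std::min(gw - 1, (int)(cx / cell));
        grid[(size_t)gi * gw + gj].push_back(i);
        placed = true;
      }
    }
  }
  PutRNGstate();
  return out;
}

// Additive Gaussian noise (R RNG) with clipping to [0,255] and 8-bit
// re-quantization, in a single pass over all channels.
// [[Rcpp::export]]
NumericVector add_noise_quantize_cpp(NumericVector img, double mean,
                                     double sd) {
  NumericVector out = clone(img);
  const R_xlen_t n = out.size();
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = out[i] + mean + (sd > 0.0 ? norm_rand() * sd : 0.0);
    v = std::round(v);
    if (v < 0.0) v = 0.0;
    if (v > 255.0) v = 255.0;
    out[i] = v;
  }
  PutRNGstate();
  return out;
}

// Per-channel white-balance gains on an h x w x 3 array: red and blue are
// scaled, clipped and re-quantized; green is copied untouched.
// [[Rcpp::export]]
NumericVector wb_gains_cpp(NumericVector arr, int h, int w, double red_gain,
                           double blue_gain) {
  NumericVector out = clone(arr);
  const size_t plane = (size_t)h * w;
  for (size_t p = 0; p < plane; ++p) {
    double r = std::round(out[p] * red_gain);
    double b = std::round(out[p + 2 * plane] * blue_gain);
    out[p] = std::min(255.0, std::max(0.0, r));
    out[p + 2 * plane] = std::min(255.0, std::max(0.0, b));
  }
  return out;
}

// Quantize a grey matrix to 8 bits and replicate it into an h x w x 3 array.
// [[Rcpp::export]]
NumericVector grey_to_rgb8_cpp(NumericMatrix grey) {
  const int h = grey.nrow(), w = grey.ncol();
  const size_t plane = (size_t)h * w;
  NumericVector out(Dimension(h, w, 3));
  for (size_t p = 0; p < plane; ++p) {
    double v = std::round(grey[p]);
    if (v < 0.0) v = 0.0;
    if (v > 255.0) v = 255.0;
    out[p] = v;
    out[p + plane] = v;
    out[p + 2 * plane] = v;
  }
  return out;
}

// Focus blur: blend a channel with its Gaussian-blurred version using a
// raised-cosine weight that is 1 inside the centred sharp rectangle
// (focus_area percent of each dimension) and falls to 0 over a 3*sigma
// transition band outside it. Result is quantized to 8 bits.
// [[Rcpp::export]]
NumericMatrix focus_blur_channel_cpp(NumericMatrix ch, double focus_area,
                                     double strength) {
  const int h = ch.nrow(), w = ch.ncol();
  NumericMatrix blurred = gauss_blur_cpp(ch, strength);
  const double hh = h * focus_area / 200.0, hw = w * focus_area / 200.0;
  const double band = 3.0 * strength;
  std::vector<double> dy(h), dx(w);
  for (int i = 0; i < h; ++i)
    dy[i] = std::max(0.0, std::fabs(i + 0.5 - h / 2.0) - hh);
  for (int j = 0; j < w; ++j)
    dx[j] = std::max(0.0, std::fabs(j + 0.5 - w / 2.0) - hw);
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    const double* sharp_col = &ch(0, j);
    const double* blur_col = &blurred(0, j);
    double* out_col = &out(0, j);
    for (int i = 0; i < h; ++i) {
      const double d = std::max(dy[i], dx[j]);
      double v;
      if (d <= 0.0) {
        v = sharp_col[i];
      } else {
        const double t = std::min(d / band, 1.0);
        const double wgt = 0.5 * (1.0 + std::cos(M_PI * t));
        v = wgt * sharp_col[i] + (1.0 - wgt) * blur_col[i];
      }
      v = std::round(v);
      if (v < 0.0) v = 0.0;
      if (v > 255.0) v = 255.0;
      out_col[i] = v;
    }
  }
  return out;
}

// Half-contrast (FWHM) sizing area per label: for each component, the count
// of its pixels lying below the midpoint between the local background
// estimate and the component's darkest pixel. For blurred disks this contour
// tracks the true edge much more closely than the detection mask does.
// [[Rcpp::export]]
NumericVector label_halfmax_area_cpp(IntegerMatrix lab, NumericMatrix grey,
                                     NumericMatrix local_mean, int n_labels) {
  NumericVector vmin(n_labels, 255.0), bg(n_labels, 0.0);
  const int h = lab.nrow(), w = lab.ncol();
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      const int l = lab(i, j);
      if (l > 0) {
        if (grey(i, j) < vmin[l - 1]) {
          vmin[l - 1] = grey(i, j);
          bg[l - 1] = local_mean(i, j);
        }
      }
    }
  NumericVector thr(n_labels);
  for (int l = 0; l < n_labels; ++l) thr[l] = 0.5 * (bg[l] + vmin[l]);
  NumericVector area(n_labels, 0.0);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      const int l = lab(i, j);
      if (l > 0 && grey(i, j) < thr[l - 1]) area[l - 1] += 1.0;
    }
  return area;
}
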