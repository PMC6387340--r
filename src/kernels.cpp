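// Inner loops of the cost-volume pipeline. Images are plain R matrices
// (rows = y, cols = x), intensities in [0,1]. All window operations use
// replicate padding (index clamping) at the borders.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Adaptive-support-weight aggregation of a per-pixel raw cost map.
// out(p) = sum_{o in window} w(p,o) * raw(p+o) / sum_o w(p,o)
// w(p,o) = exp(-(|ref(p)-ref(p+o)|/sigma_c + ||o||/sigma_d))
// [[Rcpp::export]]
NumericMatrix cpp_asw_aggregate(NumericMatrix raw, NumericMatrix ref, int hws,
                                double sigma_c, double sigma_d) {
  int H = raw.nrow(), W = raw.ncol();
  NumericMatrix out(H, W);
  int win = 2 * hws + 1;
  std::vector<double> dgeom(win * win);
  for (int q = -hws; q <= hws; ++q)
    for (int r = -hws; r <= hws; ++r)
      dgeom[(q + hws) * win + (r + hws)] =
          std::sqrt((double)(r * r + q * q)) / sigma_d;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double c0 = ref(i, j), acc = 0.0, norm = 0.0;
      for (int q = -hws; q <= hws; ++q) {
        int jj = clampi(j + q, 0, W - 1);
        for (int r = -hws; r <= hws; ++r) {
          int ii = clampi(i + r, 0, H - 1);
          double w = std::exp(-(std::fabs(c0 - ref(ii, jj)) / sigma_c +
                                dgeom[(q + hws) * win + (r + hws)]));
          acc += w * raw(ii, jj);
          norm += w;
        }
      }
      out(i, j) = acc / norm;
    }
  }
  return out;
}

// Per-pixel normalized Hamming distance between the census transforms of two
// images. Census window is (2*chws+1)^2 - 1 comparisons against the center.
// Comparisons use a tiny epsilon so exact intensity ties (frequent after
// bilinear interpolation at half-pixel weights) classify identically under
// global offsets despite floating-point rounding.
// [[Rcpp::export]]
NumericMatrix cpp_census_hamming(NumericMatrix I1, NumericMatrix I2, int chws) {
  const double teps = 1e-9;
  int H = I1.nrow(), W = I1.ncol();
  NumericMatrix out(H, W);
  int nbits = (2 * chws + 1) * (2 * chws + 1) - 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double c1 = I1(i, j), c2 = I2(i, j);
      int ham = 0;
      for (int q = -chws; q <= chws; ++q) {
        int jj = clampi(j + q, 0, W - 1);
        for (int r = -chws; r <= chws; ++r) {
          if (r == 0 && q == 0) continue;
          int ii = clampi(i + r, 0, H - 1);
          bool b1 = I1(ii, jj) < c1 - teps;
          bool b2 = I2(ii, jj) < c2 - teps;
          if (b1 != b2) ++ham;
        }
      }
      out(i, j) = (double)ham / (double)nbits;
    }
  }
  return out;
}

// Weighted normalized cross-correlation between I1 and I2 in a window around
// each pixel, using adaptive support weights computed on `ref`.
// Windows with weighted variance below var_eps in either image give NCC = 0.
// [[Rcpp::export]]
NumericMatrix cpp_weighted_ncc(NumericMatrix I1, NumericMatrix I2,
                               NumericMatrix ref, int hws, double sigma_c,
                               double sigma_d, double var_eps) {
  int H = I1.nrow(), W = I1.ncol();
  NumericMatrix out(H, W);
  int win = 2 * hws + 1;
  std::vector<double> dgeom(win * win);
  for (int q = -hws; q <= hws; ++q)
    for (int r = -hws; r <= hws; ++r)
      dgeom[(q + hws) * win + (r + hws)] =
          std::sqrt((double)(r * r + q * q)) / sigma_d;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double c0 = ref(i, j);
      double sw = 0, s1 = 0, s2 = 0, s11 = 0, s22 = 0, s12 = 0;
      for (int q = -hws; q <= hws; ++q) {
        int jj = clampi(j + q, 0, W - 1);
        for (int r = -hws; r <= hws; ++r) {
          int ii = clampi(i + r, 0, H - 1);
          double w = std::exp(-(std::fabs(c0 - ref(ii, jj)) / sigma_c +
                                dgeom[(q + hws) * win + (r + hws)]));
          double a = I1(ii, jj), b = I2(ii, jj);
          sw += w; s1 += w * a; s2 += w * b;
          s11 += w * a * a; s22 += w * b * b; s12 += w * a * b;
        }
      }
      double m1 = s1 / sw, m2 = s2 / sw;
      double v1 = s11 / sw - m1 * m1;
      double v2 = s22 / sw - m2 * m2;
      if (v1 < var_eps || v2 < var_eps) {
        out(i, j) = 0.0;
      } else {
        double cv = s12 / sw - m1 * m2;
        double ncc = cv / std::sqrt(v1 * v2);
        if (ncc > 1.0) ncc = 1.0;
        if (ncc < -1.0) ncc = -1.0;
        out(i, j) = ncc;
      }
    }
  }
  return out;
}

// Sample img at (row + dy, col + dx) with bilinear interpolation; coordinates
// are clamped to the frame, `valid` records which samples were fully inside.
// [[Rcpp::export]]
List cpp_bilinear_shift(NumericMatrix img, double dx, double dy) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  LogicalMatrix valid(H, W);
  for (int j = 0; j < W; ++j) {
    double x = j + dx;
    bool vx = (x >= 0.0 && x <= W - 1.0);
    double xc = x < 0 ? 0 : (x > W - 1 ? W - 1 : x);
    int x0 = (int)std::floor(xc);
    int x1 = clampi(x0 + 1, 0, W - 1);
    double fx = xc - x0;
    for (int i = 0; i < H; ++i) {
      double y = i + dy;
      double yc = y < 0 ? 0 : (y > H - 1 ? H - 1 : y);
      int y0 = (int)std::floor(yc);
      int y1 = clampi(y0 + 1, 0, H - 1);
      double fy = yc - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      valid(i, j) = vx && (y >= 0.0 && y <= H - 1.0);
    }
  }
  return List::create(_["image"] = out, _["valid"] = valid);
}

// SLIC superpixels on a grayscale image. Cluster centers start on a regular
// grid with spacing `step`, optionally nudged to the lowest-gradient pixel in
// a 3x3 neighbourhood; assignment distance is
//   D = sqrt((dI/compactness)^2 + (ds/step)^2)
// Small fragments (< min_frac * step^2) are merged into the preceding
// connected neighbour. Returns 0-based labels, contiguous after merging.
// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, int step, double compactness,
                       int iters, double min_frac) {
  int H = img.nrow(), W = img.ncol();
  std::vector<double> cx, cy, ci;
  for (int y = step / 2; y < H; y += step)
    for (int x = step / 2; x < W; x += step) {
      // nudge to lowest local gradient (3x3), deterministic tie to first
      int bx = x, by = y;
      double bg = R_PosInf;
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          int xx = clampi(x + ox, 1, W - 2), yy = clampi(y + oy, 1, H - 2);
          double gx = img(yy, xx + 1) - img(yy, xx - 1);
          double gy = img(yy + 1, xx) - img(yy - 1, xx);
          double g = gx * gx + gy * gy;
          if (g < bg) { bg = g; bx = xx; by = yy; }
        }
      cx.push_back(bx); cy.push_back(by); ci.push_back(img(by, bx));
    }
  int K = (int)cx.size();
  std::vector<int> lab(H * W, -1);
  std::vector<double> dist(H * W);
  double inv_m = 1.0 / compactness, inv_s = 1.0 / step;
  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int x0 = clampi((int)cx[k] - step, 0, W - 1),
          x1 = clampi((int)cx[k] + step, 0, W - 1);
      int y0 = clampi((int)cy[k] - step, 0, H - 1),
          y1 = clampi((int)cy[k] + step, 0, H - 1);
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          double dc = (img(y, x) - ci[k]) * inv_m;
          double dxs = (x - cx[k]) * inv_s, dys = (y - cy[k]) * inv_s;
          double d = dc * dc + dxs * dxs + dys * dys;
          int idx = x * H + y;
          if (d < dist[idx]) { dist[idx] = d; lab[idx] = k; }
        }
    }
    std::vector<double> nx(K, 0), ny(K, 0), ni(K, 0), nn(K, 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int k = lab[x * H + y];
        if (k < 0) continue;
        nx[k] += x; ny[k] += y; ni[k] += img(y, x); nn[k] += 1;
      }
    for (int k = 0; k < K; ++k)
      if (nn[k] > 0) {
        cx[k] = nx[k] / nn[k]; cy[k] = ny[k] / nn[k]; ci[k] = ni[k] / nn[k];
      }
  }
  // connectivity enforcement: flood-fill components; absorb small ones into
  // the previously-labelled neighbour
  IntegerMatrix out(H, W);
  std::vector<int> newlab(H * W, -1);
  int next = 0;
  int min_size = (int)(min_frac * step * step);
  if (min_size < 1) min_size = 1;
  std::vector<int> stackv;
  const int dx4[4] = {-1, 1, 0, 0}, dy4[4] = {0, 0, -1, 1};
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int idx = x * H + y;
      if (newlab[idx] >= 0) continue;
      int adj = -1;  // neighbouring already-relabelled component
      stackv.clear();
      stackv.push_back(idx);
      newlab[idx] = next;
      std::vector<int> comp;
      comp.push_back(idx);
      while (!stackv.empty()) {
        int cur = stackv.back();
        stackv.pop_back();
        int cxp = cur / H, cyp = cur % H;
        for (int d = 0; d < 4; ++d) {
          int xx = cxp + dx4[d], yy = cyp + dy4[d];
          if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
          int nidx = xx * H + yy;
          if (newlab[nidx] < 0 && lab[nidx] == lab[idx]) {
            newlab[nidx] = next;
            stackv.push_back(nidx);
            comp.push_back(nidx);
          } else if (newlab[nidx] >= 0 && newlab[nidx] != next) {
            adj = newlab[nidx];
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (size_t t = 0; t < comp.size(); ++t) newlab[comp[t]] = adj;
      } else {
        ++next;
      }
    }
  // compress label ids (absorptions can leave gaps)
  std::vector<int> remap(next, -1);
  int nfinal = 0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int l = newlab[x * H + y];
      if (remap[l] < 0) remap[l] = nfinal++;
      out(y, x) = remap[l];
    }
  return out;
}

// Weighted median filter of an integer label image. Weights are guide-image
// affinities exp(-|g(p)-g(q)|/sigma_g) quantized to integers 1..wmax.
// Labels must be in 0..(nlab-1).
// [[Rcpp::export]]
IntegerMatrix cpp_weighted_median(IntegerMatrix labels, NumericMatrix guide,
                                  int hws, int nlab, double sigma_g, int wmax) {
  int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix out(H, W);
  std::vector<int> hist(nlab);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      double g0 = guide(i, j);
      int total = 0;
      for (int q = -hws; q <= hws; ++q) {
        int jj = clampi(j + q, 0, W - 1);
        for (int r = -hws; r <= hws; ++r) {
          int ii = clampi(i + r, 0, H - 1);
          int w = (int)std::lround(
              wmax * std::exp(-std::fabs(g0 - guide(ii, jj)) / sigma_g));
          if (w < 1) w = 1;
          hist[labels(ii, jj)] += w;
          total += w;
        }
      }
      int half = (total + 1) / 2, cum = 0, med = nlab - 1;
      for (int t = 0; t < nlab; ++t) {
        cum += hist[t];
        if (cum >= half) { med = t; break; }
      }
      out(i, j) = med;
    }
  }
  return out;
}
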