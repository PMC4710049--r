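#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling of a logical mask.
// Labels are assigned 1..K in raster-scan (row-major) order of each
// component's first pixel, matching the CellProfiler-style convention.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % H, cc = idx / H;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Expand labelled nuclei by a fixed Euclidean distance: every background
// pixel within `distance` of a nucleus pixel receives the label of the
// nearest nucleus pixel; exact ties go to the lowest label.
// [[Rcpp::export]]
IntegerMatrix cpp_expand_labels(IntegerMatrix labels, double distance) {
  const int H = labels.nrow(), W = labels.ncol();
  const int d = (int)std::floor(distance);
  const double d2max = distance * distance;
  IntegerMatrix out(H, W);
  std::vector<double> best(H * (size_t)W, R_PosInf);
  // nucleus pixels keep their own label at distance 0
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (labels(r, c) > 0) {
        out(r, c) = labels(r, c);
        best[r + (size_t)c * H] = 0.0;
      }
  // precompute disc offsets
  std::vector<int> odr, odc;
  std::vector<double> od2;
  for (int dr = -d; dr <= d; ++dr)
    for (int dc = -d; dc <= d; ++dc) {
      double d2 = (double)dr * dr + (double)dc * dc;
      if (d2 > 0 && d2 <= d2max) {
        odr.push_back(dr);
        odc.push_back(dc);
        od2.push_back(d2);
      }
    }
  const int K = (int)odr.size();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int lb = labels(r, c);
      if (lb <= 0) continue;
      for (int k = 0; k < K; ++k) {
        int nr = r + odr[k], nc = c + odc[k];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (labels(nr, nc) > 0) continue; // nucleus pixels never reassigned
        size_t idx = nr + (size_t)nc * H;
        if (od2[k] < best[idx] || (od2[k] == best[idx] && lb < out(nr, nc))) {
          best[idx] = od2[k];
          out(nr, nc) = lb;
        }
      }
    }
  }
  return out;
}

// Accumulate the separable truncated-Gaussian contribution of each spot
// (outer-product saxpy over the clipped kernel window).
static void splat(double *out, int H, int W,
                  const int *rows, const int *cols, int n,
                  const double *kv, int half) {
  for (int s = 0; s < n; ++s) {
    const int r0 = rows[s] - 1, c0 = cols[s] - 1;
    const int clo = std::max(0, c0 - half), chi = std::min(W - 1, c0 + half);
    const int rlo = std::max(0, r0 - half), rhi = std::min(H - 1, r0 + half);
    const int len = rhi - rlo + 1;
    const double *kr = kv + (rlo - r0 + half);
    for (int c = clo; c <= chi; ++c) {
      const double kc = kv[c - c0 + half];
      double *col = out + (size_t)c * H + rlo;
      for (int i = 0; i < len; ++i)
        col[i] += kc * kr[i];
    }
  }
}

// Zero-padded convolution of a binary spot image with the separable
// truncated Gaussian kernel k1d (outer product form), accumulated spot by
// spot. rows/cols are 1-based pixel coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_splat_density(IntegerVector rows, IntegerVector cols,
                                int H, int W, NumericVector k1d) {
  const int half = (k1d.size() - 1) / 2;
  NumericMatrix out(H, W);
  if (rows.size() == 0) return out;
  std::vector<double> kv(k1d.begin(), k1d.end());
  splat(&out(0, 0), H, W, &rows[0], &cols[0], rows.size(), kv.data(), half);
  return out;
}

// Permutation-null inner loop: for each row of xperm (one label
// randomization; TRUE = X label), recompute the X density by splatting,
// derive the Y-purity field p = (total - x)/total on pixels with
// total >= eps, and accumulate the purity histogram (n_bins equal-width
// bins on [0,1]) and the three dominance-category proportions.
// Returns per-randomization relative bin frequencies and proportions
// (x_dominant, mixed, y_dominant).
// [[Rcpp::export]]
List cpp_perm_purity_stats(IntegerVector rows, IntegerVector cols,
                           LogicalMatrix xperm, NumericMatrix total,
                           NumericVector k1d, double eps,
                           int n_bins, double cutoff) {
  const int H = total.nrow(), W = total.ncol();
  const int n = rows.size(), R = xperm.nrow();
  const int half = (k1d.size() - 1) / 2;
  const double xcut = 1.0 - cutoff;
  NumericMatrix freq(R, n_bins);
  NumericMatrix props(R, 3);
  std::vector<double> kv(k1d.begin(), k1d.end());
  std::vector<double> xd(H * (size_t)W);
  std::vector<int> xr, xc;
  xr.reserve(n); xc.reserve(n);
  // list of unmasked pixel indices (shared across randomizations)
  std::vector<size_t> unmasked;
  const double *tp = &total(0, 0);
  for (size_t i = 0; i < (size_t)H * W; ++i)
    if (tp[i] >= eps) unmasked.push_back(i);
  const double n_un = (double)unmasked.size();
  std::vector<int> counts(n_bins);
  for (int p = 0; p < R; ++p) {
    std::fill(xd.begin(), xd.end(), 0.0);
    xr.clear(); xc.clear();
    for (int s = 0; s < n; ++s) {
      if (xperm(p, s)) { xr.push_back(rows[s]); xc.push_back(cols[s]); }
    }
    splat(xd.data(), H, W, xr.data(), xc.data(), (int)xr.size(),
          kv.data(), half);
    std::fill(counts.begin(), counts.end(), 0);
    double nx = 0, nmix = 0, ny = 0;
    for (size_t ui = 0; ui < unmasked.size(); ++ui) {
      const size_t i = unmasked[ui];
      double pur = (tp[i] - xd[i]) / tp[i];
      if (pur < 0) pur = 0;
      if (pur > 1) pur = 1;
      int b = (int)(pur * n_bins);
      if (b >= n_bins) b = n_bins - 1;
      ++counts[b];
      if (pur <= xcut) ++nx;
      else if (pur >= cutoff) ++ny;
      else ++nmix;
    }
    for (int b = 0; b < n_bins; ++b) freq(p, b) = counts[b] / n_un;
    props(p, 0) = nx / n_un;
    props(p, 1) = nmix / n_un;
    props(p, 2) = ny / n_un;
  }
  return List::create(_["freq"] = freq, _["props"] = props,
                      _["n_unmasked"] = (double)unmasked.size());
}
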