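#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a binary mask.
// connectivity: 4 or 8. Labels are assigned in scan order (down columns,
// then across) starting at 1; 0 marks background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int ndir = connectivity;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < ndir; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Box counts for the box-counting dimension: for each box side s (pixels),
// the number of s-by-s boxes (grid anchored at the top-left of the mask)
// containing at least one foreground pixel.
// [[Rcpp::export]]
IntegerVector cpp_box_counts(const LogicalMatrix& mask, const IntegerVector& sizes) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerVector out(sizes.size());
  for (int k = 0; k < sizes.size(); ++k) {
    const int s = sizes[k];
    if (s < 1) stop("box sizes must be >= 1");
    const int nbr = (nr + s - 1) / s, nbc = (nc + s - 1) / s;
    std::vector<char> seen((size_t)nbr * nbc, 0);
    int count = 0;
    for (int c = 0; c < nc; ++c) {
      const int bc = c / s;
      for (int r = 0; r < nr; ++r) {
        if (!mask(r, c)) continue;
        size_t b = (size_t)(r / s) + (size_t)bc * nbr;
        if (!seen[b]) { seen[b] = 1; ++count; }
      }
    }
    out[k] = count;
  }
  return out;
}

static std::vector<std::pair<int,int> > disk_offsets(double radius_px) {
  std::vector<std::pair<int,int> > off;
  int R = (int)std::floor(radius_px);
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius_px * radius_px)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_dilate(const LogicalMatrix& mask, double radius_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disk_offsets(radius_px);
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) out(r2, c2) = true;
      }
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_erode(const LogicalMatrix& mask, double radius_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disk_offsets(radius_px);
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool all = true;
      for (size_t k = 0; k < off.size() && all; ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        // outside the image counts as foreground, so closing leaves a
        // solid image unchanged instead of eroding its border
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!mask(r2, c2)) all = false;
      }
      out(r, c) = all;
    }
  return out;
}

// Separable Gaussian smoothing with reflected boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(const NumericMatrix& img, double sigma_px) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma_px <= 0) return clone(img);
  const int h = std::max(1, (int)std::ceil(3.0 * sigma_px));
  std::vector<double> kern(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    kern[i + h] = std::exp(-0.5 * i * i / (sigma_px * sigma_px));
    s += kern[i + h];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        acc += kern[i + h] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // along columns (horizontal direction)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        acc += kern[i + h] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

static double pearson(const NumericMatrix& a, const NumericMatrix& b) {
  const R_xlen_t n = a.size();
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0, sbb = 0, sab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Block-permutation null for the smoothed zero-lag Pearson correlation.
// `a_smooth` is the already-smoothed reference image; `b_raw` is permuted by
// shuffling the positions of full block_px-by-block_px tiles (partial edge
// tiles stay fixed), smoothed with the same sigma, and correlated with
// a_smooth. Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_block_null(const NumericMatrix& a_smooth,
                             const NumericMatrix& b_raw,
                             int block_px, double sigma_px, int nperm) {
  const int nr = b_raw.nrow(), nc = b_raw.ncol();
  if (block_px < 1) stop("block_px must be >= 1");
  const int nbr = nr / block_px, nbc = nc / block_px;
  if (nbr * nbc < 4) stop("ROI smaller than 4 full blocks; decrease block size");
  const int nb = nbr * nbc;
  NumericVector out(nperm);
  NumericMatrix perm(nr, nc);
  for (int p = 0; p < nperm; ++p) {
    IntegerVector ord = sample(nb, nb, false); // 1-based
    // start from b_raw so partial edge tiles keep their original content
    std::copy(b_raw.begin(), b_raw.end(), perm.begin());
    for (int dest = 0; dest < nb; ++dest) {
      int src = ord[dest] - 1;
      int dr0 = (dest % nbr) * block_px, dc0 = (dest / nbr) * block_px;
      int sr0 = (src % nbr) * block_px, sc0 = (src / nbr) * block_px;
      for (int c = 0; c < block_px; ++c)
        for (int r = 0; r < block_px; ++r)
          perm(dr0 + r, dc0 + c) = b_raw(sr0 + r, sc0 + c);
    }
    NumericMatrix ps = cpp_gauss_smooth(perm, sigma_px);
    out[p] = pearson(a_smooth, ps);
  }
  return out;
}

// Single block permutation of an image (exported for the property test that
// the per-block pixel multiset is preserved).
// [[Rcpp::export]]
NumericMatrix cpp_block_permute_once(const NumericMatrix& b_raw, int block_px) {
  const int nr = b_raw.nrow(), nc = b_raw.ncol();
  const int nbr = nr / block_px, nbc = nc / block_px;
  const int nb = nbr * nbc;
  if (nb < 4) stop("ROI smaller than 4 full blocks; decrease block size");
  NumericMatrix perm = clone(b_raw);
  IntegerVector ord = sample(nb, nb, false);
  for (int dest = 0; dest < nb; ++dest) {
    int src = ord[dest] - 1;
    int dr0 = (dest % nbr) * block_px, dc0 = (dest / nbr) * block_px;
    int sr0 = (src % nbr) * block_px, sc0 = (src / nbr) * block_px;
    for (int c = 0; c < block_px; ++c)
      for (int r = 0; r < block_px; ++r)
        perm(dr0 + r, dc0 + c) = b_raw(sr0 + r, sc0 + c);
  }
  return perm;
}
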