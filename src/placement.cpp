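#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial hash over cell centroids (micron coordinates) for fast
// minimum-distance queries during sequential placement.
struct CentroidHash {
  double bin;       // bin side, microns
  int nbx, nby;
  std::vector<std::vector<int> > cells;
  std::vector<double> xs, ys;

  CentroidHash(double width_um, double height_um, double bin_um)
    : bin(bin_um) {
    nbx = std::max(1, (int)std::ceil(width_um / bin));
    nby = std::max(1, (int)std::ceil(height_um / bin));
    cells.resize((size_t)nbx * nby);
  }
  int bin_of(double x, double y) const {
    int bx = std::min(nbx - 1, std::max(0, (int)(x / bin)));
    int by = std::min(nby - 1, std::max(0, (int)(y / bin)));
    return bx + by * nbx;
  }
  void insert(double x, double y) {
    xs.push_back(x); ys.push_back(y);
    cells[bin_of(x, y)].push_back((int)xs.size() - 1);
  }
  // true if some centroid other than `exclude` lies within d of (x, y)
  bool any_within(double x, double y, double d, int exclude = -1) const {
    int bx0 = std::max(0, (int)((x - d) / bin)), bx1 = std::min(nbx - 1, (int)((x + d) / bin));
    int by0 = std::max(0, (int)((y - d) / bin)), by1 = std::min(nby - 1, (int)((y + d) / bin));
    double d2 = d * d;
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx) {
        const std::vector<int>& v = cells[bx + by * nbx];
        for (size_t k = 0; k < v.size(); ++k) {
          int i = v[k];
          if (i == exclude) continue;
          double dx = xs[i] - x, dy = ys[i] - y;
          if (dx * dx + dy * dy < d2) return true;
        }
      }
    return false;
  }
};

// Sequential random placement of disk-shaped cells.
// eps_norm: EPS field normalized to [0, 1]; acceptance probability is
// (1 - coupling) + coupling * eps_norm at the candidate pixel, times
// margin_density outside the patch rectangle. Placement stops when the
// occupied fraction of the patch reaches target_cov. Uses the R RNG.
// patch rectangle: [r0, r1) x [c0, c1), 0-based pixel indices.
// [[Rcpp::export]]
List cpp_place_cells(const NumericMatrix& eps_norm, double pixel_size,
                     int r0, int r1, int c0, int c1,
                     double target_cov, double coupling, double radius_um,
                     double overlap_factor, double margin_density,
                     double max_attempts) {
  const int nr = eps_norm.nrow(), nc = eps_norm.ncol();
  const double W = nc * pixel_size, H = nr * pixel_size;
  if (r0 < 0 || c0 < 0 || r1 > nr || c1 > nc || r1 <= r0 || c1 <= c0)
    stop("patch rectangle outside the grid");
  const double min_dist = 2.0 * radius_um * overlap_factor;
  const double rad_px = radius_um / pixel_size;
  const long patch_px = (long)(r1 - r0) * (c1 - c0);

  CentroidHash hash(W, H, std::max(min_dist, 1.0));
  std::vector<int> counts((size_t)nr * nc, 0);
  long covered = 0;
  const int R = (int)std::floor(rad_px);
  double attempts = 0;
  while ((double)covered / patch_px < target_cov) {
    if (attempts >= max_attempts)
      stop("could not reach target coverage %.4f; achieved %.4f after %.0f attempts",
           target_cov, (double)covered / patch_px, attempts);
    attempts += 1;
    double x = unif_rand() * W, y = unif_rand() * H;
    int pc = std::min(nc - 1, (int)(x / pixel_size));
    int pr = std::min(nr - 1, (int)(y / pixel_size));
    double p = (1.0 - coupling) + coupling * eps_norm(pr, pc);
    bool in_patch = (pr >= r0 && pr < r1 && pc >= c0 && pc < c1);
    if (!in_patch) p *= margin_density;
    if (unif_rand() >= p) continue;
    if (hash.any_within(x, y, min_dist)) continue;
    hash.insert(x, y);
    // stamp the disk into the count grid; track newly covered patch pixels
    for (int dr = -R - 1; dr <= R + 1; ++dr)
      for (int dc = -R - 1; dc <= R + 1; ++dc) {
        int rr = pr + dr, cc = pc + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double px = (cc + 0.5) * pixel_size, py = (rr + 0.5) * pixel_size;
        double dx = px - x, dy = py - y;
        if (dx * dx + dy * dy > radius_um * radius_um) continue;
        size_t idx = (size_t)rr + (size_t)cc * nr;
        if (counts[idx] == 0 && rr >= r0 && rr < r1 && cc >= c0 && cc < c1)
          ++covered;
        ++counts[idx];
      }
  }
  int n = (int)hash.xs.size();
  NumericMatrix cent(n, 2);
  for (int i = 0; i < n; ++i) { cent(i, 0) = hash.xs[i]; cent(i, 1) = hash.ys[i]; }
  return List::create(_["centroids"] = cent,
                      _["coverage"] = (double)covered / patch_px,
                      _["attempts"] = attempts);
}

// Union-of-disks occupancy mask from centroids (microns).
// [[Rcpp::export]]
LogicalMatrix cpp_stamp_disks(int nr, int nc, const NumericMatrix& centroids,
                              double radius_um, double pixel_size) {
  LogicalMatrix out(nr, nc);
  const int R = (int)std::ceil(radius_um / pixel_size) + 1;
  for (int i = 0; i < centroids.nrow(); ++i) {
    double x = centroids(i, 0), y = centroids(i, 1);
    int pc = (int)(x / pixel_size), pr = (int)(y / pixel_size);
    for (int dr = -R; dr <= R; ++dr)
      for (int dc = -R; dc <= R; ++dc) {
        int rr = pr + dr, cc = pc + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double px = (cc + 0.5) * pixel_size, py = (rr + 0.5) * pixel_size;
        double dx = px - x, dy = py - y;
        if (dx * dx + dy * dy <= radius_um * radius_um) out(rr, cc) = true;
      }
  }
  return out;
}
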