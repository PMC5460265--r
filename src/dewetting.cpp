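#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Greedy nucleation-site selection: candidate pixels inside the patch are
// ranked by rupture resistance (ascending; ties broken by row-major pixel
// order) and accepted one by one subject to a minimum inter-site spacing.
// Cell-occupied pixels carry a huge resistance upstream and are excluded here
// by the `finite < 1e29` guard.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_nucleate(const NumericMatrix& resistance,
                           int r0, int r1, int c0, int c1,
                           double spacing_px, int max_sites) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  if (r0 < 0 || c0 < 0 || r1 > nr || c1 > nc || r1 <= r0 || c1 <= c0)
    stop("patch rectangle outside the grid");
  struct Cand { double v; int r, c; };
  std::vector<Cand> cand;
  cand.reserve((size_t)(r1 - r0) * (c1 - c0));
  for (int r = r0; r < r1; ++r)
    for (int c = c0; c < c1; ++c)
      if (resistance(r, c) < 1e29) {
        Cand cd; cd.v = resistance(r, c); cd.r = r; cd.c = c;
        cand.push_back(cd);
      }
  if (cand.empty()) stop("no valid nucleation site: every patch pixel is cell-occupied");
  std::sort(cand.begin(), cand.end(), [nc](const Cand& a, const Cand& b) {
    if (a.v != b.v) return a.v < b.v;
    return (long)a.r * nc + a.c < (long)b.r * nc + b.c; // row-major tie-break
  });
  // coarse grid over accepted sites for the spacing test
  const double bin = std::max(1.0, spacing_px);
  const int gbx = (int)std::ceil(nc / bin), gby = (int)std::ceil(nr / bin);
  std::vector<std::vector<int> > grid((size_t)gbx * gby);
  std::vector<int> ar, ac;
  const double sp2 = spacing_px * spacing_px;
  for (size_t i = 0; i < cand.size() && (int)ar.size() < max_sites; ++i) {
    int r = cand[i].r, c = cand[i].c;
    int bx = (int)(c / bin), by = (int)(r / bin);
    bool ok = true;
    for (int dy = -1; dy <= 1 && ok; ++dy)
      for (int dx = -1; dx <= 1 && ok; ++dx) {
        int bx2 = bx + dx, by2 = by + dy;
        if (bx2 < 0 || bx2 >= gbx || by2 < 0 || by2 >= gby) continue;
        const std::vector<int>& v = grid[(size_t)bx2 + (size_t)by2 * gbx];
        for (size_t k = 0; k < v.size(); ++k) {
          double dr = ar[v[k]] - r, dc = ac[v[k]] - c;
          if (dr * dr + dc * dc < sp2) { ok = false; break; }
        }
      }
    if (!ok) continue;
    ar.push_back(r); ac.push_back(c);
    grid[(size_t)bx + (size_t)by * gbx].push_back((int)ar.size() - 1);
  }
  IntegerMatrix out((int)ar.size(), 2);
  for (int i = 0; i < (int)ar.size(); ++i) { out(i, 0) = ar[i]; out(i, 1) = ac[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Lattice simulator of evaporation-driven dewetting over a cell monolayer.
//
// Holes nucleate at prescribed sites/times and their contact-line fronts
// advance outward over wet (label 0) pixels. Front elements carry an
// accumulated load of scraped cells; speed is reduced by load and a segment
// pins permanently when load + EPS resistance exceeds pin_threshold, when it
// meets a stronghold cell (rearrangement regime, adhesion >= capillary
// force) or when it contacts another hole. Regimes: 0 = removal (weak cells
// detached with probability p_detach), 1 = rearrangement (weak cells pushed
// outward along the front normal and added to the load), 2 = no effect.
// All randomness (detachment rolls) uses the R RNG.
// ---------------------------------------------------------------------------

struct FrontEl {
  int r, c, hole;      // pixel and owning hole (1-based)
  double progress;     // µm of accumulated advance toward this pixel
  double threshold;    // µm needed to claim: the chamfer step cost (1 or
                       // sqrt(2) pixels), giving near-isotropic growth
  double load;         // scraped-cell load carried by this segment
  bool diagonal;       // spawned by a diagonal step (needs 4-conn support)
  short waits;         // claim attempts deferred for lack of 4-conn support
  bool pinned;
  bool retired;
};

struct CellStore {
  std::vector<double> x, y;
  std::vector<char> removed, tested;
  std::vector<double> adhesion;
  double bin; int nbx, nby;
  std::vector<std::vector<int> > bins;
  std::vector<int> binof;

  void init(const NumericMatrix& cent, const NumericVector& adh,
            double W, double H, double bin_um) {
    int n = cent.nrow();
    x.resize(n); y.resize(n);
    removed.assign(n, 0); tested.assign(n, 0);
    adhesion.resize(n); binof.resize(n);
    bin = bin_um;
    nbx = std::max(1, (int)std::ceil(W / bin));
    nby = std::max(1, (int)std::ceil(H / bin));
    bins.assign((size_t)nbx * nby, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      x[i] = cent(i, 0); y[i] = cent(i, 1); adhesion[i] = adh[i];
      binof[i] = bin_index(x[i], y[i]);
      bins[binof[i]].push_back(i);
    }
  }
  int bin_index(double px, double py) const {
    int bx = std::min(nbx - 1, std::max(0, (int)(px / bin)));
    int by = std::min(nby - 1, std::max(0, (int)(py / bin)));
    return bx + by * nbx;
  }
  void move(int i, double nx, double ny) {
    int nb = bin_index(nx, ny);
    if (nb != binof[i]) {
      std::vector<int>& v = bins[binof[i]];
      v.erase(std::find(v.begin(), v.end(), i));
      bins[nb].push_back(i);
      binof[i] = nb;
    }
    x[i] = nx; y[i] = ny;
  }
  void query(double px, double py, double d, std::vector<int>& out) const {
    out.clear();
    int bx0 = std::max(0, (int)((px - d) / bin)), bx1 = std::min(nbx - 1, (int)((px + d) / bin));
    int by0 = std::max(0, (int)((py - d) / bin)), by1 = std::min(nby - 1, (int)((py + d) / bin));
    double d2 = d * d;
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx) {
        const std::vector<int>& v = bins[(size_t)bx + (size_t)by * nbx];
        for (size_t k = 0; k < v.size(); ++k) {
          int i = v[k];
          if (removed[i]) continue;
          double dx = x[i] - px, dy = y[i] - py;
          if (dx * dx + dy * dy <= d2) out.push_back(i);
        }
      }
    std::sort(out.begin(), out.end()); // deterministic order
  }
  bool any_within(double px, double py, double d, int exclude) const {
    int bx0 = std::max(0, (int)((px - d) / bin)), bx1 = std::min(nbx - 1, (int)((px + d) / bin));
    int by0 = std::max(0, (int)((py - d) / bin)), by1 = std::min(nby - 1, (int)((py + d) / bin));
    double d2 = d * d;
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx) {
        const std::vector<int>& v = bins[(size_t)bx + (size_t)by * nbx];
        for (size_t k = 0; k < v.size(); ++k) {
          int i = v[k];
          if (i == exclude || removed[i]) continue;
          double dx = x[i] - px, dy = y[i] - py;
          if (dx * dx + dy * dy < d2) return true;
        }
      }
    return false;
  }
};

// [[Rcpp::export]]
List cpp_run_dewetting(const NumericMatrix& eps_norm,
                       const NumericMatrix& centroids,
                       const NumericVector& adhesion,
                       const IntegerMatrix& sites,
                       const NumericVector& t_nuc,
                       double pixel_size, double cell_radius_um,
                       int regime,
                       double capillary_force, double p_detach,
                       double pin_threshold, double resist_scale,
                       double v_max, double ramp_time, bool inv_r, double r_ref,
                       double dt, double total_time,
                       double push_spacing, double push_search,
                       double stall_frac, double stall_speed,
                       int record_stride) {
  const int nr = eps_norm.nrow(), nc = eps_norm.ncol();
  const double W = nc * pixel_size, H = nr * pixel_size;
  const int nholes = sites.nrow();
  if (t_nuc.size() != nholes) stop("t_nuc length must match site count");
  if (dt <= 0 || dt > 0.02 + 1e-12) stop("dt must be in (0, 0.02] s");
  if (total_time < 5) stop("total_time must be >= 5 s");

  IntegerMatrix label(nr, nc);                 // 0 = wet/intact
  std::vector<int> in_front((size_t)nr * nc, 0); // element index + 1
  std::vector<FrontEl> els;
  els.reserve(1 << 16);
  std::vector<int> active;
  std::vector<long> area_px(nholes, 0);
  std::vector<double> hx(nholes), hy(nholes);
  std::vector<char> nucleated(nholes, 0), alive(nholes, 0);
  for (int h = 0; h < nholes; ++h) {
    hx[h] = (sites(h, 1) + 0.5) * pixel_size;
    hy[h] = (sites(h, 0) + 0.5) * pixel_size;
  }

  CellStore cells;
  cells.init(centroids, adhesion, W, H, std::max(1.0, 2 * cell_radius_um));

  long ev_removed = 0, ev_pushed = 0, ev_fallback = 0, ev_collision = 0,
       ev_eps_pin = 0, ev_stronghold = 0, ev_stranded = 0;

  const int nsteps = (int)std::ceil(total_time / dt);
  const int nrec = nsteps / record_stride + 1;
  NumericMatrix areas(nrec, nholes);
  NumericVector rec_times(nrec);
  int irec = 0;
  const double pix_area = pixel_size * pixel_size;

  std::vector<int> contacted;
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};

  // push one cell radially outward from its hole's nucleation centre
  auto push_cell = [&](int i, int hole) {
    double dx = cells.x[i] - hx[hole - 1], dy = cells.y[i] - hy[hole - 1];
    double nrm = std::sqrt(dx * dx + dy * dy);
    if (nrm < 1e-9) { dx = 1.0; dy = 0.0; nrm = 1.0; }
    dx /= nrm; dy /= nrm;
    const double step = pixel_size / 2.0;
    const int K = (int)std::ceil(push_search / step);
    for (int k = 1; k <= K; ++k) {
      double cx = cells.x[i] + dx * k * step, cy = cells.y[i] + dy * k * step;
      if (cx < 0 || cx >= W || cy < 0 || cy >= H) break; // ray leaves grid
      int pr = (int)(cy / pixel_size), pc = (int)(cx / pixel_size);
      if (label(pr, pc) != 0) continue;                  // inside a hole
      if (cells.any_within(cx, cy, push_spacing, i)) continue;
      cells.move(i, cx, cy);
      return true;
    }
    // fallback: breadth-first search for the nearest wet pixel, ignore spacing
    int pr0 = (int)(cells.y[i] / pixel_size), pc0 = (int)(cells.x[i] / pixel_size);
    for (int rad = 1; rad <= (int)(push_search / pixel_size); ++rad) {
      for (int ddr = -rad; ddr <= rad; ++ddr)
        for (int ddc = -rad; ddc <= rad; ++ddc) {
          if (std::max(std::abs(ddr), std::abs(ddc)) != rad) continue;
          int rr = pr0 + ddr, ccx = pc0 + ddc;
          if (rr < 0 || rr >= nr || ccx < 0 || ccx >= nc) continue;
          if (label(rr, ccx) != 0) continue;
          cells.move(i, (ccx + 0.5) * pixel_size, (rr + 0.5) * pixel_size);
          ++ev_fallback;
          return true;
        }
    }
    ++ev_stranded; // nowhere to go; cell stays put
    return false;
  };

  // attempt to claim element ei's pixel for its hole
  // NOTE: els may reallocate inside this function; never hold a FrontEl
  // reference across a push_back.
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  auto claim = [&](int ei) {
    const int r = els[ei].r, c = els[ei].c, hole = els[ei].hole;
    if (label(r, c) != 0) { els[ei].retired = true; in_front[(size_t)r + (size_t)c * nr] = 0; return; }
    // a diagonal child may only claim once it has orthogonal support from
    // its own hole, so hole regions stay 4-connected
    if (els[ei].diagonal) {
      bool support = false, possible = false;
      for (int k = 0; k < 4 && !support; ++k) {
        int r2 = r + dr4[k], c2 = c + dc4[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (label(r2, c2) == hole) { support = true; break; }
        if (label(r2, c2) == 0) {
          int f = in_front[(size_t)r2 + (size_t)c2 * nr];
          if (f != 0 && els[f - 1].hole == hole && !els[f - 1].pinned &&
              !els[f - 1].retired)
            possible = true; // an active own-front bridge may still claim it
        }
      }
      if (!support) {
        // wait for the bridge, but not forever: mutually waiting diagonal
        // neighbours would otherwise livelock
        if (possible && els[ei].waits < 50) {
          ++els[ei].waits;
          els[ei].progress = els[ei].threshold;
        } else {
          els[ei].pinned = true;
        }
        return;
      }
    }
    // EPS + load pinning
    if (els[ei].load + resist_scale * eps_norm(r, c) >= pin_threshold) {
      els[ei].pinned = true; ++ev_eps_pin; return;
    }
    // collision with another hole's territory (8-neighbourhood)
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int l2 = label(r2, c2);
      if (l2 != 0 && l2 != hole) { els[ei].pinned = true; ++ev_collision; return; }
    }
    // cells whose body covers this pixel's centre
    double px = (c + 0.5) * pixel_size, py = (r + 0.5) * pixel_size;
    cells.query(px, py, cell_radius_um, contacted);
    if (regime == 1) {
      for (size_t k = 0; k < contacted.size(); ++k)
        if (cells.adhesion[contacted[k]] >= capillary_force) {
          els[ei].pinned = true; ++ev_stronghold; return; // stronghold blocks the line
        }
    }
    // claim the pixel
    label(r, c) = hole;
    ++area_px[hole - 1];
    in_front[(size_t)r + (size_t)c * nr] = 0;
    els[ei].retired = true;
    double load = els[ei].load;
    const double progress = els[ei].progress;
    if (regime == 0) {
      for (size_t k = 0; k < contacted.size(); ++k) {
        int i = contacted[k];
        if (cells.adhesion[i] >= capillary_force) continue;
        if (!cells.tested[i]) {
          cells.tested[i] = 1;
          if (unif_rand() < p_detach) { cells.removed[i] = 1; ++ev_removed; }
        }
      }
    } else if (regime == 1) {
      for (size_t k = 0; k < contacted.size(); ++k) {
        int i = contacted[k];
        if (cells.adhesion[i] >= capillary_force) continue;
        if (push_cell(i, hole)) { load += 1.0; ++ev_pushed; }
      }
      els[ei].load = load;
    }
    // spawn children on wet 8-neighbours (chamfer costs: 1 / sqrt(2) px)
    const double thr = els[ei].threshold;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (label(r2, c2) != 0) continue;
      size_t idx2 = (size_t)r2 + (size_t)c2 * nr;
      int f = in_front[idx2];
      if (f != 0) {
        FrontEl& other = els[f - 1];
        if (other.hole != hole && !other.retired && !other.pinned) {
          other.pinned = true; ++ev_collision; // fronts meet: both sides stop
        }
        continue;
      }
      FrontEl ch;
      ch.r = r2; ch.c = c2; ch.hole = hole;
      ch.diagonal = k >= 4;
      ch.threshold = (k >= 4 ? M_SQRT2 : 1.0) * pixel_size;
      ch.progress = std::max(0.0, progress - thr);
      ch.load = load;
      ch.waits = 0; ch.pinned = false; ch.retired = false;
      els.push_back(ch);
      in_front[idx2] = (int)els.size();
    }
  };

  double t = 0.0;
  bool finished = false;
  // record state at t = 0
  rec_times[irec] = 0.0;
  for (int h = 0; h < nholes; ++h) areas(irec, h) = 0.0;
  ++irec;

  for (int step = 1; step <= nsteps; ++step) {
    t = step * dt;
    // fire due nucleations (end of previous interval)
    for (int h = 0; h < nholes; ++h) {
      if (nucleated[h] || t_nuc[h] > t - dt) continue;
      nucleated[h] = 1;
      int r = sites(h, 0), c = sites(h, 1);
      size_t idx = (size_t)r + (size_t)c * nr;
      if (label(r, c) != 0 || in_front[idx] != 0) continue; // site overrun
      label(r, c) = h + 1;
      area_px[h] = 1;
      alive[h] = 1;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + dr8[k], c2 = c + dc8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (label(r2, c2) != 0) continue;
        size_t idx2 = (size_t)r2 + (size_t)c2 * nr;
        if (in_front[idx2] != 0) continue;
        FrontEl ch; ch.r = r2; ch.c = c2; ch.hole = h + 1;
        ch.diagonal = k >= 4;
        ch.threshold = (k >= 4 ? M_SQRT2 : 1.0) * pixel_size;
        ch.progress = 0.0; ch.load = 0.0; ch.waits = 0; ch.pinned = false; ch.retired = false;
        els.push_back(ch);
        in_front[idx2] = (int)els.size();
      }
    }
    // per-hole speed
    std::vector<double> vh(nholes, 0.0);
    std::vector<char> ramped(nholes, 0);
    for (int h = 0; h < nholes; ++h) {
      if (!nucleated[h] || !alive[h]) continue;
      double ramp = ramp_time > 0 ? std::min(1.0, (t - t_nuc[h]) / ramp_time) : 1.0;
      if (ramp < 0) ramp = 0;
      ramped[h] = ramp >= 1.0;
      double v = v_max * ramp;
      if (inv_r && area_px[h] > 0) {
        double rm = std::sqrt(area_px[h] * pix_area / M_PI);
        if (rm > r_ref) v *= r_ref / rm;
      }
      vh[h] = v;
    }
    // advance front elements (snapshot: children advance next step)
    size_t n_now = els.size();
    for (size_t i = 0; i < n_now; ++i) {
      FrontEl& e = els[i];
      if (e.retired || e.pinned) continue;
      double slow = 1.0 - e.load / pin_threshold;
      // a nearly fully loaded or creeping segment has stalled: treat as
      // pinned (the evaporative driving is spent); only after the ramp
      if (slow <= stall_frac ||
          (ramped[e.hole - 1] && vh[e.hole - 1] * slow < stall_speed)) {
        e.pinned = true; ++ev_eps_pin; continue;
      }
      e.progress += vh[e.hole - 1] * slow * dt;
      if (e.progress >= e.threshold) claim((int)i);
    }
    if (step % record_stride == 0 && irec < nrec) {
      rec_times[irec] = t;
      for (int h = 0; h < nholes; ++h) areas(irec, h) = area_px[h] * pix_area;
      ++irec;
    }
    // early exit when nothing can move any more
    bool pending_nuc = false;
    for (int h = 0; h < nholes; ++h) if (!nucleated[h]) { pending_nuc = true; break; }
    if (!pending_nuc) {
      bool any_active = false;
      for (size_t i = 0; i < els.size(); ++i)
        if (!els[i].retired && !els[i].pinned) { any_active = true; break; }
      if (!any_active) { finished = true; break; }
    }
  }
  int n_active = 0;
  for (size_t i = 0; i < els.size(); ++i)
    if (!els[i].retired && !els[i].pinned) ++n_active;
  finished = n_active == 0;
  // pad the record to the full schedule with the (static) final state
  while (irec < nrec) {
    rec_times[irec] = (double)irec * record_stride * dt;
    for (int h = 0; h < nholes; ++h) areas(irec, h) = area_px[h] * pix_area;
    ++irec;
  }

  int n = (int)cells.x.size();
  NumericMatrix cent_out(n, 2);
  LogicalVector removed(n);
  for (int i = 0; i < n; ++i) {
    cent_out(i, 0) = cells.x[i]; cent_out(i, 1) = cells.y[i];
    removed[i] = cells.removed[i] != 0;
  }
  IntegerVector events = IntegerVector::create(
    _["cells_removed"] = (int)ev_removed,
    _["push_events"] = (int)ev_pushed,
    _["fallback_placements"] = (int)ev_fallback,
    _["stranded_cells"] = (int)ev_stranded,
    _["collision_pins"] = (int)ev_collision,
    _["load_eps_pins"] = (int)ev_eps_pin,
    _["stronghold_pins"] = (int)ev_stronghold);
  return List::create(
    _["centroids"] = cent_out,
    _["removed"] = removed,
    _["hole_labels"] = label,
    _["times"] = rec_times,
    _["areas_um2"] = areas,
    _["events"] = events,
    _["finished"] = finished,
    _["n_active_fronts"] = n_active,
    _["t_end"] = t);
}
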