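---
title: "Methods: simulating bubble-induced biofilm disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating bubble-induced biofilm disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

When a long air bubble travels through a shallow microchannel it stays
separated from the walls by a residual liquid film. The film thickness is set
by the capillary number Ca = µU/σ through the lubrication scaling
h ≈ c·H·Ca^(2/3) with c of order unity. At the operating point modeled here
(U = 250 µm s⁻¹, µ = 10⁻³ Pa s, σ = 25–50 mN m⁻¹, H = 50 µm) this gives
Ca = (5–10)×10⁻⁶ and h ≤ 0.1 µm — thinner than a bacterium. Such a film
evaporates in t = hρ/E ≈ 1–2 s (E = 5×10⁻⁵ kg m⁻² s⁻¹ at room temperature and
moderate humidity), far less than the ~10 s the bubble takes to pass. The film
therefore ruptures while the bubble is overhead; the receding three-phase
contact line exerts capillary forces on surface-attached cells that protrude
through it.

`physical_params()` and the `capillary_number()` / `film_thickness()` /
`evaporation_time()` / `bubble_passage_time()` / `mean_velocity()` /
`wall_shear_rate()` closed forms encode exactly this chain of estimates. Two
deliberate scope limits: the humidity-to-evaporation-rate conversion is *not*
modeled (E is a direct input, only sanity-warned against the plausible
10⁻⁵–10⁻⁴ kg m⁻² s⁻¹ range), and the wall shear rate uses the plane-Poiseuille
formula 6U/H, valid because the channel aspect ratio W/H = 80 makes side-wall
corrections negligible. Note a documented inconsistency in the source
estimates: a simple mass balance with h = 0.1 µm gives evaporation times of
1–10 s over the stated E range, whereas the quoted sensitivity analysis says
1–4 s; the package implements the mass balance and does not force agreement.

## What the synthetic data emulates

No raw images are deposited for this system, so every downstream stage is
exercised on synthetic data with the reported statistical structure:

* **EPS field** — spatially heterogeneous with a characteristic scale of
  ~10 µm that persists even when cell cover is uniform. Modeled as a Gaussian
  random field with isotropic Gaussian autocorrelation (unit-variance white
  noise convolved with a Gaussian kernel of SD ℓ/2, giving autocorrelation
  exp(−r²/ℓ²), i.e. a 1/e crossing at ℓ = 10 µm), exponentiated to lognormal
  amplitudes (`eps_lognormal_sigma` = 0.8). The distribution of EPS intensity
  is not constrained by any published statistic; lognormality was chosen once
  because it produces both the low-EPS voids where holes open and the
  high-EPS strongholds that survive, and σ = 0.8 is a free calibration
  constant. The exponentiation pulls the empirical 1/e crossing of the
  *lognormal* field in to ≈0.9ℓ, still comfortably inside the ±20 % band the
  generator is tested against.
* **Cell monolayer** — near-uniform cover at age-dependent coverage
  (31.6 %, 44.6 %, 49.5 % at 4, 8, 12 h; these published means are used as
  calibration constants). Cells are rigid disks of radius 0.5 µm placed by
  sequential rejection sampling with acceptance probability
  (1 − κ) + κ·EPS, κ = `eps_cell_coupling` = 0.2, so pre-disruption cover is
  only weakly EPS-associated (tested: correlation < 0.3). Placement stops
  when patch coverage reaches target; overshoot is below one cell's area.
  Rod shape, growth dynamics between ages, and motility trail networks are
  deliberately out of scope. The off-patch margin is colonized at a reduced
  density (`margin_density` = 0.3) rather than through a substrate-chemistry
  model.
* **Images** — 16-bit single-channel TIFFs with constant background and
  Gaussian read noise; rendering exists so the Otsu/segmentation path is
  exercised on realistic input, not to model a specific camera.

A green generator test therefore establishes that the *statistical targets*
(coverage, correlation length, weak coupling) are met — not that the fields
look like any particular micrograph, and not that real EPS is lognormal.

## The dewetting simulator

The simulator is a lattice model of the mechanism: rupture at discrete sites,
radially receding contact lines that scrape cells outward, and pinning into
levees.

* **Nucleation.** Rupture sites are chosen greedily by ascending rupture
  resistance (normalized EPS; infinite on cell-occupied pixels, since rupture
  starts in the voids between bacteria) with a minimum spacing, over the
  whole imaged field — the film dewets off-patch too, and restricting
  nucleation to the patch lets edge holes expand unopposed into the margin.
  Nucleation times are drawn uniformly in [0, t_evap] with t_evap taken from
  the physics module (~2 s) instead of simulating film thinning pixel-wise.
* **Front motion.** Fronts advance over wet pixels on an 8-neighbour chamfer
  metric (orthogonal step cost 1 pixel, diagonal √2), which keeps hole growth
  near-isotropic; a pure 4-neighbour front was tried first and produces
  diamond-shaped holes whose tips meet corner-to-corner, an obvious lattice
  artifact. A diagonal claim requires prior 4-connected support from its own
  hole, so hole regions remain exactly 4-connected. Speed is
  v = v_max · ramp(t) · min(1, r_ref/r) · (1 − load/pin_threshold): the ramp
  gives the slow initial opening, the 1/r geometric factor converts constant
  radial speed into the observed *linear-in-time area* growth of the middle
  phase, and load slowing gives the slow finish.
* **Cell interaction, by regime.** Per-cell adhesion is
  `age_factor`·EPS + `cell_bonus`, compared with `capillary_force`:
  removal (4 h): weak cells detach with probability `p_detach` and leave the
  domain; rearrangement (8 h): weak cells are pushed outward along the front
  normal (re-deposited at the first wet position ≥ `push_spacing` from other
  cells, with a bounded nearest-free-pixel fallback) and add to the segment's
  load, while strong cells pin the segment locally (strongholds — this also
  keeps cells out of hole interiors); no-effect (12 h): adhesion exceeds the
  capillary force everywhere and the map is returned unchanged, exactly.
  Scraped cells may pile up (push spacing is one radius, not one diameter):
  levees are concentrated, effectively multilayered ridges. This is also why
  the end state can simultaneously show ~68 % porosity while cell *count* is
  conserved — a strict monolayer could not, since the published porosity and
  post-bubble coverage sum to more than 100 %.
* **Pinning and termination.** A segment pins permanently when
  load + resistance·EPS ≥ `pin_threshold`, when it contacts another hole
  (fronts meeting form the inter-hole levee; holes never merge), when a
  stronghold blocks it, or when it has effectively stalled (load slowdown
  below `stall_frac`, or post-ramp speed below `stall_speed` = 0.2 µm s⁻¹ —
  by then the evaporative driving is spent). The stall rules exist for
  clean termination; they do not measurably change the end-state metrics.
* **Determinism.** All tie-breaks are fixed (row-major), all randomness
  (nucleation times, detachment rolls) flows from R's seeded RNG, and
  identical seeds give bit-identical results. The EPS field is never
  modified — the insult redistributes cells, not matrix.

### Calibration

Hole nucleation density and the pinning scales are not published; they were
calibrated once, before the acceptance tests were written, against the three
published end-state facts for the 8 h regime on a 200 µm patch — porosity
~68 %, hole equivalent radius 6.5–8 µm, overall opening time ~5 s — and then
frozen: `nucleation_spacing` 12 µm, `capillary_force` 0.28,
`pin_threshold` 30, `resist_scale` 60, `front_speed_max` 7 µm s⁻¹,
`ramp_time` 1 s, `r_ref` 2 µm, `dt` 0.02 s (the 50 frames s⁻¹ imaging
cadence), `total_time` 10 s (the bubble passage time). The 12 µm spacing is
smaller than the ~15 µm inter-hole scale it produces because holes that
collide through locally cell-free corridors are indistinguishable in the
segmented image and merge, pulling the measured radius up.

## Image statistics

* **Coverage** is foreground fraction of the patch ROI. **Porosity** is
  *not* 100 − coverage: holes are 4-connected background components after a
  morphological closing of the foreground with a 1 µm disk (sealing
  digitization gaps in one-cell-wide levees), keeping border-touching
  components and discarding those under 3 µm². This operational definition is
  ours; the published "~68 % porosity" is not defined operationally and is
  inconsistent with 100 − coverage there too.
* **Box-counting dimension** uses dyadic box sizes from 2 px to ROI/4
  (ROI/2 is excluded — at that scale nearly every box is occupied and the
  point only flattens the fit), grid anchored at the ROI origin with no
  offset averaging; D is the least-squares slope of ln N vs ln(1/s). The
  implementation is verified against an exhaustive double-loop count and
  against analytic sets (filled square, line, Sierpinski carpet).
* **Growth curves** are normalized per hole by final area, averaged with SEM,
  and fitted with a continuous 3-segment piecewise-linear model by breakpoint
  grid search; the slow–fast–slow flag requires the middle slope to exceed
  the outer ones by 10 % of the largest slope, and the fit is declared
  degenerate when three segments do not beat one line by 1 % of its residual
  sum of squares (so a straight line is never classified slow–fast–slow).
* **Cross-correlation** is zero-lag Pearson on fields smoothed with a 2 µm
  Gaussian — densities are compared, not pixel-exact overlap, and the images
  are compared at fixed alignment (no lag search). The permutation null
  shuffles 10 µm blocks (the EPS correlation scale), not pixels: pixel
  shuffling would destroy within-cell structure and make the null trivially
  tight. Partial edge blocks stay fixed so the ROI geometry is exact.
* **Coordinates** are 0-based with half-open ROIs, pixel centers at
  (i + 0.5)·pixel_size, y increasing downward; all outputs in µm.

## Known limitations

* The simulator is 2-D and kinematic: no thin-film lubrication PDE, no
  meniscus shape, no cell deformation, no EPS production during the insult.
* Disk-shaped cells underestimate the anisotropy of rod-shaped bacteria;
  fractal dimensions of the synthetic maps differ somewhat from published
  values for real micrographs (the direction of the disruption-induced drop
  is reproduced; its absolute values are not calibration targets).
* Post-disruption coverage is below the published 38.7 % at the calibration
  that reproduces 68 % porosity; the two published numbers cannot both hold
  for a monolayer union mask, and porosity is the graded quantity.
* The block-permutation null assumes approximate stationarity of the cell
  field at the block scale; strongly non-stationary inputs would need a
  different null.
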