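# dewpatch

Bacteria colonizing a surface lay down a heterogeneous skeleton of
extracellular polymeric substances (EPS) before their cover looks uniform.
When a long air bubble passes over such an early-stage biofilm in a
microfluidic channel, the thin residual liquid film it leaves behind
(thickness h ~ H·Ca^(2/3), Ca = µU/σ ≈ 10⁻⁵, so h ≲ 0.1 µm) evaporates in a
couple of seconds, ruptures in the voids between cells, and the receding
three-phase contact line scrapes weakly adhering bacteria outward until it
pins — leaving a semi-regular pattern of ~15 µm holes separated by "bacterial
levees", with holes opening precisely where EPS was scarcest.

`dewpatch` is an R package for scientists studying biofilm mechanics and
removal. It provides, end to end:

* **Physics** — the closed-form estimates that make the mechanism plausible:
  capillary number, Bretherton film thickness, evaporation and
  bubble-passage timescales, channel mean velocity and wall shear rate.
* **Synthetic data** — a generator for EPS random fields (lognormal, ~10 µm
  correlation length) and near-uniform cell monolayers at age-dependent
  coverage (31.6 / 44.6 / 49.5 % at 4 / 8 / 12 h), rendered to 16-bit TIFFs.
  No raw images are deposited for this system, so the generator is what
  makes every downstream stage testable.
* **Simulator** — a deterministic, seeded lattice model of
  evaporation-driven dewetting with three age regimes: cell removal (4 h),
  rearrangement into levees with EPS-dependent pinning (8 h), no effect
  (12 h).
* **Morphometrics** — surface coverage, hole segmentation and porosity,
  equivalent radii, box-counting fractal dimension, mean inter-cell
  distance, and slow–linear–slow classification of hole-growth curves.
* **Correlation** — zero-lag normalized cross-correlation between EPS and
  cell maps with a spatial block-permutation null, and the pre/post fold
  change that quantifies "holes form where EPS is least".

## Worked example

```r
library(dewpatch)

physics_report()
#>      Ca film_thickness_m evaporation_time_s bubble_passage_time_s
#> 1 5e-06     1.462009e-08          0.2924018                    10
#>   mean_velocity_m_s wall_shear_rate_per_s
#> 1           0.00025                    30
```

Ca = 5×10⁻⁶ at σ = 50 mN m⁻¹; the ~15 nm film (an order-of-magnitude
estimate, ≤ 0.1 µm) evaporates in well under the 10 s the bubble needs to
pass, so rupture happens while the bubble is overhead. Shear at the wall is
a mild 30 s⁻¹ — shear alone does not detach these cells.

```r
geom  <- patch_geometry(side = 200)          # 200 µm patch, 0.25 µm/px
cfg   <- synth_config(age_h = 8)             # 44.6 % coverage, 10 µm EPS scale
eps   <- generate_eps_field(geom, cfg, seed = 11)
cells <- generate_cell_map(geom, eps, cfg, seed = 12)
res   <- run_dewetting(eps, cells, sim_config("rearrangement_8h", seed = 13))

b <- binary_patch(res$cells_final$occupancy, geom$pixel_size, geom$patch_px)
metrics_report(b)
#>   coverage_pct porosity_pct n_holes mean_hole_radius_um median_hole_radius_um
#> 1         24.4         66.7     129                 6.9                  6.25
#>   fractal_D fractal_fit_r2
#> 1      1.67          0.999

characterize_growth(res)[c("slow_fast_slow", "duration_s")]
#> slow-fast-slow: TRUE   duration: 5.54 s
```

The end state has ~67 % of the patch inside bacteria-free holes of ~7 µm
equivalent radius that opened over ~5.5 s in a slow–linear–slow profile —
the signature of ramped rupture, constant-rate area growth, and
load-limited pinning.

```r
cc <- correlation_ratio(eps$values, cells$occupancy + 0,
                        res$cells_final$occupancy + 0,
                        geom$pixel_size, roi = geom$patch_px)
#> r_before = 0.092, r_after = 0.723, ratio = 7.9

bootstrap_null(eps$values, res$cells_final$occupancy + 0, geom$pixel_size,
               roi = geom$patch_px, n = 200, seed = 14)[c("null_mean", "z_score")]
#> null mean = 0.0004, z = 16.2
```

Before the bubble, cells are only weakly associated with EPS (r ≈ 0.09);
after it, the surviving pattern correlates strongly with the *pre-bubble*
EPS map (r ≈ 0.72, ~8-fold higher), while block-permutation controls sit at
zero — the disruption pattern is dictated by the hidden EPS skeleton.

## Command line

```sh
Rscript inst/cli/dewpatch.R physics report
Rscript inst/cli/dewpatch.R synth generate --age 8 --side 200 --seed 1 --out run/
Rscript inst/cli/dewpatch.R simulate --eps run/eps.tif --cells run/cells.tif \
    --centroids run/centroids.csv --regime rearrangement_8h --seed 1 --out run/
Rscript inst/cli/dewpatch.R analyze --image run/cells_final.tif --out report.csv
Rscript inst/cli/dewpatch.R correlate --eps run/eps.tif --cells-before run/cells.tif \
    --cells-after run/cells_final.tif --n-perm 1000 --seed 1 --out corr.csv
Rscript inst/cli/dewpatch.R pipeline run --seed 1 --out run/
```

See `vignettes/dewpatch-methods.Rmd` for the model, its assumptions, the
calibration of the simulator defaults, and known limitations.
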