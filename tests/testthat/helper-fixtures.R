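# Shared fixtures. Simulator runs are cached so several test files can reuse
# the same seeded run without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

# a small 100 µm patch world at the default resolution
small_world <- function(seed = 1, age_h = 8) {
  key <- paste0("world_", seed, "_", age_h)
  if (is.null(.fixture_cache[[key]])) {
    geom <- patch_geometry(100, 10, 0.25)
    cfg <- synth_config(age_h = age_h, seed = seed)
    eps <- generate_eps_field(geom, cfg)
    cells <- generate_cell_map(geom, eps, cfg, seed = seed + 1000)
    .fixture_cache[[key]] <- list(geom = geom, cfg = cfg, eps = eps,
                                  cells = cells)
  }
  .fixture_cache[[key]]
}

# default rearrangement run on the small world
small_run <- function(seed = 1, regime = "rearrangement_8h",
                      age_h = if (regime == "removal_4h") 4 else
                              if (regime == "no_effect_12h") 12 else 8) {
  key <- paste0("run_", seed, "_", regime)
  if (is.null(.fixture_cache[[key]])) {
    w <- small_world(seed, age_h)
    sc <- sim_config(regime, seed = seed + 2000)
    .fixture_cache[[key]] <-
      list(world = w, res = suppressWarnings(run_dewetting(w$eps, w$cells, sc)))
  }
  .fixture_cache[[key]]
}

# hand-built eps_field on a given geometry
manual_eps <- function(geom, values) {
  structure(list(values = values, pixel_size = geom$pixel_size,
                 patch_px = geom$patch_px, geom = geom), class = "eps_field")
}

# Sierpinski carpet mask of a given depth (3^depth pixels per side)
sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    n <- nrow(m)
    out <- matrix(FALSE, 3 * n, 3 * n)
    for (br in 0:2) for (bc in 0:2) {
      if (br == 1 && bc == 1) next
      out[br * n + seq_len(n), bc * n + seq_len(n)] <- m
    }
    m <- out
  }
  m
}

# independent brute-force box count: exhaustive double loop over boxes
brute_box_count <- function(mask, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  count <- 0L
  for (br in seq_len(ceiling(nr / s))) {
    for (bc in seq_len(ceiling(nc / s))) {
      rows <- ((br - 1) * s + 1):min(br * s, nr)
      cols <- ((bc - 1) * s + 1):min(bc * s, nc)
      if (any(mask[rows, cols])) count <- count + 1L
    }
  }
  count
}
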