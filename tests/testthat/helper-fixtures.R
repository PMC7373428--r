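# Shared fixture builders; everything is generated in code at test time.

two_arm_config <- function(lambda = 2, n = 200, seed = 1, ...) {
  lifespan_sim_config(list(lifespan_arm("ctl"),
                           lifespan_arm("trt", lambda = lambda, ...)),
                      n_per_arm = n, seed = seed)
}

# small square-worm stack config; ROI is the iron footprint
small_stack_config <- function(f, counts_scale = 1e4, jitter = 0,
                               poisson = TRUE, seed = 1, n = 24) {
  fm <- matrix(f, n, n)
  dm <- matrix(0, n, n); dm[7:(n - 6), 7:(n - 6)] <- 1
  xanes_sim_config(fe2_fraction_map = fm, iron_density_map = dm,
                   counts_scale = counts_scale, frame_jitter_px = jitter,
                   poisson = poisson, seed = seed)
}

stack_roi <- function(cfg) cfg$iron_density_map > 0

two_worm_scene_config <- function(seed = 1, ...) {
  xfm_sim_config(worm_specs = list(
    worm_spec(centroid = c(120, 150), axes = c(100, 40), fe_density = 0.02),
    worm_spec(centroid = c(240, 320), axes = c(45, 36), fe_density = 0.05)),
    seed = seed, ...)
}

# roi_set wrapping an exact truth pixel set, for quantification checks
truth_roi_set <- function(scene, worm = 1) {
  tr <- sim_truth(scene)
  dims <- dim(scene$channels$Fe)
  lab <- matrix(0L, dims[1], dims[2])
  lab[tr$worms[[worm]]$pixels] <- 1L
  structure(list(label_map = lab, roi_ids = 1L,
                 pixel_counts = tr$worms[[worm]]$n_pixels, status = "ok",
                 pre_filter_foreground = tr$foreground),
            class = "roi_set")
}

model_spectrum <- function(em, grid = build_energy_grid()) {
  structure(list(energies = grid$energies, mu = em$mu(grid$energies)),
            class = "xanes_spectrum")
}
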