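test_that("a jitter-free stack aligns with all-zero shifts (and stays aligned)", {
  cfg <- small_stack_config(0.5, counts_scale = 1e4, jitter = 0, seed = 2)
  st <- gen_xanes_stack(cfg)
  al <- align_stack(st)
  expect_true(all(al$alignment_state == 0))
  expect_false(any(al$excluded))
  al2 <- align_stack(al)
  expect_identical(al2$alignment_state, al$alignment_state)
})

test_that("planted integer jitter is recovered exactly from the calcium channel", {
  n <- 30
  fm <- matrix(0.5, n, n)
  dm <- matrix(0, n, n); dm[12:20, 10:22] <- 1
  cfg <- xanes_sim_config(fe2_fraction_map = fm, iron_density_map = dm,
                          ca_density_map = dm, counts_scale = 1e4,
                          frame_jitter_px = 2, seed = 8)
  st <- gen_xanes_stack(cfg)
  planted <- sim_truth(st)$jitter
  al <- align_stack(st, max_shift = 5)
  # alignment is relative to frame 1, which may itself carry jitter
  rel <- planted - matrix(planted[1, ], nrow(planted), 2, byrow = TRUE)
  expect_true(all(al$alignment_state == rel))
  expect_false(any(al$excluded))
})

test_that("foil derivative-peak calibration maps to the 7112.0 eV reference", {
  g <- build_energy_grid()
  shifted <- xanes_endmember(pre_center = 7100, pre_amp = 0, edge_pos = 7110)
  off <- calibrate_energy_axis(model_spectrum(shifted))
  expect_equal(off, 2.0, tolerance = 0.02)
  ontarget <- xanes_endmember(pre_center = 7100, pre_amp = 0, edge_pos = 7112)
  expect_equal(calibrate_energy_axis(model_spectrum(ontarget)), 0,
               tolerance = 0.02)
  # no derivative maximum inside the window
  flat <- structure(list(energies = g$energies,
                         mu = 0.001 * g$energies), class = "xanes_spectrum")
  expect_error(calibrate_energy_axis(flat), "maximum")
})

test_that("normalized spectra are invariant to rescaling the raw counts", {
  cfg <- small_stack_config(0.3, poisson = FALSE)
  st <- gen_xanes_stack(cfg)
  sp <- extract_normalized_spectrum(st, stack_roi(cfg))
  st2 <- st
  st2$frames <- st$frames * 7.3
  sp2 <- extract_normalized_spectrum(st2, stack_roi(cfg))
  expect_equal(sp$mu, sp2$mu, tolerance = 1e-10)
})

test_that("a 50/50 mixture with equal edge jumps is the average of normalized endmembers", {
  # endmembers sharing the edge profile and differing only in the pre-edge
  em <- list(fe2 = xanes_endmember(pre_center = 7112.1, edge_pos = 7121),
             fe3 = xanes_endmember(pre_center = 7113.5, edge_pos = 7121))
  cfg <- small_stack_config(0.5, poisson = FALSE)
  cfg$endmembers <- em
  st <- gen_xanes_stack(cfg)
  sp <- extract_normalized_spectrum(st, stack_roi(cfg))
  E <- sp$energies
  n2 <- ferroscale:::normalize_spectrum(E, em$fe2$mu(E))
  n3 <- ferroscale:::normalize_spectrum(E, em$fe3$mu(E))
  expect_lt(max(abs(sp$mu - (n2 + n3) / 2)), 1e-8)
})

test_that("energies of excluded frames are marked missing but the spectrum survives", {
  cfg <- small_stack_config(0.5, poisson = FALSE)
  st <- gen_xanes_stack(cfg)
  st$excluded[10] <- TRUE
  sp <- extract_normalized_spectrum(st, stack_roi(cfg))
  expect_true(is.na(sp$raw[10]))
  expect_true(is.na(sp$mu[10]))
  expect_false(anyNA(sp$mu[-10]))
  expect_error(extract_normalized_spectrum(st, matrix(FALSE, 24, 24)), "empty")
})
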