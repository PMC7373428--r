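test_that("foil calibration returns density/flux and the zero-intercept slope", {
  f <- foil_calibration(data.frame(element = "Fe",
                                   known_areal_density = 50.1,
                                   measured_flux = 1000))
  expect_equal(unname(f["Fe"]), 0.0501)
  # applied back to the foil's own flux it returns the known density
  expect_equal(unname(f["Fe"]) * 1000, 50.1)
  # two standards on a perfect line through the origin share the slope
  f2 <- foil_calibration(data.frame(element = "Mn",
                                    known_areal_density = c(18.9, 37.8),
                                    measured_flux = c(500, 1000)))
  expect_equal(unname(f2["Mn"]), 18.9 / 500)
  expect_error(foil_calibration(data.frame(element = "Fe",
                                           known_areal_density = 50.1,
                                           measured_flux = 0)), "positive")
})

test_that("Compton segmentation keeps only whole-animal-sized components", {
  sc <- gen_xfm_scene(two_worm_scene_config(seed = 4))
  tr <- sim_truth(sc)
  rois <- segment_compton(sc)               # default min_pixels = 10000
  expect_equal(rois$status, "ok")
  expect_length(rois$roi_ids, 1)
  m1 <- matrix(FALSE, 300, 400); m1[tr$worms[[1]]$pixels] <- TRUE
  seg <- rois$label_map == 1
  jac <- sum(m1 & seg) / sum(m1 | seg)
  expect_gte(jac, 0.95)
  # lowering the filter below the second worm's size reveals both
  rois2 <- segment_compton(sc, min_pixels = 3000)
  expect_length(rois2$roi_ids, 2)
  expect_setequal(rois2$pixel_counts > 3000, TRUE)
})

test_that("segmentation is invariant to positive rescaling of the Compton channel", {
  sc <- gen_xfm_scene(two_worm_scene_config(seed = 6))
  rois <- segment_compton(sc)
  sc2 <- sc
  sc2$channels$Compton <- sc$channels$Compton * 2.5
  rois2 <- segment_compton(sc2)
  expect_identical(rois$label_map, rois2$label_map)
})

test_that("a featureless Compton raster yields an empty ROI set with a warning, not an error", {
  sc <- gen_xfm_scene(two_worm_scene_config(seed = 2))
  sc$channels$Compton <- matrix(7, 300, 400)
  expect_warning(rois <- segment_compton(sc), "foreground")
  expect_length(rois$roi_ids, 0)
  expect_equal(rois$status, "no-foreground")
})

test_that("labelling is 8-connected so thin diagonal bodies stay whole", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:5, 1:5)] <- TRUE     # a diagonal line
  lab <- ferroscale:::label_components(m)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 5)
})

test_that("Currie critical level follows the paired-blank formula", {
  expect_equal(currie_threshold(rep(0, 10))$critical_level, 0)
  lv <- currie_threshold(rep(100, 50), alpha = 0.05)
  expect_equal(lv$critical_level, qnorm(0.95) * sqrt(200), tolerance = 1e-12)
  expect_equal(lv$critical_level, 23.3, tolerance = 0.01)
  expect_error(currie_threshold(c(3, -1)), "non-negative")
  expect_error(currie_threshold(numeric(0)), "background")
})

test_that("paired-blank false-detection rate sits near alpha on pure background", {
  set.seed(60)
  B <- 50; n <- 4e4
  lv <- currie_threshold(rpois(2e4, B), alpha = 0.05)
  rate <- mean(rpois(n, B) - rpois(n, B) > lv$critical_level)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("ROI quantification does the arithmetic and stays additive", {
  sc <- gen_xfm_scene(two_worm_scene_config(seed = 8))
  tr <- sim_truth(sc)
  rois <- truth_roi_set(sc)
  cur <- currie_threshold(sc$channels$Fe[!tr$foreground])
  q <- quantify_rois(sc, rois, tr$fe_factor_ugcm2, cur)
  # exact identity: total mass = mean areal density x area
  expect_identical(q$total_mass, q$mean_areal_density * q$area)
  # recovery within 3 Poisson sigma of the planted mass
  sig <- sqrt(sum(sc$channels$Fe[tr$worms[[1]]$pixels])) /
    tr$config$fe_gain * 0.64
  expect_lt(abs(q$total_mass - tr$worms[[1]]$fe_total_pg), 3 * sig)
  # additivity: splitting the ROI in two sums to the whole
  lab <- rois$label_map
  px <- which(lab == 1)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[px[seq_len(5000)]] <- 1L
  lab2[px[-seq_len(5000)]] <- 2L
  rois2 <- rois; rois2$label_map <- lab2; rois2$roi_ids <- 1:2
  rois2$pixel_counts <- c(5000L, length(px) - 5000L)
  q2 <- quantify_rois(sc, rois2, tr$fe_factor_ugcm2, cur)
  expect_equal(sum(q2$total_mass), q$total_mass, tolerance = 1e-12)
})

test_that("an all-background ROI quantifies to zero under Currie zeroing", {
  cfg <- xfm_sim_config(worm_specs = worm_spec(c(60, 60), c(25, 15)),
                        scene_shape = c(120, 120), background_rate = 3,
                        seed = 10)
  sc <- gen_xfm_scene(cfg)
  tr <- sim_truth(sc)
  lab <- matrix(0L, 120, 120); lab[1:20, 1:20] <- 1L  # far from the worm
  rois <- structure(list(label_map = lab, roi_ids = 1L,
                         pixel_counts = 400L, status = "ok",
                         pre_filter_foreground = tr$foreground),
                    class = "roi_set")
  cur <- currie_threshold(sc$channels$Fe[!tr$foreground])
  q <- quantify_rois(sc, rois, tr$fe_factor_ugcm2, cur)
  # Currie zeroing suppresses the background region to (near) zero: the
  # residue is only the alpha-rate of false exceedances
  expect_lt(q$total_mass / tr$worms[[1]]$fe_total_pg, 0.01)
  expect_gt(mean(sc$channels$Fe[rois$label_map == 1] -
                 cur$background_mean <= cur$critical_level), 0.9)
})

test_that("unknown ROI ids are rejected by name", {
  sc <- gen_xfm_scene(two_worm_scene_config(seed = 3))
  rois <- truth_roi_set(sc)
  expect_error(quantify_rois(sc, rois, 0.1, NULL, roi_ids = c(1, 7)), "7")
})
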