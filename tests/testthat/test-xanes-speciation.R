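test_that("pre-edge fit pins pure-endmember centroids to their generator truth", {
  for (em in list(c(f = 1, c = 7112.1), c(f = 0, c = 7113.5))) {
    cfg <- small_stack_config(em[["f"]], poisson = FALSE)
    st <- gen_xanes_stack(cfg)
    sp <- extract_normalized_spectrum(st, stack_roi(cfg))
    pe <- fit_pre_edge(sp)
    expect_lt(abs(pe$centroid - em[["c"]]), 0.05)
    expect_gt(pe$gaussian[["width"]], 0)
    expect_true(pe$fit_ci[1] <= pe$centroid && pe$centroid <= pe$fit_ci[2])
  }
})

test_that("equal-amplitude 50/50 mixture centres at the amplitude-weighted midpoint", {
  # shared edge profile isolates the pre-edge blend, whose symmetric
  # 50/50 sum centres at the midpoint of the two component centers
  cfg <- small_stack_config(0.5, poisson = FALSE)
  cfg$endmembers <- list(
    fe2 = xanes_endmember(pre_center = 7112.1, edge_pos = 7122),
    fe3 = xanes_endmember(pre_center = 7113.5, edge_pos = 7122))
  st <- gen_xanes_stack(cfg)
  sp <- extract_normalized_spectrum(st, stack_roi(cfg))
  pe <- fit_pre_edge(sp)
  expect_lt(abs(pe$centroid - 7112.8), 0.05)
  # with the study endmembers (edges differing too) the pull stays small
  cfg2 <- small_stack_config(0.5, poisson = FALSE)
  pe2 <- fit_pre_edge(extract_normalized_spectrum(gen_xanes_stack(cfg2),
                                                  stack_roi(cfg2)))
  expect_lt(abs(pe2$centroid - 7112.8), 0.1)
})

test_that("centroid endpoints invert to fractions 1 and 0 under the linear calibration", {
  cal <- speciation_calibration(endmembers = NULL)  # linear fallback
  mk <- function(centroid) {
    structure(list(centroid = centroid), class = "preedge_fit")
  }
  sp <- structure(list(energies = 1, mu = 1, raw = NULL), class = "xanes_spectrum")
  expect_equal(estimate_fe2_fraction(mk(7112.1), sp, cal, n_boot = 0)$fe2_fraction, 1)
  expect_equal(estimate_fe2_fraction(mk(7113.5), sp, cal, n_boot = 0)$fe2_fraction, 0)
  out <- estimate_fe2_fraction(mk(7111.0), sp, cal, n_boot = 0)
  expect_true(out$clipped)
  expect_equal(out$fe2_fraction, 1)
  expect_error(speciation_calibration(centroid_fe2_ref = 7113.5,
                                      centroid_fe3_ref = 7113.5), "below")
})

test_that("both estimation modes recover planted fractions within 0.05, monotonically", {
  cal <- speciation_calibration()
  fs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  est <- vapply(fs, function(f) {
    cfg <- small_stack_config(f, seed = 300 + round(100 * f))
    st <- gen_xanes_stack(cfg)
    sp <- extract_normalized_spectrum(st, stack_roi(cfg))
    pe <- fit_pre_edge(sp)
    c(cen = estimate_fe2_fraction(pe, sp, cal, "centroid", n_boot = 0)$fe2_fraction,
      der = estimate_fe2_fraction(NULL, sp, cal, "derivative", n_boot = 0)$fe2_fraction)
  }, numeric(2))
  expect_true(all(abs(est["cen", ] - fs) <= 0.05))
  expect_true(all(abs(est["der", ] - fs) <= 0.05))
  expect_true(all(diff(est["cen", ]) > 0))
  expect_true(all(diff(est["der", ]) > 0))
})

test_that("fraction and centroid are invariant to count rescaling", {
  cal <- speciation_calibration()
  cfg <- small_stack_config(0.4, poisson = FALSE)
  st <- gen_xanes_stack(cfg)
  st2 <- st; st2$frames <- st$frames * 5
  f1 <- estimate_fe2_fraction(NULL, extract_normalized_spectrum(st, stack_roi(cfg)),
                              cal, "centroid", n_boot = 0)
  f2 <- estimate_fe2_fraction(NULL, extract_normalized_spectrum(st2, stack_roi(cfg)),
                              cal, "centroid", n_boot = 0)
  expect_equal(f1$fe2_fraction, f2$fe2_fraction, tolerance = 1e-8)
})

test_that("bootstrap CI covers the truth at generator default counts", {
  cal <- speciation_calibration()
  hits <- vapply(1:5, function(s) {
    cfg <- small_stack_config(0.3, seed = 500 + s)
    st <- gen_xanes_stack(cfg)
    sp <- extract_normalized_spectrum(st, stack_roi(cfg))
    r <- estimate_fe2_fraction(fit_pre_edge(sp), sp, cal, "centroid",
                               n_boot = 60, seed = s)
    r$ci95[1] <= 0.3 && 0.3 <= r$ci95[2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("group comparison reports deltas against the reference with honest CIs", {
  mk <- function(f) structure(list(fe2_fraction = f), class = "speciation_result")
  res <- lapply(c(0.30, 0.32, 0.28, 0.20, 0.22, 0.18), mk)
  grp <- rep(c("aged", "treated"), each = 3)
  out <- compare_groups(res, grp, reference = "aged", n_boot = 500, seed = 1)
  expect_equal(out$delta[out$group == "aged"], 0)
  expect_equal(out$delta[out$group == "treated"], -0.1, tolerance = 1e-9)
  expect_true(all(out$ci_available))
  # identical groups: delta zero, CI spans zero
  res2 <- lapply(c(0.3, 0.31, 0.29, 0.3, 0.31, 0.29), mk)
  out2 <- compare_groups(res2, grp, "aged", n_boot = 500, seed = 2)
  trt <- out2[out2$group == "treated", ]
  expect_true(trt$ci_lo <= 0 && 0 <= trt$ci_hi)
  # single-member groups still yield a delta, with the CI flagged off
  out3 <- compare_groups(list(mk(0.3), mk(0.4)), c("a", "b"), "a", n_boot = 100)
  expect_false(out3$ci_available[out3$group == "b"])
  expect_equal(out3$delta[out3$group == "b"], 0.1)
  expect_error(compare_groups(list(mk(0.3)), "a", reference = "zz"), "empty")
})
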