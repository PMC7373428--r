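test_that("generator is bit-reproducible under a fixed seed", {
  a <- gen_lifespan(two_arm_config(seed = 42))
  b <- gen_lifespan(two_arm_config(seed = 42))
  expect_identical(a$day, b$day)
  c <- gen_lifespan(two_arm_config(seed = 43))
  expect_false(identical(a$day, c$day))
})

test_that("frailty-free marginal is exactly Weibull: S(b*lambda) near exp(-1)", {
  cfg <- lifespan_sim_config(list(
    lifespan_arm("a", shape = 3, scale = 10, frailty_var = 0, lambda = 1.5)),
    n_per_arm = 20000, seed = 5)
  co <- gen_lifespan(cfg)
  expect_equal(mean(co$day > 10 * 1.5), exp(-1), tolerance = 0.02)
})

test_that("closed-form Gamma-frailty marginal: sigma2=1, k=1, b=1 gives S(1) = 1/2", {
  cfg <- lifespan_sim_config(list(
    lifespan_arm("a", shape = 1, scale = 1, frailty_var = 1)),
    n_per_arm = 40000, seed = 9)
  co <- gen_lifespan(cfg)
  expect_equal(mean(co$day > 1), 0.5, tolerance = 0.02)
  # and the analytic law the generator inverts: S(t) = 1/(1+t)
  expect_equal(mean(co$day > 3), 0.25, tolerance = 0.02)
})

test_that("a pure lambda = 2 arm doubles the KM median", {
  co <- gen_lifespan(two_arm_config(lambda = 2, n = 5000, seed = 11))
  m <- vapply(split(as.data.frame(co), co$arm),
              function(d) km_curve(d$day, d$event)$median, numeric(1))
  expect_equal(unname(m[["trt"]] / m[["ctl"]]), 2, tolerance = 0.05)
  expect_true(sim_truth(co)$pure_scaling)
})

test_that("pure scaling shifts log-times by a location constant only", {
  co <- gen_lifespan(two_arm_config(lambda = 2, n = 3000, seed = 13))
  lt <- split(log(co$day), co$arm)
  ks <- suppressWarnings(ks.test(lt$ctl, lt$trt - log(2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("shape or frailty deltas clear the pure_scaling flag", {
  co <- gen_lifespan(two_arm_config(dlog_shape = log(2), seed = 1))
  expect_false(sim_truth(co)$pure_scaling)
})

test_that("invalid arm parameters are rejected naming the field", {
  expect_error(lifespan_arm("a", shape = -1), "shape")
  expect_error(lifespan_arm("a", scale = 0), "scale")
  expect_error(lifespan_arm("a", lambda = 0), "lambda")
  expect_error(lifespan_arm("a", frailty_var = -0.1), "frailty_var")
})

test_that("censoring and day-discretized scoring behave as configured", {
  cfg <- lifespan_sim_config(list(lifespan_arm("a")), n_per_arm = 500,
                             censor_day = 8, discretize = TRUE, seed = 3)
  co <- gen_lifespan(cfg)
  expect_true(all(co$day <= 8))
  expect_true(all(co$day == round(co$day)))
  expect_true(any(co$event == 0))
  expect_true(all(co$event[co$day < 8] == 1))
})

test_that("cohort CSV round-trips unchanged and validates on read", {
  co <- gen_lifespan(two_arm_config(n = 30, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$day, co$day)
  expect_equal(as.character(back$arm), as.character(co$arm))
  bad <- as.data.frame(co); bad$day[3] <- -1
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "row\\(s\\) 3")
})
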