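test_that("the marginal frailty law has its closed forms", {
  # sigma2 = 1, k = 1, b = 1: S(t) = 1/(1+t)
  expect_equal(sweibgamma(2, 1, 1, 1), 1 / 3, tolerance = 1e-9)
  expect_equal(sweibgamma(1, 1, 1, 1), 1 / 2, tolerance = 1e-9)
  # sigma2 -> 0 limit is Weibull, continuously across the floor
  t <- c(0.5, 1, 2, 5)
  expect_equal(sweibgamma(t, 3, 2, 0), pweibull(t, 3, 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(dweibgamma(t, 3, 2, 1e-8), dweibull(t, 3, 2), tolerance = 1e-5)
  # density integrates against survival: -d/dt S = f (finite difference)
  h <- 1e-6
  expect_equal((sweibgamma(2 - h, 4, 10, 0.5) - sweibgamma(2 + h, 4, 10, 0.5)) / (2 * h),
               dweibgamma(2, 4, 10, 0.5), tolerance = 1e-5)
  # population hazard decelerates under frailty
  hz <- hweibgamma(seq(0.5, 30, 0.5), 3, 10, 1)
  expect_true(which.max(hz) < length(hz))
})

test_that("a frailty-free cohort is fitted like a Weibull model (survreg cross-check)", {
  ks <- bs <- s2s <- numeric(3)
  for (s in 1:3) {
    co <- gen_lifespan(lifespan_sim_config(lifespan_arm("a", frailty_var = 0),
                                           n_per_arm = 2000, seed = s))
    fw <- fit_weibull_gamma(co)
    sr <- survival::survreg(survival::Surv(day, event) ~ 1, data = co,
                            dist = "weibull")
    # the frailty model nests Weibull, so its maximized likelihood can
    # never fall below the Weibull one
    expect_gte(fw$loglik, unclass(logLik(sr))[1] - 1e-4)
    ks[s] <- exp(fw$params[["log_k"]])
    bs[s] <- exp(fw$params[["log_b"]])
    s2s[s] <- exp(fw$params[["log_s2"]])
  }
  expect_equal(mean(ks), 4, tolerance = 0.05)
  expect_equal(mean(bs), 8.5, tolerance = 0.05)
  expect_lt(max(s2s), 0.1)   # frailty variance sits at or near the floor
})

test_that("shape, scale, frailty and lambda are recovered from a two-arm cohort", {
  cfg <- lifespan_sim_config(list(
    lifespan_arm("ctl", shape = 4, scale = 10, frailty_var = 0.5),
    lifespan_arm("trt", shape = 4, scale = 10, frailty_var = 0.5, lambda = 2)),
    n_per_arm = 2000, seed = 17)
  fit <- fit_weibull_gamma(gen_lifespan(cfg))
  ap <- ferroscale:::arm_params(fit)
  expect_equal(ap$k[1], 4, tolerance = 0.10)
  expect_equal(ap$b[1], 10, tolerance = 0.10)
  expect_equal(ap$sigma2[1], 0.5, tolerance = 0.25)
  expect_equal(fit$params[["dlog_b.trt"]], log(2), tolerance = 0.05)
})

test_that("likelihood-ratio selection keeps the scaling-only model under pure scaling", {
  picks <- vapply(1:6, function(s) {
    co <- gen_lifespan(two_arm_config(lambda = 2, n = 300, seed = 950 + s))
    lrt_select(co)$best$model_label
  }, character(1))
  expect_gte(mean(picks == "scaling-only"), 0.5)
})

test_that("a planted frailty departure is selected with good power", {
  picks <- vapply(1:5, function(s) {
    cfg <- lifespan_sim_config(list(
      lifespan_arm("ctl", frailty_var = 0.5),
      lifespan_arm("trt", frailty_var = 0.5, lambda = 2, dlog_frailty = -1.5)),
      n_per_arm = 500, seed = 970 + s)
    sel <- lrt_select(gen_lifespan(cfg))
    grepl("frailty|full", sel$best$model_label)
  }, logical(1))
  expect_gte(mean(picks), 0.8)
})

test_that("identical log-likelihoods break ties toward the simpler model", {
  co <- gen_lifespan(two_arm_config(lambda = 2, n = 200, seed = 55))
  f0 <- fit_weibull_gamma(co, "scale")
  # candidates forced to the same log-likelihood: no addition is significant
  f1 <- fit_weibull_gamma(co, c("scale", "shape"))
  f1$loglik <- f0$loglik
  f2 <- fit_weibull_gamma(co, c("scale", "frailty"))
  f2$loglik <- f0$loglik
  sel <- lrt_select(fits = list("scaling-only" = f0, "+shape" = f1,
                                "+frailty" = f2,
                                "full" = fit_weibull_gamma(co, c("scale", "shape", "frailty"))))
  expect_equal(sel$best$model_label, "scaling-only")
})

test_that("goodness of fit is calibrated for well-specified data and fails a bimodal mixture", {
  chis <- vapply(1:5, function(s) {
    co <- gen_lifespan(lifespan_sim_config(
      lifespan_arm("a", shape = 4, scale = 10, frailty_var = 0.4),
      n_per_arm = 1000, seed = 100 + s))
    g <- gof_chisq(fit_weibull_gamma(co), n_bins = 8)
    expect_equal(g$df, 7)
    g$chisq
  }, numeric(1))
  expect_lt(abs(mean(chis) - 7), 6)
  # misspecification: bimodal mixture dressed as one arm
  set.seed(77)
  tm <- c(rweibull(500, 8, 4), rweibull(500, 8, 16))
  mix <- data.frame(day = tm, event = 1L, arm = factor("a"))
  fit <- fit_weibull_gamma(mix)
  g <- gof_chisq(fit, n_bins = 8)
  expect_lt(g$p, 0.001)
})

test_that("small samples merge GOF bins and tiny ones are rejected", {
  co <- gen_lifespan(lifespan_sim_config(lifespan_arm("a"), n_per_arm = 25,
                                         seed = 2))
  fit <- fit_weibull_gamma(co)
  g <- gof_chisq(fit, n_bins = 10)
  expect_lte(g$n_bins, 5)
  tiny <- as.data.frame(gen_lifespan(lifespan_sim_config(lifespan_arm("a"),
                                                         n_per_arm = 12,
                                                         seed = 3)))
  expect_error(gof_chisq(fit, data = tiny[1:10, ], n_bins = 10), "bins")
})
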