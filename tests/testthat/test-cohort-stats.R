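test_that("Wilson interval hits its closed form and endpoint behaviour", {
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_equal(wilson_ci(10, 10)$upper, 1)
  w <- wilson_ci(50, 100)
  # closed-form oracle
  z <- qnorm(0.975); p <- 0.5; n <- 100
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(w$lower, lo, tolerance = 1e-14)
  expect_equal(w$lower, prop.test(50, 100, correct = FALSE)$conf.int[1],
               tolerance = 1e-10)
  # always inside [0,1] and containing the point estimate
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:60, 1); k <- sample(0:n, 1)
    ww <- wilson_ci(k, n)
    expect_true(ww$lower >= 0 && ww$upper <= 1)
    expect_true(ww$lower <= k / n && k / n <= ww$upper)
  }
  expect_error(wilson_ci(5, 10, conf = 1.2), "conf")
})

test_that("N-1 chi-square is the Pearson statistic rescaled by (N-1)/N", {
  set.seed(8)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 20) + 1, 2)
    o <- n1_chisq(tb)
    pear <- suppressWarnings(chisq.test(tb, correct = FALSE)$statistic)
    expect_equal(o$chisq, unname(pear) * (sum(tb) - 1) / sum(tb),
                 tolerance = 1e-12)
    expect_equal(n1_chisq(tb[2:1, ])$chisq, o$chisq, tolerance = 1e-12)
  }
  expect_equal(n1_chisq(matrix(c(10, 10, 5, 5), 2))$chisq, 0)
  expect_error(n1_chisq(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("two-proportion z is antisymmetric and squares to the Pearson chi-square", {
  a <- two_prop_z(30, 40, 20, 45)
  b <- two_prop_z(20, 45, 30, 40)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)
  tb <- matrix(c(30, 10, 20, 25), 2)
  expect_equal(a$Z^2,
               unname(suppressWarnings(chisq.test(tb, correct = FALSE)$statistic)),
               tolerance = 1e-12)
  expect_equal(two_prop_z(5, 10, 10, 20)$Z, 0)
  expect_error(two_prop_z(1, 0, 2, 5), "trial")
})

test_that("one-way ANOVA squares the two-group pooled t and nulls identical groups", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  om <- omnibus(c(x, y), rep(c("a", "b"), c(20, 25)), "anova", "sidak")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(om$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(om$df, c(1, 43))
  same <- omnibus(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                  "anova", "tukey")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms, Dunn p-adj >= p", {
  set.seed(4)
  v <- c(rnorm(15), rnorm(15, 1), rnorm(12, 2))
  g <- rep(c("a", "b", "c"), c(15, 15, 12))
  o1 <- omnibus(v, g, "kruskal", "dunn_sidak")
  o2 <- omnibus(exp(v), g, "kruskal", "dunn_sidak")
  expect_equal(o1$statistic, o2$statistic, tolerance = 1e-12)
  expect_equal(o1$statistic,
               unname(kruskal.test(v, factor(g))$statistic), tolerance = 1e-12)
  expect_true(all(o1$posthoc$p_adj >= o1$posthoc$p - 1e-15))
  expect_error(omnibus(v, g, "kruskal", "tukey"), "anova")
  expect_error(omnibus(c(1, 2, 3), c("a", "a", "b"), "anova", "tukey"),
               "fewer than 2")
})

test_that("normality gate flags skewed data and passes Gaussian data", {
  set.seed(6)
  gaussian <- rnorm(150)
  skewed <- rexp(150)
  expect_gt(dagostino_pearson(gaussian)$p, 0.01)
  expect_lt(dagostino_pearson(skewed)$p, 0.01)
  om <- omnibus(c(gaussian[1:20], rnorm(20, 2)), rep(c("a", "b"), each = 20),
                "anova", "tukey", normality_check = TRUE)
  expect_length(om$normality, 2)
  expect_error(dagostino_pearson(rnorm(5)), "at least 9")
})

test_that("linear regression reports slope, R2 and a calibrated null p", {
  o <- suppressWarnings(linreg(1:5, 2 * (1:5) + 3))
  expect_equal(o$slope, 2, tolerance = 1e-12)
  expect_equal(o$r_squared, 1, tolerance = 1e-12)
  set.seed(10)
  covered <- vapply(1:40, function(i) {
    x <- rnorm(50); y <- rnorm(50)
    ci <- confint(linreg(x, y)$fit)[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_error(linreg(rep(1, 5), rnorm(5)), "constant")
  expect_error(linreg(1:2, 1:2), "3 points")
})
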