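#' Wilson score confidence interval for a proportion
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level in (0, 1).
#' @return A list with \code{estimate}, \code{lower}, \code{upper}.
#' @examples
#' wilson_ci(50, 100)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (conf <= 0 || conf >= 1) stopf("'conf' must be in (0, 1)")
  if (n < 1) stopf("'n' must be >= 1")
  if (k < 0 || k > n) stopf("'k' must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, center - half),
       upper = min(1, center + half))
}

#' N-1 chi-squared test on a 2x2 table
#'
#' Pearson's chi-square (uncorrected) rescaled by \eqn{(N-1)/N}, referred
#' to chi-square with 1 df.
#'
#' @param table a 2x2 matrix of counts with all margins positive.
#' @return A list with \code{chisq}, \code{p}, \code{pearson}.
#' @export
n1_chisq <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stopf("'table' must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("all table margins must be positive")
  N <- sum(table)
  E <- outer(rowSums(table), colSums(table)) / N
  pearson <- sum((table - E)^2 / E)
  chisq <- pearson * (N - 1) / N
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
       pearson = pearson)
}

#' Two-proportion z-test (pooled variance, no continuity correction)
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return A list with \code{Z} and two-sided \code{p}.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stopf("both groups need at least one trial")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(Z = z, p = 2 * pnorm(-abs(z)))
}

#' Hill-curve fit to dose-lethality proportions
#'
#' Binomial maximum likelihood for
#' \eqn{P(d) = \mathrm{lo} + (\mathrm{hi}-\mathrm{lo})\,
#' d^h/(d^h + \mathrm{LD50}^h)} on linear dose; asymptotes fixed at 0 and
#' 1 by default (set \code{free_asymptotes} for partially protective or
#' background lethality).  LD50 and slope are optimized on the log scale,
#' with Wald CIs from the observed information.
#'
#' @param data data frame with either per-animal rows (\code{dose},
#'   \code{dead}) or aggregated rows (\code{dose}, \code{deaths},
#'   \code{n}).
#' @param free_asymptotes also fit lower/upper asymptotes.
#' @return A list of class \code{"sigmoid_fit"}: \code{ld50}, \code{hill},
#'   \code{ld50_ci}, \code{asymptotes}, \code{loglik}, \code{covariance}
#'   (log-parameter scale).
#' @export
fit_sigmoid <- function(data, free_asymptotes = FALSE) {
  if (all(c("dose", "dead") %in% names(data)) && !"deaths" %in% names(data)) {
    agg <- aggregate(dead ~ dose, data, function(x) c(sum(x), length(x)))
    data <- data.frame(dose = agg$dose, deaths = agg$dead[, 1],
                       n = agg$dead[, 2])
  }
  if (!all(c("dose", "deaths", "n") %in% names(data)))
    stopf("'data' needs (dose, dead) per animal or (dose, deaths, n)")
  if (length(unique(data$dose)) < 4) stopf("need at least 4 dose levels")
  if (all(data$deaths == 0) || all(data$deaths == data$n))
    stopf("all-0 or all-1 responses: LD50 is unidentifiable")
  nll <- function(p) {
    L <- exp(p[1]); h <- exp(p[2])
    lo <- if (free_asymptotes) plogis(p[3]) * 0.5 else 0
    hi <- if (free_asymptotes) 0.5 + plogis(p[4]) * 0.5 else 1
    pr <- lo + (hi - lo) * hill_p(data$dose, L, h)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(dbinom(data$deaths, data$n, pr, log = TRUE))
  }
  # start LD50 near the dose bracketing half response
  prop <- data$deaths / data$n
  L0 <- data$dose[which.min(abs(prop - 0.5))]
  if (L0 <= 0) L0 <- stats::median(data$dose[data$dose > 0])
  p0 <- c(log(L0), log(2), if (free_asymptotes) c(0, 0))
  fit <- stats::optim(p0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  covar <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA, length(p0), length(p0)))
  se_logL <- sqrt(covar[1, 1])
  ld50 <- exp(fit$par[1])
  structure(list(ld50 = ld50, hill = exp(fit$par[2]),
                 ld50_ci = exp(fit$par[1] + c(-1.96, 1.96) * se_logL),
                 asymptotes = if (free_asymptotes)
                   c(lower = plogis(fit$par[3]) * 0.5,
                     upper = 0.5 + plogis(fit$par[4]) * 0.5)
                 else c(lower = 0, upper = 1),
                 loglik = -fit$value, covariance = covar,
                 data = data),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> LD50 = %.3f (95%% CI %.3f-%.3f), Hill slope %.2f\n",
              x$ld50, x$ld50_ci[1], x$ld50_ci[2], x$hill))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(ld50 = object$ld50, hill = object$hill, object$asymptotes)
}

#' @export
predict.sigmoid_fit <- function(object, dose, ...) {
  a <- object$asymptotes
  a[["lower"]] + (a[["upper"]] - a[["lower"]]) *
    hill_p(dose, object$ld50, object$hill)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness transform of D'Agostino (1970) and the kurtosis
#' transform of Anscombe and Glynn (1983) into
#' \eqn{K^2 = Z_1^2 + Z_2^2 \sim \chi^2_2}.
#'
#' @param x numeric sample (n >= 9).
#' @return A list with \code{K2}, \code{p}, \code{Z_skew}, \code{Z_kurt}.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 9) stopf("need at least 9 observations")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness: D'Agostino
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  dlt <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- dlt * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  Z2 <- ((1 - 2 / (9 * A)) -
         ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(K2 = K2, p = pchisq(K2, 2, lower.tail = FALSE),
       Z_skew = Z1, Z_kurt = Z2)
}

#' One-way omnibus test with post hoc pairwise comparisons
#'
#' Either a one-way ANOVA (\code{stats::aov}) with Tukey HSD or
#' Sidak-adjusted pooled-variance pairwise t tests, or a Kruskal-Wallis
#' test (\code{stats::kruskal.test}, tie-corrected H) with Dunn's
#' rank-based pairwise z tests under Sidak adjustment.  A
#' D'Agostino-Pearson normality report per group is attached when
#' requested (the usual gate for choosing between the two).
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, >= 2 values each).
#' @param kind "anova" or "kruskal".
#' @param posthoc "tukey", "sidak" (pairwise t) or "dunn_sidak" (Dunn's
#'   test, only with \code{kind = "kruskal"}).
#' @param normality_check attach per-group D'Agostino-Pearson results.
#' @return A list of class \code{"omnibus_result"}: \code{statistic}
#'   (F or H), \code{df} (df pair for F, single df for H), \code{p},
#'   \code{posthoc} (data frame of pairwise comparisons with adjusted p),
#'   \code{normality} (or NULL).
#' @export
omnibus <- function(values, groups, kind = c("anova", "kruskal"),
                    posthoc = c("tukey", "sidak", "dunn_sidak"),
                    normality_check = FALSE) {
  kind <- match.arg(kind)
  posthoc <- match.arg(posthoc)
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stopf("need at least two groups")
  cnt <- table(g)
  if (any(cnt < 2)) stopf("group '%s' has fewer than 2 values",
                          names(cnt)[which(cnt < 2)[1]])
  norm <- NULL
  if (normality_check)
    norm <- lapply(split(values, g), function(v)
      tryCatch(dagostino_pearson(v), error = function(e) NULL))
  if (kind == "anova") {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1]]
    stat <- an[1, "F value"]; df <- c(an[1, "Df"], an[2, "Df"])
    p <- an[1, "Pr(>F)"]
    ph <- switch(posthoc,
                 tukey = {
                   tk <- stats::TukeyHSD(fit)$g
                   data.frame(comparison = rownames(tk),
                              diff = tk[, "diff"], p_adj = tk[, "p adj"],
                              row.names = NULL)
                 },
                 sidak = sidak_pairwise_t(values, g),
                 dunn_sidak = stopf("dunn_sidak applies to kind = 'kruskal'"))
  } else {
    kw <- stats::kruskal.test(values, g)
    stat <- unname(kw$statistic); df <- unname(kw$parameter); p <- kw$p.value
    ph <- switch(posthoc,
                 dunn_sidak = dunn_sidak_test(values, g),
                 tukey = stopf("tukey applies to kind = 'anova'"),
                 sidak = sidak_pairwise_t(values, g))
  }
  structure(list(statistic = stat, df = df, p = p, kind = kind,
                 posthoc = ph, normality = norm),
            class = "omnibus_result")
}

sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

sidak_pairwise_t <- function(values, g) {
  levs <- levels(g)
  n <- table(g)
  means <- tapply(values, g, mean)
  N <- length(values)
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) /
    (N - length(levs))
  pairs <- combn(levs, 2)
  m <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    tt <- (means[[pr[1]]] - means[[pr[2]]]) / se
    p <- 2 * pt(-abs(tt), N - length(levs))
    c(diff = means[[pr[1]]] - means[[pr[2]]], t = tt, p = p)
  })
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
             diff = out["diff", ], t = out["t", ],
             p = out["p", ], p_adj = sidak_adjust(out["p", ], m),
             row.names = NULL)
}

dunn_sidak_test <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(values)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  levs <- levels(g)
  pairs <- combn(levs, 2)
  m <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tiecorr) *
               (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = out["z", ], p = out["p", ],
             p_adj = sidak_adjust(out["p", ], m), row.names = NULL)
}

#' @export
print.omnibus_result <- function(x, ...) {
  if (x$kind == "anova")
    cat(sprintf("<omnibus_result> ANOVA F(%d, %d) = %.3f, p = %.3g\n",
                x$df[1], x$df[2], x$statistic, x$p))
  else
    cat(sprintf("<omnibus_result> Kruskal-Wallis H(%d) = %.3f, p = %.3g\n",
                x$df, x$statistic, x$p))
  invisible(x)
}

#' Ordinary least squares regression of y on x
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @return A list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p} (slope t test), \code{fit} (the underlying \code{lm}).
#' @export
linreg <- function(x, y) {
  if (length(x) < 3) stopf("need at least 3 points")
  if (stats::sd(x) == 0) stopf("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = sm$coefficients[2, 4], fit = fit)
}
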