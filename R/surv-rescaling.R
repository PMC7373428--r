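#' Permutation Kolmogorov-Smirnov test for departure from temporal rescaling
#'
#' Under pure temporal rescaling an intervention shifts log survival times
#' by a constant, so after removing arm effects with an accelerated failure
#' time fit the residual distributions of all arms coincide.  The statistic
#' is the largest censoring-aware two-sample sup-distance
#' \eqn{D = \sup_e |\hat F_a(e) - \hat F_{a'}(e)|} between arm-wise
#' Kaplan-Meier estimates of the residual distribution, maximized over arm
#' pairs.  The null distribution accounts for the estimated AFT
#' coefficients (the "modified" aspect): arm labels are permuted and the
#' AFT model refitted for every permutation before recomputing D.
#' \eqn{p = (1 + \#\{D^* \ge D\})/(n_{\mathrm{perm}} + 1)}.
#'
#' @param aft a [fit_buckley_james()] fit.
#' @param n_perm number of label permutations (< 100 draws a warning).
#' @param seed RNG seed for the permutations.
#' @return A list of class \code{"rescaling_test"}: \code{D}, \code{p},
#'   \code{n_perm}, \code{seed}, \code{perm_D}.
#' @export
ks_rescaling_test <- function(aft, n_perm = 1000, seed = 1) {
  if (!inherits(aft, "bj_fit")) stopf("'aft' must be a fit_buckley_james() fit")
  if (is.null(aft$event)) stopf("residuals carry no censoring flags")
  if (nlevels(aft$group) < 2) stopf("need at least two arms")
  if (n_perm < 100) warnf("n_perm = %d gives a coarse p-value", n_perm)
  D <- ks_stat_groups(aft$raw_residuals, aft$event, aft$group)
  d <- aft$data
  cov <- aft$covariate
  set_seed_if(seed)
  perm_D <- vapply(seq_len(n_perm), function(i) {
    dp <- d
    dp[[cov]] <- sample(d[[cov]])
    fp <- fit_buckley_james(dp, covariate = cov)
    ks_stat_groups(fp$raw_residuals, fp$event, fp$group)
  }, numeric(1))
  p <- (1 + sum(perm_D >= D)) / (n_perm + 1)
  structure(list(D = D, p = p, n_perm = n_perm, seed = seed,
                 perm_D = perm_D),
            class = "rescaling_test")
}

#' @export
print.rescaling_test <- function(x, ...) {
  cat(sprintf("<rescaling_test> D = %.4f, permutation p = %.4g (%d permutations)\n",
              x$D, x$p, x$n_perm))
  invisible(x)
}

# Max over arm pairs of sup |F_a - F_b| between censoring-aware KM CDFs.
# The sup for each pair is restricted to the common support where both
# CDFs are estimable (up to the smaller of the two largest event
# residuals); beyond it one KM curve is flat by construction and the
# distance would be inflated artificially under unequal censoring.
ks_stat_groups <- function(e, delta, group) {
  levs <- levels(group)
  cdfs <- lapply(levs, function(l) {
    sel <- group == l
    km_cdf(e[sel], delta[sel])
  })
  grid <- sort(unique(e))
  Fm <- vapply(cdfs, function(cd) cdf_eval(cd, grid), numeric(length(grid)))
  upper <- vapply(cdfs, function(cd) max(cd$x), numeric(1))
  best <- 0
  for (i in seq_along(levs)[-1]) for (j in seq_len(i - 1)) {
    ok <- grid <= min(upper[i], upper[j])
    if (any(ok))
      best <- max(best, max(abs(Fm[ok, i] - Fm[ok, j])))
  }
  best
}

# KM estimate of the CDF of (possibly right-censored) residuals
km_cdf <- function(e, delta) {
  if (all(delta == 1)) {
    es <- sort(e)
    return(list(x = es, F = seq_along(es) / length(es)))
  }
  o <- order(e)
  e <- e[o]; delta <- delta[o]
  n <- length(e)
  at_risk <- n:1
  surv <- cumprod(1 - delta / at_risk)
  keep <- delta == 1
  list(x = e[keep], F = 1 - surv[keep])
}

cdf_eval <- function(cd, grid) {
  i <- findInterval(grid, cd$x)
  c(0, cd$F)[i + 1]
}

#' Combine replicate-level p-values by Fisher's method
#'
#' @param p vector of p-values in (0, 1].
#' @return A list with the chi-square \code{statistic}, \code{df} and the
#'   pooled \code{p}.
#' @export
fisher_combine <- function(p) {
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  df <- 2 * length(p)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
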