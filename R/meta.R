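#' Inverse-variance-weighted meta-analysis across replicates
#'
#' Fixed effect: pooled estimate \eqn{\sum w_i\theta_i / \sum w_i} with
#' \eqn{w_i = 1/v_i} and variance \eqn{1/\sum w_i}.  Random effect:
#' DerSimonian-Laird, \eqn{\tau^2 = \max\!\big(0,\, (Q - (m-1)) /
#' (\sum w - \sum w^2/\sum w)\big)} with weights \eqn{1/(v_i + \tau^2)};
#' the heterogeneity statistic \eqn{Q = \sum w_i(\theta_i - \hat\theta_F)^2}
#' is reported either way.
#'
#' @param estimates per-replicate parameter estimates.
#' @param variances per-replicate variances (> 0).
#' @param method "fixed" or "random".
#' @param parameter optional parameter name carried into the result.
#' @return A list of class \code{"meta_estimate"}: \code{estimate},
#'   \code{se}, \code{tau2}, \code{Q}, \code{Q_df}, \code{Q_p},
#'   \code{method}, \code{weights}, plus the inputs.
#' @export
meta_combine <- function(estimates, variances, method = c("fixed", "random"),
                         parameter = NULL) {
  method <- match.arg(method)
  if (length(estimates) != length(variances))
    stopf("'estimates' and 'variances' lengths differ")
  if (length(estimates) < 2) stopf("need at least two replicates")
  if (any(variances <= 0)) stopf("all variances must be positive")
  w <- 1 / variances
  fixed <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - fixed)^2)
  m <- length(estimates)
  tau2 <- max(0, (Q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (method == "fixed") {
    est <- fixed; v <- 1 / sum(w); wt <- w
  } else {
    wt <- 1 / (variances + tau2)
    est <- sum(wt * estimates) / sum(wt)
    v <- 1 / sum(wt)
  }
  structure(list(parameter = parameter, estimate = est, se = sqrt(v),
                 tau2 = tau2, Q = Q, Q_df = m - 1,
                 Q_p = pchisq(Q, m - 1, lower.tail = FALSE),
                 method = method, weights = wt,
                 inputs = data.frame(estimate = estimates,
                                     variance = variances)),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate>%s %s-effect pooled %.4f (se %.4f); Q = %.2f on %d df (p = %.3g), tau2 = %.4f\n",
              if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
              x$method, x$estimate, x$se, x$Q, x$Q_df, x$Q_p, x$tau2))
  invisible(x)
}
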