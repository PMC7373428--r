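#' Buckley-James accelerated failure time fit
#'
#' Least-squares AFT estimation on log survival times with a nonparametric
#' (Kaplan-Meier) residual distribution: censored log-times are replaced by
#' their conditional expectation given survival past the observed residual,
#' \deqn{\hat y_i = x_i\beta + \frac{\sum_{e_j > e_i} \hat f(e_j)\, e_j}
#'       {\hat S(e_i)},}
#' where \eqn{\hat f, \hat S} come from the KM estimate of the residual
#' distribution (largest residual treated as an event so the estimate is
#' proper), and least squares is re-run on the completed data until the
#' coefficient change falls below \code{tol}.  The estimator can oscillate
#' between two points; this is detected and the average of the oscillating
#' pair returned with a flag.  With no censoring the procedure reduces
#' exactly to ordinary least squares.
#'
#' @param cohort a \code{lifespan_cohort}, or a data frame with \code{day},
#'   \code{event} and the covariate column.
#' @param covariate name of the categorical covariate (default "arm").
#' @param tol convergence tolerance on max |coefficient change|.
#' @param max_iter iteration cap.
#' @return A list of class \code{"bj_fit"}: \code{coefficients} (intercept
#'   = reference-arm mean log-time; arm effects on the log-time scale),
#'   \code{scale} (SD of the KM residual distribution), \code{residuals}
#'   (standardized), \code{event}, \code{group}, \code{converged},
#'   \code{oscillated}, \code{iterations}, \code{data}.
#' @export
fit_buckley_james <- function(cohort, covariate = "arm", tol = 1e-6,
                              max_iter = 100) {
  d <- as.data.frame(cohort)
  if (!all(c("day", "event", covariate) %in% names(d)))
    stopf("cohort needs columns day, event, %s", covariate)
  g <- droplevels(factor(d[[covariate]]))
  y <- log(d$day)
  delta <- d$event
  for (lev in levels(g))
    if (sum(delta[g == lev]) < 2)
      stopf("arm '%s' has fewer than 2 events", lev)
  X <- stats::model.matrix(~ g)
  if (qr(X)$rank < ncol(X)) stopf("singular design matrix")
  ols <- function(yy) qr.coef(qr(X), yy)
  beta <- ols(y)
  if (all(delta == 1)) {
    res <- y - drop(X %*% beta)
    sc <- stats::sd(res)
    return(new_bj_fit(beta, res, sc, delta, g, TRUE, FALSE, 0L, d, covariate))
  }
  history <- matrix(beta, nrow = 1)
  oscillated <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- y - drop(X %*% beta)
    imp <- bj_impute(e, delta)
    ystar <- ifelse(delta == 1, y, drop(X %*% beta) + imp)
    beta_new <- ols(ystar)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    # limit cycles (any period): if this iterate revisits an earlier one,
    # return the average over the cycle, flagged
    dist <- apply(history, 1, function(h) max(abs(beta_new - h)))
    hit <- which(dist < tol)
    if (length(hit) && hit[1] < nrow(history)) {
      cyc <- history[hit[1]:nrow(history), , drop = FALSE]
      beta <- colMeans(cyc)
      oscillated <- TRUE; converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    history <- rbind(history, beta_new)
    beta <- beta_new
  }
  e <- y - drop(X %*% beta)
  sc <- km_resid_sd(e, delta)
  new_bj_fit(beta, e, sc, delta, g, converged, oscillated, iter, d, covariate)
}

new_bj_fit <- function(beta, resid, scale, event, group, converged,
                       oscillated, iterations, data, covariate) {
  names(beta) <- sub("^g", "", names(beta))
  structure(list(coefficients = beta, scale = scale,
                 residuals = resid / scale, raw_residuals = resid,
                 event = event, group = group, converged = converged,
                 oscillated = oscillated, iterations = iterations,
                 data = data, covariate = covariate),
            class = "bj_fit")
}

# KM of the residual distribution: jump masses at uncensored residuals,
# largest residual forced to an event (Efron tail convention).
km_resid_dist <- function(e, delta) {
  o <- order(e)
  e <- e[o]; delta <- delta[o]
  delta[length(delta)] <- 1L
  n <- length(e)
  at_risk <- n:1
  s_prev <- cumprod(1 - delta / at_risk)
  mass <- delta / at_risk * c(1, s_prev[-n])
  list(e = e, mass = mass, surv = s_prev)
}

# E[e | e > e_i] under the KM residual distribution, for each observation.
# Ties handled by value: the tail is over residuals strictly greater than e_i.
bj_impute <- function(e, delta) {
  km <- km_resid_dist(e, delta)
  cs <- cumsum(km$mass * km$e)
  total <- cs[length(cs)]
  grp_end <- findInterval(km$e, km$e)   # last index of each tie group
  tail_num <- total - cs[grp_end]
  surv <- km$surv[grp_end]              # P(e > e_i)
  imp_at <- ifelse(surv > 0, tail_num / surv, km$e)
  o <- order(e)
  out <- numeric(length(e))
  out[o] <- imp_at
  out
}

km_resid_sd <- function(e, delta) {
  km <- km_resid_dist(e, delta)
  m <- sum(km$mass * km$e)
  sqrt(sum(km$mass * (km$e - m)^2))
}

#' @export
print.bj_fit <- function(x, ...) {
  cat("<bj_fit> Buckley-James AFT (log-time scale)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("scale %.4f; %s after %d iteration(s)%s\n", x$scale,
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (x$oscillated) " (oscillation averaged)" else ""))
  invisible(x)
}

#' @export
coef.bj_fit <- function(object, ...) object$coefficients

#' @export
residuals.bj_fit <- function(object, standardized = TRUE, ...) {
  if (standardized) object$residuals else object$raw_residuals
}

#' @export
summary.bj_fit <- function(object, ...) {
  cat("Buckley-James accelerated failure time fit\n")
  print(object)
  cat(sprintf("n = %d (%d events, %d censored)\n", length(object$event),
              sum(object$event), sum(1 - object$event)))
  invisible(object)
}
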