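#' Kaplan-Meier survival curve with Greenwood variance
#'
#' Product-limit estimate via \code{survival::survfit}.  The median is
#' reported under the smallest-t convention: the smallest observed time at
#' which \eqn{S(t) \le 0.5} (this differs from \code{print.survfit}, which
#' averages adjacent times when \eqn{S} hits 0.5 exactly).
#'
#' @param time event/censoring times (> 0) or a \code{lifespan_cohort}.
#' @param event 1 = death, 0 = censored (ignored when a cohort is given).
#' @return A list of class \code{"km_curve"}: \code{times},
#'   \code{survival}, \code{greenwood_se}, \code{median} (NA, with
#'   \code{median_defined = FALSE}, when the curve never reaches 0.5),
#'   \code{n_events}, \code{n}.
#' @export
km_curve <- function(time, event = NULL) {
  if (inherits(time, "lifespan_cohort")) {
    event <- time$event; time <- time$day
  }
  if (any(time <= 0)) stopf("survival times must be positive")
  if (sum(event) < 1) stopf("need at least one death event")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med_idx <- which(fit$surv <= 0.5)
  med <- if (length(med_idx)) fit$time[med_idx[1]] else NA_real_
  structure(list(times = fit$time, survival = fit$surv,
                 greenwood_se = fit$std.err * fit$surv,
                 median = med, median_defined = length(med_idx) > 0,
                 n_events = sum(event), n = length(time), survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s\n", x$n,
              x$n_events,
              if (x$median_defined) format(x$median) else "undefined"))
  invisible(x)
}

#' Log-rank test between cohort arms
#'
#' @param cohort a \code{lifespan_cohort} (or data frame with \code{day},
#'   \code{event}, \code{arm}).
#' @param arms optional subset of arm labels to compare.
#' @return A list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank <- function(cohort, arms = NULL) {
  d <- as.data.frame(cohort)
  if (!is.null(arms)) d <- d[d$arm %in% arms, ]
  d$arm <- droplevels(factor(d$arm))
  if (nlevels(d$arm) < 2) stopf("log-rank needs at least two arms")
  sd <- survival::survdiff(survival::Surv(day, event) ~ arm, data = d)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df, p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Smoothed hazard (mortality) rate curve
#'
#' Life-table hazard - events per unit person-time at risk in unit-width
#' age intervals - smoothed with a Gaussian kernel weighted by exposure,
#' with a pointwise bootstrap CI over animals.
#'
#' @param time,event as in [km_curve()], or a \code{lifespan_cohort} as
#'   first argument.
#' @param bandwidth Gaussian kernel SD, days (> 0).
#' @param grid evaluation ages (default interval midpoints).
#' @param n_boot bootstrap resamples for the CI (0 = skip).
#' @param seed RNG seed.
#' @return A list of class \code{"hazard_curve"}: \code{age},
#'   \code{hazard}, \code{ci_lo}, \code{ci_hi}, \code{bandwidth}.
#' @export
hazard_curve <- function(time, event = NULL, bandwidth = 1, grid = NULL,
                         n_boot = 200, seed = 1) {
  if (inherits(time, "lifespan_cohort")) {
    event <- time$event; time <- time$day
  }
  if (bandwidth <= 0) stopf("'bandwidth' must be positive")
  if (sum(event) < 20) stopf("need at least 20 events for a hazard curve")
  breaks <- seq(0, ceiling(max(time)) + 1, by = 1)
  mids <- breaks[-1] - 0.5
  if (is.null(grid)) grid <- mids
  raw_haz <- function(tt, ev) {
    cuts <- cut(tt, breaks, right = TRUE)
    deaths <- tapply(ev, cuts, sum, default = 0)
    # person-time inside each interval
    expo <- vapply(seq_along(mids), function(i) {
      lo <- breaks[i]; hi <- breaks[i + 1]
      sum(pmax(0, pmin(tt, hi) - lo))
    }, numeric(1))
    list(deaths = as.numeric(deaths), expo = expo)
  }
  smooth_haz <- function(tt, ev) {
    r <- raw_haz(tt, ev)
    vapply(grid, function(g) {
      w <- dnorm(mids, g, bandwidth) * r$expo
      if (sum(w) == 0) return(NA_real_)
      h <- ifelse(r$expo > 0, r$deaths / r$expo, 0)
      sum(w * h) / sum(w)
    }, numeric(1))
  }
  h <- smooth_haz(time, event)
  lo <- hi <- rep(NA_real_, length(grid))
  if (n_boot > 0) {
    set_seed_if(seed)
    n <- length(time)
    bs <- replicate(n_boot, {
      i <- sample.int(n, replace = TRUE)
      smooth_haz(time[i], event[i])
    })
    qs <- apply(bs, 1, quantile, c(0.025, 0.975), na.rm = TRUE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  structure(list(age = grid, hazard = h, ci_lo = lo, ci_hi = hi,
                 bandwidth = bandwidth),
            class = "hazard_curve")
}

#' @export
plot.hazard_curve <- function(x, ...) {
  plot(x$age, x$hazard, type = "l", xlab = "age (days)",
       ylab = "hazard (1/day)", ...)
  if (!all(is.na(x$ci_lo))) {
    lines(x$age, x$ci_lo, lty = 3)
    lines(x$age, x$ci_hi, lty = 3)
  }
  invisible(x)
}
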