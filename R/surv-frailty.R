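#' Weibull--Gamma-frailty survival distribution
#'
#' Marginal (population) survival and density after integrating a
#' Gamma(mean 1, variance sigma2) multiplicative frailty out of a Weibull
#' hazard with shape \code{k} and scale \code{b}:
#' \deqn{S(t) = \left(1 + \sigma^2 (t/b)^k\right)^{-1/\sigma^2}, \qquad
#'   f(t) = \frac{k}{b}\left(\frac{t}{b}\right)^{k-1}
#'   \left(1 + \sigma^2 (t/b)^k\right)^{-1/\sigma^2 - 1}.}
#' As \eqn{\sigma^2 \to 0} both reduce continuously to the Weibull law;
#' \code{sigma2} below \code{1e-8} is floored there and the \code{log1p}
#' form keeps the limit numerically continuous.
#'
#' @param t time (> 0).
#' @param k,b Weibull shape and scale (> 0).
#' @param sigma2 frailty variance (>= 0).
#' @param log return log values.
#' @return Survival probabilities / densities.
#' @export
sweibgamma <- function(t, k, b, sigma2, log = FALSE) {
  s2 <- pmax(sigma2, 1e-8)
  u <- (t / b)^k
  ls <- -log1p(s2 * u) / s2
  if (log) ls else exp(ls)
}

#' @rdname sweibgamma
#' @export
dweibgamma <- function(t, k, b, sigma2, log = FALSE) {
  s2 <- pmax(sigma2, 1e-8)
  u <- (t / b)^k
  ld <- base::log(k / b) + (k - 1) * base::log(t / b) -
    (1 / s2 + 1) * log1p(s2 * u)
  if (log) ld else exp(ld)
}

#' @rdname sweibgamma
#' @export
pweibgamma <- function(t, k, b, sigma2) 1 - sweibgamma(t, k, b, sigma2)

#' Population hazard of the Weibull--Gamma-frailty law
#'
#' \eqn{h(t) = (k/b)(t/b)^{k-1} / (1 + \sigma^2 (t/b)^k)}: frailty makes
#' the population hazard decelerate (and, for large enough \eqn{\sigma^2},
#' attain an interior maximum then decline) even though every individual
#' hazard is increasing.
#'
#' @inheritParams sweibgamma
#' @export
hweibgamma <- function(t, k, b, sigma2) {
  s2 <- pmax(sigma2, 1e-8)
  u <- (t / b)^k
  (k / b) * (t / b)^(k - 1) / (1 + s2 * u)
}

departure_labels <- c(scale = "scaling-only", shape = "+shape",
                      frailty = "+frailty")

model_label_for <- function(departures) {
  extra <- setdiff(departures, "scale")
  if (!length(extra)) "scaling-only"
  else if (setequal(extra, c("shape", "frailty"))) "full"
  else departure_labels[[extra]]
}

#' Fit a Weibull--Gamma-frailty survival model with per-arm departures
#'
#' Maximum likelihood on the marginal log-likelihood (events contribute
#' \code{log f}, right-censored observations \code{log S}).  The reference
#' arm has baseline parameters (log b, log k, log sigma2); every other arm
#' always gets a scale departure \eqn{\Delta\log b} (temporal rescaling),
#' and optionally shape (\eqn{\Delta\log k}) and/or frailty
#' (\eqn{\Delta\log\sigma^2}) departures.  All parameters are optimized on
#' the log scale (positivity without constraints, departures read directly
#' as log-ratios), with three starting points; the best log-likelihood
#' wins.
#'
#' @param cohort a \code{lifespan_cohort} (columns \code{day},
#'   \code{event}, \code{arm}).
#' @param departures subset of \code{c("scale", "shape", "frailty")};
#'   \code{"scale"} is always included.
#' @return A list of class \code{"weibgamma_fit"}: \code{params} (named:
#'   \code{log_b}, \code{log_k}, \code{log_s2}, and per-arm
#'   \code{dlog_b.<arm>} etc.), \code{loglik}, \code{covariance},
#'   \code{model_label}, \code{n_params}, \code{arms}, \code{converged},
#'   \code{data}.
#' @export
fit_weibull_gamma <- function(cohort, departures = "scale") {
  departures <- union("scale", match.arg(departures,
                                         c("scale", "shape", "frailty"),
                                         several.ok = TRUE))
  d <- as.data.frame(cohort)
  if (sum(d$event) < 10) stopf("need at least 10 events")
  g <- droplevels(factor(d$arm))
  arms <- levels(g)
  other <- arms[-1]
  t <- d$day; ev <- d$event
  par_names <- c("log_b", "log_k", "log_s2",
                 if (length(other)) paste0("dlog_b.", other),
                 if ("shape" %in% departures && length(other))
                   paste0("dlog_k.", other),
                 if ("frailty" %in% departures && length(other))
                   paste0("dlog_s2.", other))
  gi <- as.integer(g)
  unpack <- function(p) {
    names(p) <- par_names
    db <- dk <- ds <- rep(0, length(arms))
    if (length(other)) {
      db[-1] <- p[paste0("dlog_b.", other)]
      if ("shape" %in% departures) dk[-1] <- p[paste0("dlog_k.", other)]
      if ("frailty" %in% departures) ds[-1] <- p[paste0("dlog_s2.", other)]
    }
    list(b = exp(p[["log_b"]] + db), k = exp(p[["log_k"]] + dk),
         s2 = exp(p[["log_s2"]] + ds))
  }
  negll <- function(p) {
    th <- unpack(p)
    b <- th$b[gi]; k <- th$k[gi]; s2 <- th$s2[gi]
    ll <- ifelse(ev == 1, dweibgamma(t, k, b, s2, log = TRUE),
                 sweibgamma(t, k, b, s2, log = TRUE))
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }
  # moment-flavoured start: Weibull shape from spread of log event times
  te <- t[ev == 1]
  k0 <- min(max((pi / sqrt(6)) / max(stats::sd(log(te)), 0.05), 0.3), 25)
  start0 <- c(log(stats::median(te)), log(k0), log(0.3),
              rep(0, length(par_names) - 3))
  # third start sits near the Weibull limit so a frailty-free law is not
  # missed in the flat (log k, log sigma2) trade-off direction
  starts <- list(start0,
                 start0 + c(0.3, -0.5, 1, rep(0.1, length(par_names) - 3)),
                 `[<-`(start0, 3, log(1e-7)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, negll, method = "BFGS",
                                 control = list(maxit = 1000,
                                                reltol = 1e-12),
                                 hessian = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("all optimization starts failed")
  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  covar <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) matrix(NA, length(par_names),
                                                     length(par_names)))
  else matrix(NA, length(par_names), length(par_names))
  dimnames(covar) <- list(par_names, par_names)
  params <- best$par
  names(params) <- par_names
  structure(list(params = params, loglik = -best$value, covariance = covar,
                 model_label = model_label_for(departures),
                 departures = departures, n_params = length(par_names),
                 arms = arms, converged = best$convergence == 0,
                 n = nrow(d), n_events = sum(ev), data = d),
            class = "weibgamma_fit")
}

#' @export
print.weibgamma_fit <- function(x, ...) {
  cat(sprintf("<weibgamma_fit> %s model, %d arms, loglik %.2f (%d params, n = %d)\n",
              x$model_label, length(x$arms), x$loglik, x$n_params, x$n))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
coef.weibgamma_fit <- function(object, ...) object$params

#' @export
logLik.weibgamma_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
summary.weibgamma_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$covariance), 0))
  tab <- data.frame(estimate = object$params, se = se,
                    z = object$params / se,
                    row.names = names(object$params))
  cat(sprintf("Weibull-Gamma frailty fit (%s)\n", object$model_label))
  print(round(tab, 4))
  invisible(tab)
}

# arm-specific natural-scale parameters of a fit
arm_params <- function(fit) {
  p <- fit$params
  other <- fit$arms[-1]
  db <- dk <- ds <- setNames(rep(0, length(fit$arms)), fit$arms)
  for (a in other) {
    nb <- paste0("dlog_b.", a); nk <- paste0("dlog_k.", a)
    ns <- paste0("dlog_s2.", a)
    if (nb %in% names(p)) db[a] <- p[[nb]]
    if (nk %in% names(p)) dk[a] <- p[[nk]]
    if (ns %in% names(p)) ds[a] <- p[[ns]]
  }
  data.frame(arm = fit$arms,
             b = exp(p[["log_b"]] + db), k = exp(p[["log_k"]] + dk),
             sigma2 = exp(p[["log_s2"]] + ds), row.names = NULL)
}

#' Forward likelihood-ratio model selection over departure terms
#'
#' Starts from the scaling-only model and greedily adds the departure term
#' (shape, frailty) whose likelihood-ratio test against the current model
#' is significant at \code{alpha}, preferring the larger improvement;
#' stops when no addition is significant.  Equal log-likelihoods break
#' ties toward fewer parameters (the simpler model is kept).
#'
#' @param cohort data to fit, or NULL if \code{fits} supplies all models.
#' @param fits optional pre-computed named list of \code{weibgamma_fit}s
#'   (names from their \code{model_label}); missing models are fitted.
#' @param alpha test level.
#' @return A list of class \code{"lrt_selection"}: \code{best} (the chosen
#'   fit), \code{table} (every comparison: models, df, 2*delta-loglik, p).
#' @export
lrt_select <- function(cohort = NULL, fits = NULL, alpha = 0.05) {
  get_fit <- function(departures) {
    lab <- model_label_for(departures)
    if (!is.null(fits) && lab %in% names(fits)) return(fits[[lab]])
    if (is.null(cohort)) stopf("model '%s' not supplied and no data to fit it", lab)
    fit_weibull_gamma(cohort, departures)
  }
  if (!is.null(fits)) {
    ns <- vapply(fits, `[[`, 1L, "n")
    if (length(unique(ns)) > 1) stopf("fits were not made on identical data")
  }
  current <- get_fit("scale")
  remaining <- c("shape", "frailty")
  chosen <- "scale"
  rows <- list()
  repeat {
    cand <- lapply(remaining, function(term) get_fit(c(chosen, term)))
    stat <- vapply(cand, function(f) 2 * (f$loglik - current$loglik), 1)
    dfs <- vapply(cand, function(f) f$n_params - current$n_params, 1L)
    if (any(dfs <= 0)) stopf("candidate models are not strict supersets")
    pv <- pchisq(pmax(stat, 0), dfs, lower.tail = FALSE)
    for (i in seq_along(remaining))
      rows[[length(rows) + 1]] <- data.frame(
        from = current$model_label, to = cand[[i]]$model_label,
        df = dfs[i], lrt = stat[i], p = pv[i])
    sig <- which(pv < alpha & stat > 0)
    if (!length(sig)) break
    i <- sig[which.max(stat[sig])]
    current <- cand[[i]]
    chosen <- c(chosen, remaining[i])
    remaining <- remaining[-i]
    if (!length(remaining)) break
  }
  structure(list(best = current, table = do.call(rbind, rows),
                 alpha = alpha),
            class = "lrt_selection")
}

#' @export
print.lrt_selection <- function(x, ...) {
  cat(sprintf("<lrt_selection> best model: %s\n", x$best$model_label))
  print(transform(x$table, lrt = round(lrt, 3), p = signif(p, 3)))
  invisible(x)
}

#' Chi-square goodness of fit of a frailty model
#'
#' Equal-probability time bins under the fitted (arm-specific) model:
#' event times are mapped through the fitted CDF, giving uniform values
#' under a correct model, then binned.  \eqn{\chi^2 = \sum (O-E)^2/E}
#' with \code{df = bins - 1}; no parameters are subtracted from the df
#' because the evaluated parameters are treated as externally supplied
#' (e.g. meta-analysis estimates applied to each replicate).  Bins are
#' merged until every expected count is at least 5.
#'
#' @param fit a \code{weibgamma_fit} (its parameters are evaluated).
#' @param data cohort to evaluate on (default: the fit's own data).
#' @param n_bins initial number of equal-probability bins.
#' @return A list with \code{chisq}, \code{df}, \code{p}, \code{n_bins}
#'   (after merging), \code{observed}, \code{expected}.
#' @export
gof_chisq <- function(fit, data = fit$data, n_bins = 8) {
  d <- as.data.frame(data)
  d <- d[d$event == 1, ]
  ap <- arm_params(fit)
  i <- match(as.character(d$arm), ap$arm)
  if (anyNA(i)) stopf("data contain arms absent from the fit")
  u <- pweibgamma(d$day, ap$k[i], ap$b[i], ap$sigma2[i])
  n <- length(u)
  while (n_bins >= 3 && n / n_bins < 5) n_bins <- n_bins - 1
  if (n_bins < 3) stopf("fewer than 3 bins possible with expected counts >= 5")
  br <- seq(0, 1, length.out = n_bins + 1)
  obs <- tabulate(findInterval(u, br, rightmost.closed = TRUE), n_bins)
  exp_ <- rep(n / n_bins, n_bins)
  chisq <- sum((obs - exp_)^2 / exp_)
  df <- n_bins - 1
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       n_bins = n_bins, observed = obs, expected = exp_)
}
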