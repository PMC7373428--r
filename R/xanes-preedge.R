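#' Fit the pre-edge 1s->3d feature of a normalized XANES spectrum
#'
#' Two-stage fit inside the pre-edge window (default 7108-7118 eV): the
#' rising edge is modelled as the tail of an arctangent (center, width and
#' amplitude free) fitted to the window flanks only, then a single Gaussian
#' is fitted to the baseline-subtracted residual.  The pre-edge centroid is
#' the Gaussian center, with a 95 percent CI from the fit covariance.  One
#' Gaussian is used for the whole 1s->3d envelope; multi-component pre-edge
#' deconvolution is out of scope.
#'
#' @param spectrum a \code{xanes_spectrum}.
#' @param window pre-edge window, eV.
#' @param peak_zone flank exclusion zone containing the pre-edge peak, eV;
#'   points inside it are withheld from the baseline fit.
#' @return A list of class \code{"preedge_fit"}: \code{baseline_params}
#'   (arctan center, width, amplitude), \code{gaussian} (center, amplitude,
#'   width), \code{centroid} (eV), \code{centroid_se}, \code{fit_ci}
#'   (95 percent interval), \code{residual_rms}, plus the window data and
#'   fitted curves for diagnostics.
#' @export
fit_pre_edge <- function(spectrum, window = c(7108, 7118),
                         peak_zone = c(7110.5, 7116)) {
  E <- spectrum$energies; mu <- spectrum$mu
  ok <- is.finite(mu) & E >= window[1] & E <= window[2]
  Ew <- E[ok]; muw <- mu[ok]
  if (length(Ew) < 8) stopf("too few points inside the pre-edge window")
  flank <- Ew < peak_zone[1] | Ew > peak_zone[2]
  if (sum(flank) < 4) stopf("too few flank points for the baseline fit")
  fd <- data.frame(E = Ew[flank], y = muw[flank])
  base_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ h * (0.5 + atan((E - c0) / w) / pi), data = fd,
                      start = list(h = max(fd$y) * 2 + 0.1,
                                   c0 = window[2] + 3, w = 2),
                      lower = c(1e-6, window[1], 0.1),
                      upper = c(Inf, window[2] + 60, 30),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("rising-edge baseline fit failed: %s",
                              conditionMessage(e)))
  bp <- coef(base_fit)
  baseline <- bp[["h"]] * (0.5 + atan((Ew - bp[["c0"]]) / bp[["w"]]) / pi)
  resid <- muw - baseline
  gd <- data.frame(E = Ew, r = resid)
  i0 <- which.max(resid)
  gfit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-(E - Ec)^2 / (2 * s^2)), data = gd,
                      start = list(A = max(resid), Ec = Ew[i0], s = 0.7),
                      lower = c(1e-8, window[1], 0.05),
                      upper = c(Inf, window[2], 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("pre-edge Gaussian fit failed: %s",
                              conditionMessage(e)))
  gp <- coef(gfit)
  se <- tryCatch(sqrt(diag(vcov(gfit)))[["Ec"]], error = function(e) NA_real_)
  centroid <- gp[["Ec"]]
  ci <- centroid + c(-1, 1) * 1.96 * se
  rr <- sqrt(mean(residuals(gfit)^2))
  structure(list(baseline_params = c(center = bp[["c0"]], width = bp[["w"]],
                                     amplitude = bp[["h"]]),
                 gaussian = c(center = gp[["Ec"]], amplitude = gp[["A"]],
                              width = gp[["s"]]),
                 centroid = centroid, centroid_se = se, fit_ci = ci,
                 residual_rms = rr,
                 window = window,
                 data = data.frame(E = Ew, mu = muw, baseline = baseline,
                                   resid = resid,
                                   gaussian = predict(gfit))),
            class = "preedge_fit")
}

#' @export
print.preedge_fit <- function(x, ...) {
  cat(sprintf("<preedge_fit> centroid %.3f eV (95%% CI %.3f-%.3f), width %.2f eV, residual rms %.2e\n",
              x$centroid, x$fit_ci[1], x$fit_ci[2], x$gaussian[["width"]],
              x$residual_rms))
  invisible(x)
}

#' @export
plot.preedge_fit <- function(x, ...) {
  d <- x$data
  plot(d$E, d$mu, xlab = "Energy (eV)", ylab = "normalized mu",
       main = "Pre-edge fit", ...)
  lines(d$E, d$baseline, lty = 2)
  lines(d$E, d$baseline + d$gaussian, col = 2)
  abline(v = x$centroid, col = 2, lty = 3)
  invisible(x)
}
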