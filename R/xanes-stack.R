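#' Calibrate the energy axis against an iron-foil spectrum
#'
#' The maximum of the first peak in the derivative spectrum of a metallic
#' iron foil defines 7112.0 eV.  The derivative is computed on a cubic
#' spline interpolant of the foil spectrum sampled at 0.02 eV to beat the
#' sparse native grid, and the first local maximum of d(mu)/dE inside the
#' search window is mapped to the reference.
#'
#' @param foil_spectrum a \code{xanes_spectrum} (see
#'   [extract_normalized_spectrum()]), or any list with \code{energies} and
#'   \code{mu}.
#' @param reference energy assigned to the derivative maximum, eV.
#' @param window search window for the derivative peak, eV.
#' @return Energy offset in eV to *add* to the raw axis
#'   (reference - found peak).
#' @export
calibrate_energy_axis <- function(foil_spectrum, reference = 7112.0,
                                  window = c(7100, 7135)) {
  E <- foil_spectrum$energies; mu <- foil_spectrum$mu
  ok <- is.finite(mu)
  E <- E[ok]; mu <- mu[ok]
  if (min(E) > window[1] || max(E) < window[2])
    stopf("foil spectrum does not span the %g-%g eV search window",
          window[1], window[2])
  sp <- stats::splinefun(E, mu, method = "natural")
  fine <- seq(window[1], window[2], by = 0.02)
  d <- sp(fine, deriv = 1)
  # first interior local maximum of the derivative; a genuine edge peak
  # must stand clear of the typical derivative level (a featureless ramp
  # has numerically flat d and yields no peak)
  peaks <- which(diff(sign(diff(d))) == -2) + 1L
  peaks <- peaks[d[peaks] > 0 & d[peaks] > 2 * stats::median(abs(d))]
  if (!length(peaks))
    stopf("no derivative maximum found in the %g-%g eV window",
          window[1], window[2])
  reference - fine[peaks[1]]
}

ncc <- function(a, b) {
  av <- a - mean(a); bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

#' Align an energy stack by cross-correlation of the calcium channel
#'
#' Position drifts between energy frames are recovered from the calcium
#' map, which is essentially constant through the energy series.  Each
#' frame's calcium image is compared to the first frame's over all integer
#' shifts up to \code{max_shift}; the shift maximizing the normalized
#' cross-correlation on the overlap is applied (integer-pixel only;
#' subpixel interpolation would smear sparse counts) to both the Fe and Ca
#' frames.  Frames whose best shift sits on the search boundary are flagged
#' and excluded from ROI spectra.
#'
#' @param stack a \code{spectrum_stack}.
#' @param max_shift maximum |shift| searched, pixels.
#' @return The aligned stack; \code{$alignment_state} records the applied
#'   per-frame (dy, dx), \code{$excluded} flags boundary-limited frames.
#' @export
align_stack <- function(stack, max_shift = 5) {
  if (is.null(stack$ca_frames)) stopf("stack has no per-frame calcium channel")
  nE <- dim(stack$frames)[1]
  ref <- stack$ca_frames[1, , ]
  shifts <- matrix(0L, nE, 2, dimnames = list(NULL, c("dy", "dx")))
  excluded <- logical(nE)
  rng <- -max_shift:max_shift
  ny <- nrow(ref); nx <- ncol(ref)
  for (i in seq_len(nE)) {
    fr <- stack$ca_frames[i, , ]
    best <- c(0L, 0L); best_c <- -Inf
    for (dy in rng) for (dx in rng) {
      ya <- max(1, 1 + dy):min(ny, ny + dy)
      xa <- max(1, 1 + dx):min(nx, nx + dx)
      cc <- ncc(fr[ya, xa], ref[ya - dy, xa - dx])
      if (cc > best_c) { best_c <- cc; best <- c(dy, dx) }
    }
    shifts[i, ] <- best
    if (any(abs(best) >= max_shift) && any(best != 0L)) excluded[i] <- TRUE
    if (any(best != 0L)) {
      stack$frames[i, , ] <- shift_matrix(stack$frames[i, , ], -best[1], -best[2])
      stack$ca_frames[i, , ] <- shift_matrix(stack$ca_frames[i, , ],
                                             -best[1], -best[2])
    }
  }
  stack$alignment_state <- stack$alignment_state + shifts
  stack$excluded <- stack$excluded | excluded
  stack
}

#' Extract an edge-jump-normalized XANES spectrum over a region of interest
#'
#' Sums counts over the ROI pixels at each energy, then normalizes: a line
#' fitted to the pre-edge region (below \code{pre_max} eV) is subtracted,
#' and a low-order (linear) polynomial fitted to the post-edge region (at
#' or above \code{post_min} eV) scales the edge jump to one pointwise.
#' Energies of frames flagged excluded by alignment are marked missing and
#' skipped by downstream fits.  The native energy grid is kept.
#'
#' @param stack an aligned \code{spectrum_stack}.
#' @param roi logical matrix or integer pixel indices selecting the ROI.
#' @param roi_id label carried into the result.
#' @param pre_max upper bound of the pre-edge baseline region, eV.
#' @param post_min lower bound of the post-edge region, eV.
#' @return A list of class \code{"xanes_spectrum"}: \code{energies},
#'   \code{mu} (normalized), \code{raw} (summed counts), \code{roi_id},
#'   \code{n_pixels}.
#' @export
extract_normalized_spectrum <- function(stack, roi, roi_id = 1L,
                                        pre_max = 7105, post_min = 7135) {
  dims <- dim(stack$frames)[2:3]
  if (is.matrix(roi) && is.logical(roi)) {
    idx <- which(roi)
  } else idx <- as.integer(roi)
  if (!length(idx)) stopf("ROI is empty")
  nE <- dim(stack$frames)[1]
  raw <- vapply(seq_len(nE), function(i) {
    fr <- stack$frames[i, , ]
    sum(fr[idx])
  }, numeric(1))
  raw[stack$excluded] <- NA_real_
  E <- stack$grid$energies
  sp <- normalize_spectrum(E, raw, pre_max, post_min)
  structure(list(energies = E, mu = sp, raw = raw, roi_id = roi_id,
                 n_pixels = length(idx)),
            class = "xanes_spectrum")
}

# Edge-jump normalization shared by extraction and reference generation.
normalize_spectrum <- function(E, raw, pre_max = 7105, post_min = 7135) {
  ok <- is.finite(raw)
  pre <- ok & E < pre_max
  post <- ok & E >= post_min
  if (sum(pre) < 2 || sum(post) < 2)
    stopf("too few pre- or post-edge points for normalization")
  pl <- stats::lm.fit(cbind(1, E[pre]), raw[pre])$coefficients
  sub <- raw - (pl[1] + pl[2] * E)
  po <- stats::lm.fit(cbind(1, E[post]), sub[post])$coefficients
  scale <- po[1] + po[2] * E
  if (any(scale[ok] <= 0))
    stopf("post-edge fit is non-positive inside the scan; cannot normalize")
  sub / scale
}
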