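#' Model endmember Fe K-edge spectrum
#'
#' Endmember absorption is modelled as an arctangent edge step plus a single
#' pre-edge Gaussian (the 1s->3d feature):
#' \deqn{\mu(E) = A_e\left[\tfrac12 + \tfrac1\pi \arctan\!\frac{E-E_0}{w_e}\right]
#'   + A_p \exp\!\left(-\frac{(E-E_c)^2}{2 w_p^2}\right).}
#' Default pre-edge centers follow the pre-edge literature convention of
#' roughly 7112.1 eV for ferrous and 7113.5 eV for ferric iron; the edge
#' inflection shifts up with oxidation state.
#'
#' @param pre_center pre-edge Gaussian center \eqn{E_c}, eV.
#' @param pre_amp pre-edge amplitude \eqn{A_p} (fraction of edge jump).
#' @param pre_width pre-edge Gaussian SD \eqn{w_p}, eV.
#' @param edge_pos edge inflection \eqn{E_0}, eV.
#' @param edge_width edge half-width \eqn{w_e}, eV.
#' @param edge_amp edge jump amplitude \eqn{A_e}.
#' @return A list of class \code{"xanes_endmember"} with a \code{$mu(E)}
#'   evaluator and the parameters.
#' @export
xanes_endmember <- function(pre_center, pre_amp = 0.08, pre_width = 0.75,
                            edge_pos, edge_width = 1.5, edge_amp = 1) {
  check_positive(pre_width, "pre_width")
  check_positive(edge_width, "edge_width")
  force(pre_center); force(pre_amp); force(edge_pos); force(edge_amp)
  mu <- function(E) {
    edge_amp * (0.5 + atan((E - edge_pos) / edge_width) / pi) +
      pre_amp * exp(-(E - pre_center)^2 / (2 * pre_width^2))
  }
  structure(list(mu = mu, pre_center = pre_center, pre_amp = pre_amp,
                 pre_width = pre_width, edge_pos = edge_pos,
                 edge_width = edge_width, edge_amp = edge_amp),
            class = "xanes_endmember")
}

#' Default ferrous / ferric endmember pair
#'
#' @return A list with elements \code{fe2} and \code{fe3}
#'   ([xanes_endmember()] objects).
#' @export
default_endmembers <- function() {
  list(fe2 = xanes_endmember(pre_center = 7112.1, edge_pos = 7120),
       fe3 = xanes_endmember(pre_center = 7113.5, edge_pos = 7127))
}

#' Configuration for a simulated XANES image stack
#'
#' @param grid an [build_energy_grid()] energy grid.
#' @param endmembers list with \code{fe2} and \code{fe3}
#'   [xanes_endmember()] specs; pre-edge centers must be distinct.
#' @param fe2_fraction_map 2D matrix of true ferrous fractions in [0, 1].
#' @param iron_density_map 2D matrix of relative iron densities (>= 0).
#' @param ca_density_map 2D matrix of calcium densities (>= 0); this channel
#'   anchors frame alignment.
#' @param counts_scale expected fluorescence photons per unit density per
#'   unit absorption.
#' @param frame_jitter_px maximum per-frame integer translation (pixels)
#'   planted to exercise alignment; 0 = no jitter.
#' @param poisson if FALSE, frames carry noiseless expected counts.
#' @param seed integer RNG seed.
#' @return A list of class \code{"xanes_sim_config"}.
#' @export
xanes_sim_config <- function(grid = build_energy_grid(),
                             endmembers = default_endmembers(),
                             fe2_fraction_map, iron_density_map,
                             ca_density_map = NULL, counts_scale = 1e4,
                             frame_jitter_px = 0, poisson = TRUE, seed = 1) {
  fe2_fraction_map <- as.matrix(fe2_fraction_map)
  iron_density_map <- as.matrix(iron_density_map)
  if (is.null(ca_density_map)) ca_density_map <- (iron_density_map > 0) * 1
  ca_density_map <- as.matrix(ca_density_map)
  if (!all(dim(fe2_fraction_map) == dim(iron_density_map)) ||
      !all(dim(fe2_fraction_map) == dim(ca_density_map)))
    stopf("fraction, iron and calcium maps must share dimensions")
  if (any(fe2_fraction_map < 0 | fe2_fraction_map > 1))
    stopf("'fe2_fraction_map' values must lie in [0, 1]")
  check_nonneg(iron_density_map, "iron_density_map")
  check_nonneg(ca_density_map, "ca_density_map")
  if (abs(endmembers$fe2$pre_center - endmembers$fe3$pre_center) < 1e-6)
    stopf("endmember pre-edge centers must be distinct")
  check_nonneg(counts_scale, "counts_scale")
  if (frame_jitter_px < 0) stopf("'frame_jitter_px' must be >= 0")
  structure(list(grid = grid, endmembers = endmembers,
                 fe2_fraction_map = fe2_fraction_map,
                 iron_density_map = iron_density_map,
                 ca_density_map = ca_density_map,
                 counts_scale = counts_scale,
                 frame_jitter_px = as.integer(frame_jitter_px),
                 poisson = isTRUE(poisson), seed = seed),
            class = "xanes_sim_config")
}

# shift a matrix by integer (dy, dx), zero-filling exposed margins
shift_matrix <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  ysrc <- ys - dy; xsrc <- xs - dx
  ok_y <- ysrc >= 1 & ysrc <= nrow(m)
  ok_x <- xsrc >= 1 & xsrc <= ncol(m)
  out[ys[ok_y], xs[ok_x]] <- m[ysrc[ok_y], xsrc[ok_x]]
  out
}

#' Generate a fluorescence-detected XANES image stack
#'
#' Per-pixel expected spectrum is
#' \eqn{d_{\mathrm{Fe}}\,[f\,\mu_{2}(E) + (1-f)\,\mu_{3}(E)]\times
#' \mathrm{counts\_scale}}, with Poisson counts.  Each energy frame (and its
#' calcium frame, identically) is translated by a planted integer jitter of
#' at most \code{frame_jitter_px} pixels, recorded in the truth record so
#' alignment is fully recoverable from the calcium channel.
#'
#' @param config an [xanes_sim_config()].
#' @return A list of class \code{"spectrum_stack"}: \code{frames}
#'   (energy x y x x array of Fe counts), \code{ca_frames} (same layout),
#'   \code{grid}, \code{alignment_state} (per-frame applied shift, all zero
#'   until [align_stack()] runs), and truth attached as \code{"truth"}
#'   (planted jitters, maps, endmembers).
#' @export
gen_xanes_stack <- function(config) {
  if (!inherits(config, "xanes_sim_config"))
    stopf("'config' must be a xanes_sim_config")
  set_seed_if(config$seed)
  E <- config$grid$energies
  nE <- length(E)
  dims <- dim(config$iron_density_map)
  j <- config$frame_jitter_px
  if (j > 0) {
    occ <- which(config$iron_density_map > 0 | config$ca_density_map > 0,
                 arr.ind = TRUE)
    if (nrow(occ)) {
      margin <- min(occ[, 1] - 1, dims[1] - occ[, 1],
                    occ[, 2] - 1, dims[2] - occ[, 2])
      if (j > margin)
        stopf("frame_jitter_px (%d) exceeds the %d-pixel scene margin", j, margin)
    }
  }
  mu2 <- config$endmembers$fe2$mu(E)
  mu3 <- config$endmembers$fe3$mu(E)
  f <- config$fe2_fraction_map
  dfe <- config$iron_density_map
  jit <- if (j > 0)
    cbind(dy = sample(-j:j, nE, replace = TRUE),
          dx = sample(-j:j, nE, replace = TRUE))
  else cbind(dy = integer(nE), dx = integer(nE))
  frames <- array(0, c(nE, dims))
  ca_frames <- array(0, c(nE, dims))
  ca_expected <- config$ca_density_map * config$counts_scale
  for (i in seq_len(nE)) {
    lam <- dfe * (f * mu2[i] + (1 - f) * mu3[i]) * config$counts_scale
    fr <- if (config$poisson) matrix(rpois(length(lam), lam), dims[1]) else lam
    ca <- if (config$poisson)
      matrix(rpois(length(ca_expected), ca_expected), dims[1])
    else ca_expected
    frames[i, , ] <- shift_matrix(fr, jit[i, 1], jit[i, 2])
    ca_frames[i, , ] <- shift_matrix(ca, jit[i, 1], jit[i, 2])
  }
  out <- structure(list(frames = frames, ca_frames = ca_frames,
                        grid = config$grid,
                        alignment_state = cbind(dy = integer(nE),
                                                dx = integer(nE)),
                        excluded = logical(nE)),
                   class = "spectrum_stack")
  attr(out, "truth") <- list(config = config, jitter = jit)
  out
}
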