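#' Specify one worm footprint for XFM scene simulation
#'
#' @param centroid (y, x) center in pixels.
#' @param axes (semi-major, semi-minor) ellipse axis lengths in pixels.
#' @param orientation rotation of the major axis, radians.
#' @param fe_density iron areal density, pg per square micrometre.
#' @param ca_density calcium areal density, pg per square micrometre.
#' @return A list of class \code{"worm_spec"}.
#' @export
worm_spec <- function(centroid, axes, orientation = 0,
                      fe_density = 0.02, ca_density = 0.05) {
  check_positive(axes, "axes")
  check_nonneg(fe_density, "fe_density")
  check_nonneg(ca_density, "ca_density")
  structure(list(centroid = centroid, axes = axes, orientation = orientation,
                 fe_density = fe_density, ca_density = ca_density),
            class = "worm_spec")
}

#' Configuration for a simulated XFM elemental scene
#'
#' @param scene_shape (ny, nx) scene size in pixels.
#' @param worm_specs list of [worm_spec()] footprints (elliptical, mutually
#'   disjoint so per-worm truth stays unambiguous).
#' @param background_rate mean background counts per pixel (all channels).
#' @param compton_contrast foreground/background Compton scatter ratio (> 1).
#'   When \code{background_rate} is 0 the foreground Compton mean equals
#'   \code{compton_contrast} counts (contrast against a unit reference).
#' @param fe_gain detector counts per (pg um^-2) of iron per pixel; the true
#'   counts-to-areal-density calibration is its reciprocal.
#' @param ca_gain counts per (pg um^-2) of calcium per pixel.
#' @param pixel_area pixel footprint on the specimen, square micrometres.
#' @param seed integer RNG seed.
#' @return A list of class \code{"xfm_sim_config"}.
#' @export
xfm_sim_config <- function(scene_shape = c(300, 400), worm_specs,
                           background_rate = 2, compton_contrast = 8,
                           fe_gain = 1000, ca_gain = 1000, pixel_area = 0.64,
                           seed = 1) {
  if (inherits(worm_specs, "worm_spec")) worm_specs <- list(worm_specs)
  if (!all(vapply(worm_specs, inherits, TRUE, "worm_spec")))
    stopf("'worm_specs' must be a list of worm_spec() objects")
  if (compton_contrast <= 1) stopf("'compton_contrast' must be > 1")
  check_nonneg(background_rate, "background_rate")
  check_positive(pixel_area, "pixel_area")
  check_positive(fe_gain, "fe_gain")
  structure(list(scene_shape = as.integer(scene_shape),
                 worm_specs = worm_specs, background_rate = background_rate,
                 compton_contrast = compton_contrast, fe_gain = fe_gain,
                 ca_gain = ca_gain, pixel_area = pixel_area, seed = seed),
            class = "xfm_sim_config")
}

ellipse_mask <- function(shape, spec) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- yy - spec$centroid[1]; dx <- xx - spec$centroid[2]
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- dx * co + dy * si; v <- -dx * si + dy * co
  (u / spec$axes[1])^2 + (v / spec$axes[2])^2 <= 1
}

#' Generate an XFM elemental scene with planted worms
#'
#' Renders co-registered Fe, Ca and Compton-scatter count rasters with
#' Poisson noise.  Compton counts are brighter over specimen mass, which is
#' what downstream segmentation exploits.  The truth record lists, per worm,
#' the exact pixel set, planted areal densities and total masses
#' (density x pixel count x pixel area).
#'
#' @param config an [xfm_sim_config()].
#' @return A list of class \code{"elemental_scene"}: \code{channels} (named
#'   list of matrices \code{Fe}, \code{Ca}, \code{Compton}, raw counts),
#'   \code{pixel_area}, \code{units_state = "raw"}, and calibration gains;
#'   truth attached as \code{"truth"}.
#' @export
gen_xfm_scene <- function(config) {
  if (!inherits(config, "xfm_sim_config"))
    stopf("'config' must be a xfm_sim_config")
  set_seed_if(config$seed)
  shape <- config$scene_shape
  masks <- lapply(config$worm_specs, function(w) ellipse_mask(shape, w))
  if (length(masks) > 1) {
    tot <- Reduce(`+`, lapply(masks, `+`, 0))
    if (any(tot > 1))
      stopf("worm footprints overlap; per-worm truth would be ambiguous")
  }
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (any(m[1, ]) || any(m[shape[1], ]) || any(m[, 1]) || any(m[, shape[2]]))
      stopf("worm %d touches the scene border", i)
  }
  fe_rate <- matrix(config$background_rate, shape[1], shape[2])
  ca_rate <- fe_rate
  fg_compton <- if (config$background_rate > 0)
    config$background_rate * config$compton_contrast else config$compton_contrast
  compton_rate <- matrix(config$background_rate, shape[1], shape[2])
  worms <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]; w <- config$worm_specs[[i]]
    fe_rate[m] <- fe_rate[m] + w$fe_density * config$fe_gain
    ca_rate[m] <- ca_rate[m] + w$ca_density * config$ca_gain
    compton_rate[m] <- fg_compton
    npx <- sum(m)
    worms[[i]] <- list(pixels = which(m), n_pixels = npx,
                       fe_density = w$fe_density, ca_density = w$ca_density,
                       fe_total_pg = w$fe_density * npx * config$pixel_area,
                       ca_total_pg = w$ca_density * npx * config$pixel_area)
  }
  draw <- function(rate) matrix(rpois(length(rate), rate), shape[1])
  scene <- structure(list(
    channels = list(Fe = draw(fe_rate), Ca = draw(ca_rate),
                    Compton = draw(compton_rate)),
    pixel_area = config$pixel_area, units_state = "raw",
    fe_gain = config$fe_gain, ca_gain = config$ca_gain),
    class = "elemental_scene")
  attr(scene, "truth") <- list(
    config = config, worms = worms,
    foreground = Reduce(`|`, masks),
    # true calibration factor in ug cm^-2 per count (pg um^-2 per count / 0.01)
    fe_factor_ugcm2 = (1 / config$fe_gain) / UG_CM2_TO_PG_UM2)
  scene
}
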