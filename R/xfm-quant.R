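#' Calibrate fluorescence flux against foil standards
#'
#' Thin single-element metal foils of known areal density relate detector
#' flux to elemental abundance.  With one standard the factor is simply
#' known density / measured flux; with several, a zero-intercept least
#' squares slope of density on flux is used.
#'
#' @param standards data frame with columns \code{element},
#'   \code{known_areal_density} (ug cm^-2, > 0) and \code{measured_flux}
#'   (counts, > 0).
#' @return Named numeric vector of calibration factors, ug cm^-2 per count,
#'   one per element.
#' @examples
#' foil_calibration(data.frame(element = "Fe",
#'   known_areal_density = 50.1, measured_flux = 1000))
#' @export
foil_calibration <- function(standards) {
  req <- c("element", "known_areal_density", "measured_flux")
  if (!all(req %in% names(standards)))
    stopf("'standards' needs columns %s", paste(req, collapse = ", "))
  check_positive(standards$known_areal_density, "known_areal_density")
  if (any(standards$measured_flux <= 0))
    stopf("measured flux must be positive for every standard")
  out <- vapply(split(standards, standards$element), function(s) {
    # zero-intercept LS: slope = sum(d f) / sum(f^2); equals d/f for n = 1
    sum(s$known_areal_density * s$measured_flux) / sum(s$measured_flux^2)
  }, numeric(1))
  out
}

# Otsu's two-class variance-maximizing threshold on integer-valued counts.
otsu_threshold <- function(x) {
  v <- sort(unique(x))
  if (length(v) < 2) return(NA_real_)
  cnt <- tabulate(match(x, v))
  p <- cnt / sum(cnt)
  omega <- cumsum(p)
  mu <- cumsum(p * v)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after class v[i]
  denom <- omega * (1 - omega)
  sig_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  i <- which.max(sig_b[-length(sig_b)])
  (v[i] + v[i + 1]) / 2
}

# 8-connected component labelling of a logical mask via graph components
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- matrix(seq_len(ny * nx), ny, nx)
  edges <- list()
  offs <- list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))  # down, right, two diagonals
  for (o in offs) {
    ys <- seq_len(ny - abs(o[1])); xs <- seq_len(nx - abs(o[2]))
    ya <- if (o[1] >= 0) ys else ys - o[1]
    xa <- xs
    yb <- ya + o[1]; xb <- xa + o[2]
    a <- pos[ya, xa, drop = FALSE]; b <- pos[yb, xb, drop = FALSE]
    keep <- mask[a] & mask[b]
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(a[keep], b[keep])
  }
  ed <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  verts <- as.character(idx)
  g <- igraph::graph_from_edgelist(cbind(as.character(ed[, 1]),
                                         as.character(ed[, 2])),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(verts, igraph::V(g)$name))
  comp <- igraph::components(g)
  lab[as.integer(igraph::V(g)$name)] <- comp$membership
  lab
}

#' Segment worms from the Compton scatter channel
#'
#' Thresholds the Compton map with a deterministic two-class
#' variance-maximizing (Otsu) threshold, labels 8-connected components of
#' the foreground, and removes components smaller than \code{min_pixels}
#' (regions too small to reflect whole-animal elemental content).  The
#' background used downstream is the complement of all pre-filter
#' components.
#'
#' @param scene an \code{elemental_scene}.
#' @param min_pixels minimum component size kept as a region of interest.
#' @return A list of class \code{"roi_set"}: \code{label_map} (0 =
#'   background), \code{roi_ids}, \code{pixel_counts}, \code{status}
#'   ("ok" or "no-foreground"), and \code{pre_filter_foreground} (logical
#'   matrix) for background statistics.  A scene with no separable
#'   foreground yields an empty set with a warning status, not an error.
#' @export
segment_compton <- function(scene, min_pixels = 10000) {
  if (!"Compton" %in% names(scene$channels))
    stopf("scene has no Compton channel")
  ch <- scene$channels$Compton
  thr <- otsu_threshold(as.vector(ch))
  empty <- function() {
    warnf("no foreground separable from background in the Compton channel")
    structure(list(label_map = matrix(0L, nrow(ch), ncol(ch)),
                   roi_ids = integer(0), pixel_counts = integer(0),
                   status = "no-foreground", threshold = thr,
                   pre_filter_foreground = matrix(FALSE, nrow(ch), ncol(ch))),
              class = "roi_set")
  }
  if (is.na(thr)) return(empty())
  mask <- ch > thr
  if (!any(mask) || all(mask)) return(empty())
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  out_lab <- matrix(0L, nrow(ch), ncol(ch))
  ids <- integer(0); counts <- integer(0)
  for (i in seq_along(keep)) {
    out_lab[lab == keep[i]] <- i
    ids <- c(ids, i); counts <- c(counts, sizes[keep[i]])
  }
  status <- if (length(ids)) "ok" else "no-foreground"
  if (!length(ids))
    warnf("all %d candidate components fell below min_pixels = %d",
          length(sizes), min_pixels)
  structure(list(label_map = out_lab, roi_ids = ids, pixel_counts = counts,
                 status = status, threshold = thr,
                 pre_filter_foreground = mask),
            class = "roi_set")
}

#' Currie critical level for distinguishing signal from background
#'
#' The decision threshold above background below which a net signal is not
#' distinguishable from noise at type-I rate alpha, in the paired-blank
#' convention: \eqn{L_C = z_{1-\alpha}\sqrt{2\bar B}} where \eqn{\bar B} is
#' the mean background count.  At the default alpha = 0.05 this is the
#' classical \eqn{2.33\sqrt{\bar B}} (since \eqn{1.645\sqrt 2 = 2.33}).
#'
#' @param background_pixels vector of background counts (>= 0).
#' @param alpha type-I error rate.
#' @return A list of class \code{"currie_level"} with
#'   \code{background_mean}, \code{critical_level}, \code{alpha}.
#' @export
currie_threshold <- function(background_pixels, alpha = 0.05) {
  if (!length(background_pixels)) stopf("need at least one background pixel")
  if (any(background_pixels < 0))
    stopf("background counts must be non-negative")
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  b <- mean(background_pixels)
  structure(list(background_mean = b,
                 critical_level = qnorm(1 - alpha) * sqrt(2 * b),
                 alpha = alpha),
            class = "currie_level")
}

#' Quantify per-worm elemental content over regions of interest
#'
#' Background-corrects the requested channel (subtracting the background
#' mean), zeroes net pixel values at or below the Currie critical level,
#' applies the foil calibration factor with conversion to pg um^-2, and
#' reports per ROI the mean areal density, area and total mass.  The
#' identity total mass = mean areal density x area holds exactly.
#'
#' @param scene an \code{elemental_scene} with raw-count channels.
#' @param rois a [segment_compton()] \code{roi_set}.
#' @param factor calibration factor, ug cm^-2 per count (from
#'   [foil_calibration()]).
#' @param currie a [currie_threshold()] level; NULL skips background
#'   correction and zeroing (already-calibrated maps).
#' @param element channel name to quantify.
#' @param roi_ids ROI ids to report (default all).
#' @return Data frame with one row per ROI: \code{roi_id},
#'   \code{mean_areal_density} (pg um^-2), \code{total_mass} (pg),
#'   \code{area} (um^2), \code{n_pixels}.
#' @export
quantify_rois <- function(scene, rois, factor, currie = NULL,
                          element = "Fe", roi_ids = rois$roi_ids) {
  if (!element %in% names(scene$channels))
    stopf("scene has no '%s' channel", element)
  missing_ids <- setdiff(roi_ids, rois$roi_ids)
  if (length(missing_ids))
    stopf("roi id(s) %s absent from the label map",
          paste(missing_ids, collapse = ", "))
  ch <- scene$channels[[element]]
  net <- ch
  if (!is.null(currie)) {
    net <- net - currie$background_mean
    net[net <= currie$critical_level] <- 0
  }
  dens <- net * factor * UG_CM2_TO_PG_UM2  # pg um^-2 per pixel
  out <- lapply(roi_ids, function(id) {
    px <- rois$label_map == id
    n <- sum(px)
    m <- mean(dens[px])
    area <- n * scene$pixel_area
    data.frame(roi_id = id, mean_areal_density = m, total_mass = m * area,
               area = area, n_pixels = n)
  })
  do.call(rbind, out)
}
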