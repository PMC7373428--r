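#' Energy-scan segments of the Fe K-edge imaging protocol
#'
#' The published scan protocol for fluorescence-detected XANES imaging across
#' the Fe K-edge: coarse steps far from the edge, 0.4 eV steps through the
#' near-edge region.  Each row is (start eV, end eV, number of steps, step
#' size eV).
#'
#' @return A data frame with columns \code{start}, \code{end}, \code{steps},
#'   \code{step_eV}.
#' @export
fe_kedge_segments <- function() {
  data.frame(
    start   = c(7000, 7100, 7105, 7135, 7165, 7405),
    end     = c(7100, 7105, 7135, 7165, 7405, 7455),
    steps   = c(5L, 5L, 75L, 15L, 1L, 5L),
    step_eV = c(20, 1, 0.4, 2, 240, 5))
}

#' Build an energy grid from scan segments
#'
#' Concatenates energies from the declared step counts: the grid starts at
#' the first segment's start and advances by \code{steps} increments of
#' \code{step_eV} per segment, giving \eqn{1 + \sum \mathrm{steps}} points.
#' When built from [fe_kedge_segments()] the declared total is 106 incident
#' energies, but the printed step counts sum to 106 steps (107 points) and
#' the final segment's span (50 eV) disagrees with its steps (5 x 5 eV =
#' 25 eV).  The builder trusts the step counts, truncates to
#' \code{n_points}, and records both discrepancies in
#' \code{$discrepancies} rather than silently resolving them.
#'
#' @param segments a segment table as from [fe_kedge_segments()].
#' @param n_points declared total point count to truncate to (NULL = keep
#'   all points implied by the step counts).
#' @param edge_reference nominal edge energy, eV.
#' @return A list of class \code{"energy_grid"} with fields
#'   \code{energies}, \code{segments}, \code{edge_reference},
#'   \code{discrepancies}.
#' @examples
#' g <- build_energy_grid()
#' length(g$energies)  # 106
#' @export
build_energy_grid <- function(segments = fe_kedge_segments(),
                              n_points = 106L, edge_reference = 7112) {
  if (!all(c("start", "end", "steps", "step_eV") %in% names(segments)))
    stopf("'segments' needs columns start, end, steps, step_eV")
  if (is.unsorted(segments$start))
    stopf("'segments' must be ordered by start energy")
  if (nrow(segments) > 1 &&
      any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-9))
    stopf("'segments' must be contiguous")
  notes <- character()
  energies <- segments$start[1]
  for (i in seq_len(nrow(segments))) {
    span <- segments$end[i] - segments$start[i]
    covered <- segments$steps[i] * segments$step_eV[i]
    if (abs(span - covered) > 1e-9)
      notes <- c(notes, sprintf(
        "segment %d: declared span %g eV but %d x %g eV steps cover %g eV; grid follows the step counts",
        i, span, segments$steps[i], segments$step_eV[i], covered))
    energies <- c(energies,
                  segments$start[i] + segments$step_eV[i] * seq_len(segments$steps[i]))
  }
  if (!is.null(n_points) && length(energies) != n_points) {
    notes <- c(notes, sprintf(
      "step counts imply %d points but %d were declared; truncating to %d",
      length(energies), n_points, n_points))
    energies <- energies[seq_len(min(n_points, length(energies)))]
  }
  if (is.unsorted(energies, strictly = TRUE))
    stopf("constructed energies are not strictly increasing")
  structure(list(energies = energies, segments = segments,
                 edge_reference = edge_reference, discrepancies = notes),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d points, %.1f-%.1f eV (edge ref %.1f eV)\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$edge_reference))
  for (d in x$discrepancies) cat(" note:", d, "\n")
  invisible(x)
}
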