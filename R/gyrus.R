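#' One-dimensional model of the superior temporal gyrus
#'
#' The STG length analysis is intrinsically one-dimensional: responses are
#' binned in 1-mm steps along the anterior-to-posterior extent of the gyrus.
#' `make_gyrus` therefore models the gyrus as a straight strip, parameterized
#' by position in mm from the anterior tip. Two landmarks live on the strip:
#' the anatomical boundary (a proxy for the posterior margin of Heschl's
#' gyrus) and the true functional boundary planted by the simulator, i.e. the
#' position where the generating clear-minus-noisy response difference
#' crosses zero.
#'
#' Strip positions map affinely to a standard-space anterior-posterior
#' y-coordinate: `y = standard_offset_mm - position_mm` (y decreases toward
#' posterior). The defaults place the anatomical landmark at y = -30 and the
#' true boundary at y = -28.
#'
#' @param length_mm physical length of the strip (default 100).
#' @param anatomical_landmark_mm position of the Heschl's-gyrus posterior
#'   margin proxy (default 70).
#' @param true_boundary_mm position where the planted clear-vs-noisy contrast
#'   crosses zero (default 68; in the posterior third of the default strip).
#' @param standard_offset_mm additive offset of the position-to-y map
#'   (default 40).
#' @param node_spacing_mm spacing of surface nodes (default 1).
#' @return An object of class `gyrus_model` with fields `length_mm`,
#'   `node_spacing_mm`, `anatomical_landmark_mm`, `true_boundary_mm`,
#'   `standard_offset_mm` and `nodes` (node positions in mm).
#' @examples
#' g <- make_gyrus()
#' standard_y(g, g$anatomical_landmark_mm)  # -30
#' standard_y(g, g$true_boundary_mm)        # -28
#' @export
make_gyrus <- function(length_mm = 100,
                       anatomical_landmark_mm = 70,
                       true_boundary_mm = 68,
                       standard_offset_mm = 40,
                       node_spacing_mm = 1) {
  if (!is.numeric(length_mm) || length_mm <= 0)
    stopf("length_mm must be positive (got %s)", format(length_mm))
  if (anatomical_landmark_mm <= 0 || anatomical_landmark_mm >= length_mm)
    stopf("anatomical_landmark_mm must lie strictly inside (0, %g)", length_mm)
  if (true_boundary_mm <= 0 || true_boundary_mm >= length_mm)
    stopf("true_boundary_mm must lie strictly inside (0, %g)", length_mm)
  if (node_spacing_mm <= 0) stopf("node_spacing_mm must be positive")
  n_nodes <- floor(length_mm / node_spacing_mm) + 1
  structure(
    list(
      length_mm = length_mm,
      node_spacing_mm = node_spacing_mm,
      anatomical_landmark_mm = anatomical_landmark_mm,
      true_boundary_mm = true_boundary_mm,
      standard_offset_mm = standard_offset_mm,
      nodes = seq(0, by = node_spacing_mm, length.out = n_nodes)
    ),
    class = "gyrus_model"
  )
}

#' Map strip position to standard-space y-coordinate
#'
#' @param gyrus a `gyrus_model`.
#' @param position_mm numeric vector of positions along the strip.
#' @return standard-space y in mm (more negative = more posterior).
#' @export
standard_y <- function(gyrus, position_mm) {
  stopifnot(inherits(gyrus, "gyrus_model"))
  gyrus$standard_offset_mm - position_mm
}

#' Anatomical anterior/posterior STG boundary
#'
#' Returns the position of the anatomical landmark (the posterior-most point
#' of Heschl's gyrus in the real anatomy) that divides the strip into
#' anterior and posterior STG.
#'
#' @param gyrus a `gyrus_model`.
#' @return position in mm along the strip.
#' @export
anatomical_boundary <- function(gyrus) {
  stopifnot(inherits(gyrus, "gyrus_model"))
  gyrus$anatomical_landmark_mm
}

#' @export
print.gyrus_model <- function(x, ...) {
  cat(sprintf(
    "<gyrus_model> %g mm strip, %d nodes (%g mm spacing)\n",
    x$length_mm, length(x$nodes), x$node_spacing_mm))
  cat(sprintf("  anatomical landmark: %g mm (standard y = %g)\n",
              x$anatomical_landmark_mm, standard_y(x, x$anatomical_landmark_mm)))
  cat(sprintf("  true functional boundary: %g mm (standard y = %g)\n",
              x$true_boundary_mm, standard_y(x, x$true_boundary_mm)))
  invisible(x)
}
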