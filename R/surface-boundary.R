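#' Sample a voxel statistic map onto surface nodes
#'
#' For each surface node, the line along the local cortical thickness is
#' subdivided into 15 equal steps; the voxel value at each step is sampled
#' (nearest voxel) and the 15 samples are averaged. In the strip geometry a
#' node at position p reads from the voxel column nearest p across its depth
#' voxels.
#'
#' @param stat_values per-voxel statistic (e.g. contrast t), aligned with
#'   `voxels`.
#' @param voxels voxel table (`position_mm`, `depth`, `on_gyrus`), e.g.
#'   `session$voxels`.
#' @param gyrus a `gyrus_model` (provides the node coordinates).
#' @param f_steps number of thickness samples (default 15).
#' @return data.frame `position_mm` (node), `value`.
#' @export
sample_volume_to_surface <- function(stat_values, voxels, gyrus, f_steps = 15) {
  stopifnot(inherits(gyrus, "gyrus_model"), length(stat_values) == nrow(voxels))
  on <- which(voxels$on_gyrus)
  if (length(on) == 0) stopf("no on-gyrus voxels")
  pos <- voxels$position_mm[on]
  dep <- voxels$depth[on]
  cols <- sort(unique(pos))
  depths <- sort(unique(dep))
  n_depth <- length(depths)
  vals <- vapply(gyrus$nodes, function(p) {
    col <- cols[which.min(abs(cols - p))]
    # thickness coordinate runs (0, 1]; each step reads the nearest depth voxel
    steps <- (seq_len(f_steps) - 0.5) / f_steps
    d_idx <- depths[pmin(n_depth, pmax(1L, ceiling(steps * n_depth)))]
    v <- vapply(d_idx, function(d) {
      i <- on[pos == col & dep == d]
      if (length(i) == 0) NA_real_ else stat_values[i[1]]
    }, numeric(1))
    mean(v)
  }, numeric(1))
  data.frame(position_mm = gyrus$nodes, value = vals)
}

#' Bin node values into a 1-mm anterior-to-posterior profile
#'
#' @param node_values numeric values per node.
#' @param node_positions node positions in mm.
#' @param length_mm strip length (default max position).
#' @param bin_mm bin width (default 1).
#' @return Object of class `surface_profile`: data.frame `bin_start_mm`,
#'   `bin_end_mm`, `mean_t`, `n_nodes` (empty bins have `NA` mean), with
#'   attribute `length_mm`.
#' @export
bin_profile <- function(node_values, node_positions,
                        length_mm = max(node_positions), bin_mm = 1) {
  if (length(node_values) == 0) stopf("no nodes")
  stopifnot(length(node_values) == length(node_positions))
  if (any(node_positions < 0 | node_positions > length_mm))
    stopf("node positions outside [0, %g]", length_mm)
  starts <- seq(0, length_mm - bin_mm, by = bin_mm)
  idx <- pmin(length(starts), floor(node_positions / bin_mm) + 1L)
  mean_t <- rep(NA_real_, length(starts))
  n_nodes <- integer(length(starts))
  agg_n <- tapply(node_values, idx, function(v) sum(!is.na(v)))
  agg_m <- tapply(node_values, idx, mean, na.rm = TRUE)
  at <- as.integer(names(agg_m))
  n_nodes[at] <- as.integer(agg_n)
  mean_t[at] <- ifelse(n_nodes[at] > 0, agg_m, NA_real_)
  out <- data.frame(bin_start_mm = starts, bin_end_mm = starts + bin_mm,
                    mean_t = mean_t, n_nodes = n_nodes)
  structure(out, class = c("surface_profile", "data.frame"),
            length_mm = length_mm)
}

#' Locate the functional boundary as the first posterior-third zero-crossing
#'
#' Scans the binned t-profile anterior to posterior within the posterior
#' third of the strip and returns the first bin at which the sign of the
#' mean t changes relative to the previous non-empty bin (the crossing bin
#' is the posterior bin of the sign-changing pair; a bin mean of exactly
#' zero counts as a crossing and that bin is reported). The initial
#' reference sign is the dominant sign of the anterior two-thirds of the
#' profile, so a profile that has already flipped when the posterior third
#' begins reports the third's first non-empty bin (the crossing completed
#' at or just before the third). Returns `NA` when the profile never
#' changes sign.
#'
#' @param profile a `surface_profile`.
#' @return Position (mm) of the lower edge of the crossing bin, or `NA_real_`.
#' @export
find_functional_boundary <- function(profile) {
  stopifnot(inherits(profile, "surface_profile"))
  length_mm <- attr(profile, "length_mm")
  nonempty <- which(!is.na(profile$mean_t))
  if (length(nonempty) == 0) stopf("all bins are empty")
  third_start <- 2 * length_mm / 3
  in_third <- nonempty[profile$bin_start_mm[nonempty] >= third_start]
  if (length(in_third) == 0) return(NA_real_)
  prior <- nonempty[nonempty < in_third[1]]
  ref_sign <- if (length(prior) > 0) sign(mean(profile$mean_t[prior])) else 0
  s <- c(ref_sign, sign(profile$mean_t[in_third]))
  for (k in seq_along(in_third)) {
    if (s[k + 1] == 0) return(profile$bin_start_mm[in_third[k]])
    if (s[k] != 0 && s[k + 1] != s[k])
      return(profile$bin_start_mm[in_third[k]])
  }
  NA_real_
}

#' Boundary estimate for one hemisphere
#'
#' Combines the functional (zero-crossing) and anatomical (landmark)
#' boundary positions with their standard-space y-coordinates.
#'
#' @param profile a `surface_profile`.
#' @param gyrus a `gyrus_model`.
#' @return Object of class `boundary_estimate`: `functional_mm`,
#'   `anatomical_mm`, `functional_y`, `anatomical_y`, `distance_mm`.
#' @export
estimate_boundary <- function(profile, gyrus) {
  f <- find_functional_boundary(profile)
  a <- anatomical_boundary(gyrus)
  structure(
    list(functional_mm = f, anatomical_mm = a,
         functional_y = if (is.na(f)) NA_real_ else standard_y(gyrus, f),
         anatomical_y = standard_y(gyrus, a),
         distance_mm = abs(f - a)),
    class = "boundary_estimate"
  )
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf(
    "<boundary_estimate> functional %s mm (y = %s), anatomical %g mm (y = %g), distance %s mm\n",
    format(x$functional_mm), format(x$functional_y),
    x$anatomical_mm, x$anatomical_y, format(x$distance_mm)))
  invisible(x)
}

#' Boundary-relative anterior and posterior ROIs
#'
#' Anterior ROI: on-gyrus voxels from 30 mm anterior to the boundary up to
#' (but excluding) the boundary. Posterior ROI: voxels from the boundary to
#' 15 mm posterior (inclusive). Both are restricted to voxels whose omnibus
#' F exceeds the threshold (F > 5), mirroring the inclusion of only
#' stimulus-responsive recording sites. Extents reaching past the strip ends
#' are clipped with a warning.
#'
#' @param boundary_mm boundary position.
#' @param voxels voxel table (`position_mm`, `on_gyrus`).
#' @param omnibus_f per-voxel omnibus F.
#' @param extents_mm anterior and posterior extents (default `c(30, 15)`).
#' @param f_threshold inclusion threshold (default 5).
#' @return Object of class `roi_spec`: integer voxel indices `anterior`,
#'   `posterior`, plus the defining parameters and an `empty` flag.
#' @export
define_rois <- function(boundary_mm, voxels, omnibus_f,
                        extents_mm = c(30, 15), f_threshold = 5) {
  stopifnot(length(omnibus_f) == nrow(voxels), all(extents_mm > 0))
  lo <- boundary_mm - extents_mm[1]
  hi <- boundary_mm + extents_mm[2]
  rng <- range(voxels$position_mm, na.rm = TRUE)
  if (lo < rng[1] || hi > rng[2])
    warning("ROI extent clipped at the end of the strip", call. = FALSE)
  p <- voxels$position_mm
  keep <- voxels$on_gyrus & is.finite(omnibus_f) & omnibus_f > f_threshold
  ant <- which(keep & p >= lo & p < boundary_mm)
  post <- which(keep & p >= boundary_mm & p <= hi)
  structure(
    list(anterior = ant, posterior = post, boundary_mm = boundary_mm,
         extents_mm = extents_mm, f_threshold = f_threshold,
         empty = length(ant) == 0 && length(post) == 0),
    class = "roi_spec"
  )
}

#' Group summary of functional vs anatomical boundary locations
#'
#' Means and SDs of the standard-space boundary coordinates across
#' hemispheres, with a paired comparison of the functional and anatomical
#' positions. With fewer than 2 hemispheres the summary is descriptive only.
#'
#' @param estimates list of `boundary_estimate` objects (one per hemisphere).
#' @return list: `table` (per-hemisphere coordinates), `mean_functional_y`,
#'   `sd_functional_y`, `mean_anatomical_y`, `sd_anatomical_y`,
#'   `mean_distance_mm`, and `comparison` (a [paired_t()] result or a
#'   degenerate/descriptive marker).
#' @export
boundary_report <- function(estimates) {
  tab <- do.call(rbind, lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(hemisphere = i, functional_mm = e$functional_mm,
               anatomical_mm = e$anatomical_mm,
               functional_y = e$functional_y, anatomical_y = e$anatomical_y,
               distance_mm = e$distance_mm)
  }))
  ok <- stats::complete.cases(tab[, c("functional_y", "anatomical_y")])
  cmp <- if (sum(ok) < 2) {
    list(status = "descriptive-only", n = sum(ok))
  } else {
    paired_t(tab$functional_y[ok], tab$anatomical_y[ok])
  }
  list(table = tab,
       mean_functional_y = mean(tab$functional_y, na.rm = TRUE),
       sd_functional_y = stats::sd(tab$functional_y, na.rm = TRUE),
       mean_anatomical_y = mean(tab$anatomical_y, na.rm = TRUE),
       sd_anatomical_y = stats::sd(tab$anatomical_y, na.rm = TRUE),
       mean_distance_mm = mean(tab$distance_mm, na.rm = TRUE),
       comparison = cmp)
}
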