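#' Write / read an ECoG recording as an array container with JSON header
#'
#' Samples go to `<stem>.dat` (little-endian float32, channel-major),
#' metadata to `<stem>.json` (sample rate, channel table, gyrus geometry)
#' and events to `<stem>_events.tsv`.
#'
#' @param recording an `ecog_recording`.
#' @param stem path stem (no extension).
#' @return the stem, invisibly.
#' @export
write_ecog <- function(recording, stem) {
  hdr <- list(
    sample_rate_hz = recording$sample_rate_hz,
    n_channels = nrow(recording$samples),
    n_samples = ncol(recording$samples),
    dtype = "float32",
    order = "channel-major",
    channels = recording$channels,
    gyrus = recording$gyrus[c("length_mm", "node_spacing_mm",
                              "anatomical_landmark_mm", "true_boundary_mm",
                              "standard_offset_mm")]
  )
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$samples)), con, size = 4, endian = "little")
  utils::write.table(recording$events, paste0(stem, "_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_ecog
#' @export
read_ecog <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = hdr$n_channels * hdr$n_samples,
               size = 4, endian = "little")
  g <- hdr$gyrus
  structure(
    list(
      sample_rate_hz = hdr$sample_rate_hz,
      channels = as.data.frame(hdr$channels),
      samples = matrix(x, nrow = hdr$n_channels, byrow = TRUE),
      events = utils::read.delim(paste0(stem, "_events.tsv"),
                                 stringsAsFactors = FALSE),
      gyrus = make_gyrus(g$length_mm, g$anatomical_landmark_mm,
                         g$true_boundary_mm, g$standard_offset_mm,
                         g$node_spacing_mm)
    ),
    class = "ecog_recording"
  )
}

#' Write / read a BOLD session as NIfTI with JSON sidecar
#'
#' Voxels are laid out on a (position-column x depth x 1) grid with time as
#' the fourth dimension; off-gyrus voxels occupy an extra row of the second
#' axis. The sidecar records the TR, voxel table and gyrus geometry; motion
#' parameters go to `<stem>_motion.tsv` and events to `<stem>_events.tsv`.
#'
#' @param session a `bold_session`.
#' @param stem path stem.
#' @return the stem, invisibly.
#' @export
write_bold <- function(session, stem) {
  vox <- session$voxels
  on <- vox$on_gyrus
  pos <- sort(unique(vox$position_mm[on]))
  n_depth <- max(vox$depth[on])
  n_off <- sum(!on)
  nx <- length(pos)
  ny <- n_depth + (n_off > 0)
  n_vol <- nrow(session$series)
  arr <- array(0, dim = c(nx, ny, 1, n_vol))
  ix <- integer(nrow(vox)); iy <- integer(nrow(vox))
  ix[on] <- match(vox$position_mm[on], pos)
  iy[on] <- vox$depth[on]
  if (n_off > 0) { ix[!on] <- seq_len(n_off); iy[!on] <- ny }
  for (v in seq_len(nrow(vox)))
    arr[ix[v], iy[v], 1, ] <- session$series[, v]
  img <- RNifti::asNifti(arr, pixdim = c(2, 2, 2, session$tr_s))
  RNifti::writeNifti(img, paste0(stem, ".nii"), compression = 0)
  side <- list(RepetitionTime = session$tr_s,
               voxels = cbind(vox, ix = ix, iy = iy),
               gyrus = session$gyrus[c("length_mm", "node_spacing_mm",
                                       "anatomical_landmark_mm",
                                       "true_boundary_mm",
                                       "standard_offset_mm")],
               n_runs = session$schedule$n_runs,
               volumes_per_run = session$schedule$volumes_per_run)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(as.data.frame(session$motion), paste0(stem, "_motion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_events_tsv(session$schedule, paste0(stem, "_events.tsv"))
  invisible(stem)
}

#' @rdname write_bold
#' @export
read_bold <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  vox <- as.data.frame(side$voxels)
  n_vol <- dim(img)[4]
  series <- matrix(0, n_vol, nrow(vox))
  for (v in seq_len(nrow(vox)))
    series[, v] <- img[vox$ix[v], vox$iy[v], 1, ]
  g <- side$gyrus
  ev <- utils::read.delim(paste0(stem, "_events.tsv"), stringsAsFactors = FALSE)
  tr_s <- side$RepetitionTime
  sched <- structure(
    list(trials = data.frame(run = ev$run, onset_s = ev$onset,
                             duration_s = ev$duration,
                             condition = ev$trial_type,
                             stringsAsFactors = FALSE),
         tr_s = tr_s, volumes_per_run = side$volumes_per_run,
         n_runs = side$n_runs,
         run_duration_s = side$volumes_per_run * tr_s,
         baseline_s_per_run = side$volumes_per_run * tr_s -
           sum(ev$run == 1) * mean(ev$duration)),
    class = "event_schedule")
  structure(
    list(series = series,
         voxels = vox[, c("position_mm", "depth", "on_gyrus", "id")],
         motion = as.matrix(utils::read.delim(paste0(stem, "_motion.tsv"))),
         schedule = sched, tr_s = tr_s,
         gyrus = make_gyrus(g$length_mm, g$anatomical_landmark_mm,
                            g$true_boundary_mm, g$standard_offset_mm,
                            g$node_spacing_mm)),
    class = "bold_session"
  )
}

#' Write an electrode position table
#'
#' @param channels data.frame with `id` and `position_mm`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_electrodes_tsv <- function(channels, path) {
  utils::write.table(channels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
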