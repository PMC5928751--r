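#' Default pipeline configuration
#'
#' Bundles every tunable of the simulate -> analyze -> report pipeline. The
#' defaults reproduce the study conditions at a desk-friendly participant
#' count: rapid event-related runs of 160 volumes at TR 1.5 s with 48 3-s
#' trials (12 per condition), ECoG at 2 kHz with electrodes spanning 30 mm
#' anterior to 15 mm posterior of the boundary, and the planted response
#' geometry of [default_sim_params()].
#'
#' @param seed master seed; per-stage child seeds derive from it via
#'   [child_seed()].
#' @param n_ecog_participants ECoG participants (default 4).
#' @param n_electrodes electrodes per ECoG participant (default 6).
#' @param ecog_trials_per_condition ECoG trials per condition (default 40).
#' @param n_fmri_participants fMRI participants (default 6).
#' @param hemispheres_per_participant analyzed hemispheres each (default 2).
#' @param n_runs fMRI runs per hemisphere session (default 5).
#' @param params a `sim_params` list.
#' @param ecog_window_ms ECoG epoch window (default `c(-700, 2000)`, wide
#'   enough to cover the sustained word response for the forward model).
#' @param response_window_ms ECoG response window for amplitude summaries.
#' @param alpha electrode inclusion threshold.
#' @param f_threshold ROI omnibus-F threshold.
#' @param roi_extents_mm anterior/posterior ROI extents.
#' @param hrf the comparison HRF for the forward model.
#' @return list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L,
                                    n_ecog_participants = 4,
                                    n_electrodes = 6,
                                    ecog_trials_per_condition = 40,
                                    n_fmri_participants = 6,
                                    hemispheres_per_participant = 2,
                                    n_runs = 5,
                                    params = default_sim_params(),
                                    ecog_window_ms = c(-700, 2000),
                                    response_window_ms = c(0, 500),
                                    alpha = 1e-3,
                                    f_threshold = 5,
                                    roi_extents_mm = c(30, 15),
                                    hrf = make_double_gamma_hrf()) {
  cfg <- as.list(environment())
  stopifnot(seed == floor(seed), n_runs >= 1, alpha > 0, alpha < 1,
            all(roi_extents_mm > 0))
  structure(cfg, class = "pipeline_config")
}

# mean high-gamma percent-change timecourse across trials of a condition
# group and a set of electrodes, from time 0 onward
mean_response_timecourse <- function(hg, channels_idx, auditory) {
  keep_t <- hg$time_ms >= 0
  trials <- which(auditory_of(hg$events$condition) == auditory)
  m <- hg$pc[trials, keep_t, channels_idx, drop = FALSE]
  colMeans(matrix(aperm(m, c(1, 3, 2)), ncol = sum(keep_t)))
}

analyze_ecog_participant <- function(cfg, p) {
  gy <- make_gyrus()
  b <- gy$anatomical_landmark_mm
  positions <- seq(b - cfg$roi_extents_mm[1], b + cfg$roi_extents_mm[2],
                   length.out = cfg$n_electrodes)
  rec <- simulate_ecog(gy, positions,
                       n_trials_per_condition = cfg$ecog_trials_per_condition,
                       params = cfg$params,
                       seed = child_seed(cfg$seed, "ecog", p))
  hg <- ecog_highgamma_pipeline(rec, window_ms = cfg$ecog_window_ms)
  tp <- trial_power_summary(hg, response_ms = cfg$response_window_ms)
  strip_ids <- rec$channels$id[rec$channels$on_strip]
  sel <- select_responsive_electrodes(tp[tp$electrode %in% strip_ids, ],
                                      alpha = cfg$alpha)
  t_resp <- hg$time_ms >= cfg$response_window_ms[1] &
    hg$time_ms <= cfg$response_window_ms[2]
  rows <- list()
  for (id in sel$electrode[sel$included]) {
    ch <- match(id, hg$channels$id)
    pos <- hg$channels$position_mm[ch]
    resp <- rowMeans(hg$pc[, t_resp, ch, drop = FALSE], dims = 1)
    for (cn in condition_levels()) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = sprintf("p%d_%s", p, id), participant = sprintf("ecog_p%d", p),
        location = if (pos < b) "anterior" else "posterior",
        auditory = auditory_of(cn), visual = visual_of(cn),
        response = mean(resp[hg$events$condition == cn]),
        position_mm = pos)
    }
  }
  list(hg = hg, selection = sel, gyrus = gy,
       responses = if (length(rows)) do.call(rbind, rows) else NULL)
}

analyze_fmri_hemisphere <- function(cfg, h) {
  gy <- make_gyrus()
  sched <- make_event_schedule(n_runs = cfg$n_runs,
                               seed = child_seed(cfg$seed, "schedule", h))
  ses <- simulate_bold(gy, sched, params = cfg$params,
                       seed = child_seed(cfg$seed, "bold", h))
  psc <- scale_to_psc(ses$series)
  block <- fit_glm(psc, build_block_design(sched, ses$motion))
  con <- contrast_clear_vs_noisy(block)
  nodes <- sample_volume_to_surface(con$t, ses$voxels, gy)
  prof <- bin_profile(nodes$value, nodes$position_mm, length_mm = gy$length_mm)
  est <- estimate_boundary(prof, gy)
  boundary <- if (is.na(est$functional_mm)) est$anatomical_mm else est$functional_mm
  rois <- define_rois(boundary, ses$voxels, block$omnibus_f,
                      extents_mm = cfg$roi_extents_mm,
                      f_threshold = cfg$f_threshold)
  tent <- fit_glm(psc, build_tent_design(sched, ses$motion))
  fir <- list()
  responses <- list()
  for (region in c("anterior", "posterior")) {
    vox_idx <- rois[[region]]
    for (cn in condition_levels()) {
      f <- estimate_hrf_tent(tent, cn, voxels = vox_idx)
      fir[[paste(region, cn, sep = ".")]] <- f$mean
      amp <- if (length(vox_idx) == 0) NA_real_ else
        mean(glm_contrast(block, as.numeric(condition_levels() == cn))$estimate[vox_idx])
      responses[[length(responses) + 1L]] <- data.frame(
        unit = sprintf("hemi%02d", h),
        participant = sprintf("fmri_p%d", (h - 1) %/% cfg$hemispheres_per_participant + 1),
        location = region, auditory = auditory_of(cn), visual = visual_of(cn),
        response = amp)
    }
  }
  behav <- simulate_behavior(sched, cfg$params,
                             seed = child_seed(cfg$seed, "behavior", h))
  behav$participant <- sprintf("fmri_p%d", (h - 1) %/% cfg$hemispheres_per_participant + 1)
  list(estimate = est, profile = prof, rois = rois,
       fir = fir, knots = tent$design$knots,
       responses = do.call(rbind, responses), behavior = behav)
}

#' Run the full simulate -> analyze -> report pipeline
#'
#' Executes every stage on synthetic data with a planted boundary: ECoG
#' simulation and high-gamma quantification with electrode selection; BOLD
#' simulation, percent-signal scaling, block and tent GLMs; the 1-mm length
#' analysis with zero-crossing boundary detection per hemisphere;
#' boundary-relative ROI response estimation; the ECoG-to-BOLD forward model
#' with per-condition scale factors; and the mixed-effects and behavioral
#' summaries. Identical config + seed give identical reports.
#'
#' @param config a `pipeline_config`.
#' @param output_dir optional directory; when given, the report, a copy of
#'   the configuration and TSV tables are written there.
#' @return list of class `pipeline_report` with elements `boundary`
#'   (group summary), `boundary_estimates`, `ecog` (selection + LME input),
#'   `fir_curves`, `forward` (scale fits, correlations, mean scale),
#'   `lme_ecog`, `lme_fmri`, `behavior`, `config_hash`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  ecog <- lapply(seq_len(config$n_ecog_participants),
                 function(p) analyze_ecog_participant(config, p))
  ecog_tab <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(ecog, `[[`, "responses")))

  n_hemi <- config$n_fmri_participants * config$hemispheres_per_participant
  fmri <- lapply(seq_len(n_hemi), function(h) analyze_fmri_hemisphere(config, h))
  boundary_est <- lapply(fmri, `[[`, "estimate")
  boundary <- boundary_report(boundary_est)

  # group-mean FIR curves per region x auditory group (pooling the visual
  # factor), and matching grand-mean ECoG timecourses
  knots <- fmri[[1]]$knots
  fir_curves <- list()
  for (region in c("anterior", "posterior")) {
    for (aud in c("clear", "noisy")) {
      conds <- condition_levels()[auditory_of(condition_levels()) == aud]
      mats <- lapply(fmri, function(f)
        rowMeans(cbind(f$fir[[paste(region, conds[1], sep = ".")]],
                       f$fir[[paste(region, conds[2], sep = ".")]])))
      fir_curves[[paste(region, aud, sep = ".")]] <-
        rowMeans(do.call(cbind, mats), na.rm = TRUE)
    }
  }

  forward_fits <- list()
  for (region in c("anterior", "posterior")) {
    for (aud in c("clear", "noisy")) {
      key <- paste(region, aud, sep = ".")
      tc <- lapply(ecog, function(e) {
        b <- e$gyrus$anatomical_landmark_mm
        on_strip <- which(e$hg$channels$on_strip)
        idx <- on_strip[if (region == "anterior")
          e$hg$channels$position_mm[on_strip] < b
          else e$hg$channels$position_mm[on_strip] >= b]
        if (length(idx) == 0) return(NULL)
        mean_response_timecourse(e$hg, idx, aud)
      })
      tc <- Filter(Negate(is.null), tc)
      actual <- fir_curves[[key]]
      if (length(tc) == 0 || any(!is.finite(actual))) next
      grand <- rowMeans(do.call(cbind, tc))   # 1 ms grid from stimulus onset
      pred <- predict_bold_from_ecog(grand, config$hrf,
                                     tr_s = config$params$tr_s %||% 1.5,
                                     n_out = length(knots))
      forward_fits[[key]] <- fit_scale_factor(pred$predicted, actual,
                                              condition = key)
    }
  }
  if (length(forward_fits) == 0) stopf("forward model: no usable ROI curves")
  forward <- list(
    fits = forward_fits,
    correlations = vapply(forward_fits, `[[`, numeric(1), "pearson_r"),
    scale_factors = vapply(forward_fits, `[[`, numeric(1), "scale_factor"),
    mean_scale = aggregate_scale_factors(forward_fits)
  )

  fmri_tab <- do.call(rbind, lapply(fmri, `[[`, "responses"))
  fmri_tab <- fmri_tab[is.finite(fmri_tab$response), , drop = FALSE]
  lme_ecog <- tryCatch(fit_lme(ecog_tab[, names(ecog_tab) != "position_mm"]),
                       error = function(e) list(error = conditionMessage(e)))
  lme_fmri <- tryCatch(fit_lme(fmri_tab),
                       error = function(e) list(error = conditionMessage(e)))
  behav <- behavioral_accuracy(do.call(rbind, lapply(fmri, `[[`, "behavior")))

  report <- structure(
    list(boundary = boundary, boundary_estimates = boundary_est,
         ecog = list(responses = ecog_tab,
                     selection = do.call(rbind, lapply(ecog, `[[`, "selection"))),
         fir_curves = c(list(time_s = knots), fir_curves),
         forward = forward, lme_ecog = lme_ecog, lme_fmri = lme_fmri,
         behavior = behav,
         config_hash = config_hash(config), seed = config$seed),
    class = "pipeline_report")

  if (!is.null(output_dir)) write_report(report, config, output_dir)
  report
}

# stable hash of the configuration: md5 of its canonical JSON serialization
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(serialize_config(config), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  cfg$hrf <- cfg$hrf[c("peak_time_s", "undershoot_offset_s",
                       "response_undershoot_ratio", "dt_s", "duration_s",
                       "shape")]
  cfg
}

write_report <- function(report, config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    config = serialize_config(config),
    config_hash = report$config_hash,
    boundary = report$boundary[c("mean_functional_y", "sd_functional_y",
                                 "mean_anatomical_y", "sd_anatomical_y",
                                 "mean_distance_mm")],
    boundary_comparison = report$boundary$comparison,
    forward = list(scale_factors = as.list(report$forward$scale_factors),
                   correlations = as.list(report$forward$correlations),
                   mean_scale = report$forward$mean_scale),
    behavior = list(accuracy = report$behavior$accuracy,
                    comparison = report$behavior$comparison),
    lme_ecog = if (inherits(report$lme_ecog, "lme_result"))
      report$lme_ecog$effects else report$lme_ecog,
    lme_fmri = if (inherits(report$lme_fmri, "lme_result"))
      report$lme_fmri$effects else report$lme_fmri
  )
  jsonlite::write_json(out, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$boundary$table,
                     file.path(output_dir, "boundary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$fir_curves),
                     file.path(output_dir, "fir_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$ecog$responses,
                     file.path(output_dir, "ecog_responses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output_dir)
}

#' Generate a miniature bundled dataset
#'
#' Writes a small session (one run, 8 electrodes, reduced trial count and
#' voxel grid) in the package's on-disk formats: ECoG array container +
#' JSON header + events TSV, BOLD NIfTI + sidecar + motion/events TSV,
#' electrode table TSV and behavior TSV. Deterministic given the seed.
#'
#' @param output_dir writable directory.
#' @param seed RNG seed.
#' @return `output_dir`, invisibly.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  gy <- make_gyrus()
  b <- gy$anatomical_landmark_mm
  rec <- simulate_ecog(gy, seq(b - 30, b + 15, length.out = 8),
                       n_trials_per_condition = 4,
                       seed = child_seed(seed, "fixture-ecog"),
                       n_reference_channels = 8)
  write_ecog(rec, file.path(output_dir, "ecog_mini"))
  write_electrodes_tsv(rec$channels, file.path(output_dir, "electrodes.tsv"))
  sched <- make_event_schedule(n_runs = 1,
                               seed = child_seed(seed, "fixture-schedule"))
  ses <- simulate_bold(gy, sched, seed = child_seed(seed, "fixture-bold"),
                       voxel_spacing_mm = 4, n_depth = 2, n_off_gyrus = 4)
  write_bold(ses, file.path(output_dir, "bold_mini"))
  behav <- simulate_behavior(sched, seed = child_seed(seed, "fixture-behavior"))
  utils::write.table(behav, file.path(output_dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output_dir)
}
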