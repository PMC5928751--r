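#' Ground-truth hemodynamic kernel of the BOLD simulator
#'
#' The generative impulse kernel of the simulator: a double-gamma from the
#' same constructor as the forward model's comparison kernel, but with the
#' faster dynamics that measured single-word responses show -- peak at 5 s
#' and undershoot minimum at 10.5 s. Narrower lobes (shape 9) keep the
#' closely spaced peak and trough resolvable. Each trial's response is this
#' kernel convolved with the sustained neural envelope of the word (the
#' same envelope that drives the ECoG generator), then normalized to unit
#' peak -- see [bold_response_kernel()] -- so that the per-condition
#' amplitude parameter remains the peak percent-signal excursion.
#'
#' @param dt_s sampling step (default 0.01 s; the kernel is evaluated at TR
#'   lags by interpolation).
#' @return an `hrf_model`.
#' @export
bold_truth_kernel <- function(dt_s = 0.01) {
  make_double_gamma_hrf(peak_time_s = 5, undershoot_offset_s = 5.5, ratio = 4,
                        dt_s = dt_s, duration_s = 24, shape = 9)
}

#' Effective single-trial response kernel
#'
#' Convolves a hemodynamic impulse kernel with the word-length neural
#' envelope and renormalizes to unit peak: the shape a deconvolution
#' should recover for one trial. With the default kernel the result peaks
#' near 5.7 s (argmax knot 6 s on the TR grid) and is negative at 10.5 s.
#'
#' @param kernel an `hrf_model` impulse kernel.
#' @return an `hrf_model`-like object with `time`, `kernel`, `dt_s`.
#' @export
bold_response_kernel <- function(kernel = bold_truth_kernel()) {
  dt <- kernel$dt_s
  env <- burst_envelope(seq(0, 1.99, by = dt))
  r <- conv_open(env, kernel$kernel) * dt
  r <- r / max(r)
  structure(list(time = (seq_along(r) - 1) * dt, kernel = r, dt_s = dt,
                 duration_s = (length(r) - 1) * dt),
            class = "hrf_model")
}

# Condition regressors on the volume grid: unit-peak kernel evaluated at
# (volume time - onset) summed over that condition's trials, per run.
condition_regressors <- function(schedule, kernel) {
  conds <- condition_levels()
  n_vol <- schedule$volumes_per_run
  tr <- schedule$tr_s
  vol_t <- (seq_len(n_vol) - 1) * tr
  out <- matrix(0, nrow = n_vol * schedule$n_runs, ncol = length(conds),
                dimnames = list(NULL, conds))
  for (r in seq_len(schedule$n_runs)) {
    rows <- (r - 1) * n_vol + seq_len(n_vol)
    tr_r <- schedule$trials[schedule$trials$run == r, , drop = FALSE]
    for (j in seq_along(conds)) {
      on <- tr_r$onset_s[tr_r$condition == conds[j]]
      if (length(on) == 0) next
      x <- numeric(n_vol)
      for (o in on) x <- x + hrf_at(kernel, vol_t - o)
      out[rows, j] <- x
    }
  }
  out
}

# Smooth AR(1)-like nuisance series, one per motion axis.
motion_series <- function(n_vol, sd, ar = 0.95) {
  as.numeric(stats::filter(stats::rnorm(n_vol, sd = sd * sqrt(1 - ar^2)),
                           ar, method = "recursive"))
}

#' Simulate an event-related BOLD session on the gyrus strip
#'
#' Builds a voxel grid covering the strip (voxel columns every
#' `voxel_spacing_mm`, `n_depth` voxels along the cortical thickness axis,
#' plus `n_off_gyrus` unresponsive voxels). Each on-gyrus voxel's
#' per-condition response amplitude follows the sigmoidal
#' anterior-to-posterior profile whose clear-minus-noisy difference crosses
#' zero at the planted boundary. Amplitudes are convolved with the
#' ground-truth kernel, scaled about a raw intensity baseline, and corrupted
#' with AR(1) noise, per-run quadratic drift, and a small leak of the motion
#' regressors into the data.
#'
#' @param gyrus a `gyrus_model`.
#' @param schedule an `event_schedule`.
#' @param params a `sim_params` list.
#' @param seed RNG seed.
#' @param voxel_spacing_mm spacing of voxel columns along the strip
#'   (default 2).
#' @param n_depth voxels along the thickness axis per column (default 3).
#' @param n_off_gyrus unresponsive voxels (default 12).
#' @param kernel generative single-trial response kernel (default
#'   [bold_response_kernel()]: the impulse HRF convolved with the neural
#'   envelope, unit peak).
#' @return Object of class `bold_session`: `series` (volumes x voxels raw
#'   intensity), `voxels` (data.frame `id`, `position_mm`, `depth`,
#'   `on_gyrus`), `motion` (volumes x 6), `schedule`, `tr_s`, `gyrus`,
#'   `kernel`, `amplitudes` (true per-condition amplitude per voxel).
#' @export
simulate_bold <- function(gyrus, schedule, params = default_sim_params(),
                          seed = 1L, voxel_spacing_mm = 2, n_depth = 3,
                          n_off_gyrus = 12, kernel = bold_response_kernel()) {
  stopifnot(inherits(gyrus, "gyrus_model"), inherits(schedule, "event_schedule"))
  n_vol <- schedule$volumes_per_run * schedule$n_runs
  positions <- seq(voxel_spacing_mm / 2, gyrus$length_mm - voxel_spacing_mm / 2,
                   by = voxel_spacing_mm)
  vox <- expand.grid(position_mm = positions, depth = seq_len(n_depth))
  vox$on_gyrus <- TRUE
  if (n_off_gyrus > 0) {
    vox <- rbind(vox, data.frame(position_mm = NA_real_,
                                 depth = NA_integer_,
                                 on_gyrus = FALSE)[rep(1, n_off_gyrus), ])
  }
  vox$id <- sprintf("V%04d", seq_len(nrow(vox)))
  rownames(vox) <- NULL
  n_vox <- nrow(vox)
  conds <- condition_levels()

  X <- condition_regressors(schedule, kernel)           # n_vol x 4, unit peak
  amp <- matrix(0, nrow = n_vox, ncol = length(conds),
                dimnames = list(NULL, conds))
  for (j in seq_along(conds)) {
    on <- vox$on_gyrus
    amp[on, j] <- amplitude_profile(vox$position_mm[on], gyrus,
                                    params$bold_amp,
                                    params$transition_width_mm, conds[j])
  }
  signal_pct <- X %*% t(amp)                            # n_vol x n_vox

  nz <- params$bold_noise
  with_seed(seed, {
    motion <- sapply(seq_len(6), function(i) motion_series(n_vol, nz$motion_sd))
    colnames(motion) <- paste0("motion", 1:6)

    noise <- matrix(0, n_vol, n_vox)
    if (nz$sd > 0) {
      innov <- matrix(stats::rnorm(n_vol * n_vox, sd = nz$sd * sqrt(1 - nz$ar1^2)),
                      n_vol, n_vox)
      noise <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, nz$ar1, method = "recursive")))
    }

    drift <- matrix(0, n_vol, n_vox)
    if (nz$drift > 0) {
      n_rv <- schedule$volumes_per_run
      u <- seq(-1, 1, length.out = n_rv)
      for (r in seq_len(schedule$n_runs)) {
        rows <- (r - 1) * n_rv + seq_len(n_rv)
        a <- stats::runif(n_vox, -nz$drift, nz$drift)
        b <- stats::runif(n_vox, -nz$drift, nz$drift)
        drift[rows, ] <- outer(u, a) + outer(u^2, b)
      }
    }

    leak <- if (nz$motion_leak > 0)
      motion %*% matrix(stats::rnorm(6 * n_vox, sd = nz$motion_leak), 6, n_vox)
    else matrix(0, n_vol, n_vox)

    series <- params$baseline_intensity *
      (1 + (signal_pct + noise + drift + leak) / 100)

    structure(
      list(series = series, voxels = vox, motion = motion,
           schedule = schedule, tr_s = schedule$tr_s, gyrus = gyrus,
           kernel = kernel, amplitudes = amp),
      class = "bold_session"
    )
  })
}

#' @export
print.bold_session <- function(x, ...) {
  cat(sprintf("<bold_session> %d volumes x %d voxels (TR %g s, %d run(s))\n",
              nrow(x$series), ncol(x$series), x$tr_s, x$schedule$n_runs))
  invisible(x)
}

#' Simulate behavioral word-report accuracy
#'
#' One Bernoulli correctness draw per trial with condition-specific success
#' probability.
#'
#' @param schedule an `event_schedule`.
#' @param params a `sim_params` (field `accuracies`).
#' @param seed RNG seed.
#' @return data.frame `run`, `onset_s`, `condition`, `correct` (0/1).
#' @export
simulate_behavior <- function(schedule, params = default_sim_params(), seed = 1L) {
  stopifnot(inherits(schedule, "event_schedule"))
  acc <- params$accuracies
  if (any(acc < 0 | acc > 1)) stopf("accuracies must lie in [0, 1]")
  tr <- schedule$trials
  with_seed(seed, {
    p <- acc[tr$condition]
    data.frame(run = tr$run, onset_s = tr$onset_s, condition = tr$condition,
               correct = as.integer(stats::runif(nrow(tr)) < p),
               stringsAsFactors = FALSE)
  })
}
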