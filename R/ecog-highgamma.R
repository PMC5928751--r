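#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' removing signals shared by the whole array (reference drift, far-field
#' artifacts).
#'
#' @param recording an `ecog_recording` (or any object with a channels x time
#'   `samples` matrix).
#' @return the recording with re-referenced `samples`.
#' @export
common_average_reference <- function(recording) {
  x <- recording$samples
  if (nrow(x) < 2)
    stopf("common average reference needs >= 2 channels (it would zero a single channel)")
  recording$samples <- sweep(x, 2, colMeans(x), `-`)
  recording
}

#' Remove power-line interference
#'
#' Projects out sine and cosine components at the line frequency (and any
#' harmonics that fall inside a protected band of interest) by least-squares
#' regression over consecutive one-second segments. Regression-based notching
#' removes only the two line degrees of freedom per segment, leaving
#' broadband power in the 70-110 Hz analysis band essentially untouched.
#'
#' @param recording an `ecog_recording`.
#' @param line_hz line frequency (default 60).
#' @param segment_s segment length for the local fit (default 1 s).
#' @return the recording with the line component removed.
#' @export
remove_line_noise <- function(recording, line_hz = 60, segment_s = 1) {
  fs <- recording$sample_rate_hz
  if (line_hz >= fs / 2) stopf("line_hz must be below the Nyquist frequency (%g Hz)", fs / 2)
  x <- recording$samples
  n <- ncol(x)
  seg_len <- max(32L, round(segment_s * fs))
  starts <- seq(1L, n, by = seg_len)
  tt <- (seq_len(n) - 1) / fs
  for (s0 in starts) {
    idx <- s0:min(n, s0 + seg_len - 1L)
    basis <- cbind(sin(2 * pi * line_hz * tt[idx]),
                   cos(2 * pi * line_hz * tt[idx]))
    coefs <- qr.solve(basis, t(x[, idx, drop = FALSE]))
    x[, idx] <- x[, idx, drop = FALSE] - t(basis %*% coefs)
  }
  recording$samples <- x
  recording
}

#' Epoch a recording around auditory-onset events
#'
#' Cuts one channels x time epoch per event, aligned to auditory onset.
#' Events whose window would reach past either edge of the recording are
#' dropped with a message.
#'
#' @param recording an `ecog_recording`.
#' @param window_ms epoch window relative to onset (default `c(-700, 800)`).
#' @return Object of class `ecog_epochs`: list with `epochs` (list of
#'   channels x time matrices), `events` (kept events), `time_ms` (sample
#'   times relative to onset), `sample_rate_hz`, `channels`, `dropped`
#'   (number of dropped events).
#' @export
epoch_trials <- function(recording, window_ms = c(-700, 800)) {
  fs <- recording$sample_rate_hz
  n <- ncol(recording$samples)
  i_rel <- seq(round(window_ms[1] / 1000 * fs), round(window_ms[2] / 1000 * fs))
  onset_idx <- round(recording$events$onset_s * fs) + 1L
  ok <- (onset_idx + i_rel[1]) >= 1L & (onset_idx + i_rel[length(i_rel)]) <= n
  if (any(!ok))
    message(sprintf("epoch_trials: dropped %d event(s) too close to the recording edge",
                    sum(!ok)))
  epochs <- lapply(onset_idx[ok], function(i0)
    recording$samples[, i0 + i_rel, drop = FALSE])
  structure(
    list(epochs = epochs,
         events = recording$events[ok, , drop = FALSE],
         time_ms = i_rel / fs * 1000,
         sample_rate_hz = fs,
         channels = recording$channels,
         dropped = sum(!ok)),
    class = "ecog_epochs"
  )
}

# Sine-taper (Riedel-Sidorenko) multitaper family.
sine_tapers <- function(n, k) {
  sapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1)))
}

# Multitaper band-power time series for a set of equal-length signals.
# x: signals x samples matrix. Returns signals x windows matrix of mean
# power over the requested band, plus the window-center times (sample index,
# 1-based, fractional).
mt_bandpower <- function(x, fs, band, window_s = 0.2, step_s = 0.01,
                         n_tapers = 3) {
  n <- ncol(x)
  wl <- round(window_s * fs)
  if (wl > n) stopf("multitaper window longer than the signal")
  step <- max(1L, round(step_s * fs))
  starts <- seq(1L, n - wl + 1L, by = step)
  tapers <- sine_tapers(wl, n_tapers)
  freqs <- (seq_len(wl) - 1) * fs / wl
  bin <- which(freqs >= band[1] & freqs <= band[2])
  if (length(bin) == 0) stopf("band contains no frequency bins; widen the window")
  nw <- length(starts)
  ns <- nrow(x)
  idx <- outer(seq_len(wl) - 1L, starts, `+`)        # wl x nw window gather
  out <- matrix(0, nrow = ns, ncol = nw)
  # batch several signals per FFT call to amortize interpreter overhead
  chunk <- max(1L, floor(2e6 / (wl * nw)))
  for (s0 in seq(1L, ns, by = chunk)) {
    sig <- s0:min(ns, s0 + chunk - 1L)
    # columns ordered: windows 1..nw of the first signal, then the next
    w <- matrix(t(x[sig, , drop = FALSE])[as.vector(idx), ], nrow = wl)
    p <- 0
    for (k in seq_len(n_tapers)) {
      ft <- stats::mvfft(w * tapers[, k])
      p <- p + abs(ft[bin, , drop = FALSE])^2
    }
    pm <- colMeans(p) / n_tapers
    out[sig, ] <- matrix(pm, nrow = length(sig), ncol = nw, byrow = TRUE)
  }
  list(power = out, center = starts + (wl - 1) / 2)
}

#' Multitaper high-gamma percent-change timecourses
#'
#' Time-resolved 70-110 Hz power via sliding-window multitaper spectral
#' estimation (200 ms windows, 10 ms step, 3 sine tapers ~ +/-5 Hz
#' effective smoothing), averaged over the band and expressed per trial as
#' `100 * (P(t) - Pbase) / Pbase`, where `Pbase` is the electrode's mean
#' band power over the baseline window, averaged across trials (a common
#' divisor, so baseline-estimation noise does not bias every trace). The
#' window-rate estimate is interpolated to a 1 ms output grid.
#'
#' @param epochs an `ecog_epochs`.
#' @param band frequency band in Hz (default `c(70, 110)`).
#' @param baseline_ms baseline window relative to onset (default
#'   `c(-500, -100)`).
#' @param window_s,step_s,n_tapers spectral-estimation controls.
#' @return Object of class `highgamma_timecourse`: `pc` array
#'   (trials x times x channels) of percent change, `time_ms` (1 ms grid),
#'   `events`, `channels`, `band`, `baseline_ms`.
#' @export
multitaper_highgamma <- function(epochs, band = c(70, 110),
                                 baseline_ms = c(-500, -100),
                                 window_s = 0.2, step_s = 0.01, n_tapers = 3) {
  stopifnot(inherits(epochs, "ecog_epochs"))
  fs <- epochs$sample_rate_hz
  if (band[2] >= fs / 2) stopf("band exceeds the Nyquist frequency")
  if (baseline_ms[1] < epochs$time_ms[1])
    stopf("epoch does not cover the baseline window")
  n_trials <- length(epochs$epochs)
  n_ch <- nrow(epochs$channels)
  if (n_trials == 0) stopf("no epochs")

  # stack trials: for each channel, run all trials' windows at once
  epoch_len <- length(epochs$time_ms)
  big <- matrix(0, nrow = n_trials * n_ch, ncol = epoch_len)
  for (tr in seq_len(n_trials))
    big[(tr - 1) * n_ch + seq_len(n_ch), ] <- epochs$epochs[[tr]]
  bp <- mt_bandpower(big, fs, band, window_s, step_s, n_tapers)
  center_ms <- epochs$time_ms[1] + (bp$center - 1) / fs * 1000

  out_ms <- seq(ceiling(center_ms[1]), floor(center_ms[length(center_ms)]))
  base_cols <- center_ms >= baseline_ms[1] & center_ms <= baseline_ms[2]
  if (!any(base_cols)) stopf("baseline window is empty at the window rate")

  # baseline power per electrode = mean over trials of the baseline-window
  # power; a common divisor avoids the ratio bias (and variance) a short
  # per-trial baseline estimate would inject into every percent-change trace
  pc <- array(NA_real_, dim = c(n_trials, length(out_ms), n_ch))
  for (ch in seq_len(n_ch)) {
    rows <- (seq_len(n_trials) - 1) * n_ch + ch
    p_base <- mean(bp$power[rows, base_cols])
    for (tr in seq_len(n_trials)) {
      v <- 100 * (bp$power[rows[tr], ] - p_base) / p_base
      pc[tr, , ch] <- stats::approx(center_ms, v, xout = out_ms)$y
    }
  }
  structure(
    list(pc = pc, time_ms = out_ms, events = epochs$events,
         channels = epochs$channels, band = band, baseline_ms = baseline_ms),
    class = "highgamma_timecourse"
  )
}

#' Per-trial response/baseline power summaries
#'
#' Collapses high-gamma timecourses to one row per trial x electrode with
#' the mean relative band power (`P / Pbase`) in the baseline and response
#' windows -- the quantities the electrode inclusion test operates on.
#'
#' @param hg a `highgamma_timecourse`.
#' @param response_ms response window (default `c(0, 500)`).
#' @return data.frame `electrode`, `trial`, `condition`, `rel_base`,
#'   `rel_resp`.
#' @export
trial_power_summary <- function(hg, response_ms = c(0, 500)) {
  stopifnot(inherits(hg, "highgamma_timecourse"))
  t_resp <- hg$time_ms >= response_ms[1] & hg$time_ms <= response_ms[2]
  t_base <- hg$time_ms >= hg$baseline_ms[1] & hg$time_ms <= hg$baseline_ms[2]
  n_trials <- dim(hg$pc)[1]
  n_ch <- dim(hg$pc)[3]
  do.call(rbind, lapply(seq_len(n_ch), function(ch) {
    data.frame(
      electrode = hg$channels$id[ch],
      trial = seq_len(n_trials),
      condition = hg$events$condition,
      rel_base = 1 + rowMeans(hg$pc[, t_base, ch, drop = FALSE], dims = 1) / 100,
      rel_resp = 1 + rowMeans(hg$pc[, t_resp, ch, drop = FALSE], dims = 1) / 100,
      stringsAsFactors = FALSE
    )
  }))
}

#' Select electrodes with significant high-gamma responses
#'
#' Inclusion test: per electrode, a paired t-test across trials of
#' log response-window band power against log baseline-window band power
#' (log stabilizes the variance of power estimates). Electrodes with
#' `p < alpha` are included.
#'
#' @param trial_power data.frame from [trial_power_summary()] (columns
#'   `electrode`, `rel_base`, `rel_resp`).
#' @param alpha inclusion threshold (default 1e-3).
#' @return data.frame `electrode`, `t`, `df`, `p`, `included`.
#' @export
select_responsive_electrodes <- function(trial_power, alpha = 1e-3) {
  stopifnot(all(c("electrode", "rel_base", "rel_resp") %in% names(trial_power)))
  diffs_all <- log(pmax(trial_power$rel_resp, 1e-12)) -
    log(pmax(trial_power$rel_base, 1e-12))
  groups <- split(diffs_all, trial_power$electrode)
  # keep first-appearance order of electrode ids
  groups <- groups[unique(as.character(trial_power$electrode))]
  n <- lengths(groups)
  if (any(n < 2)) stopf("electrode %s has fewer than 2 trials",
                        names(groups)[which(n < 2)[1]])
  m <- vapply(groups, mean, numeric(1))
  s <- vapply(groups, stats::sd, numeric(1))
  tval <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  data.frame(electrode = names(groups), t = unname(tval), df = unname(n - 1),
             p = unname(p), included = unname(p < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clear-vs-noisy condition contrast for one electrode
#'
#' Pools the two auditory-clear conditions against the two auditory-noisy
#' conditions and compares per-trial response-window percent change with a
#' Welch (unequal-variance) two-sample t-test, Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param hg a `highgamma_timecourse`.
#' @param electrode electrode id (row of `hg$channels`).
#' @param response_ms response window (default `c(0, 500)`).
#' @return Object of class `electrode_contrast`: per-group means and SEMs,
#'   `t`, `df`, `p`, trial counts.
#' @export
electrode_condition_contrast <- function(hg, electrode, response_ms = c(0, 500)) {
  stopifnot(inherits(hg, "highgamma_timecourse"))
  ch <- match(electrode, hg$channels$id)
  if (is.na(ch)) stopf("unknown electrode '%s'", electrode)
  t_resp <- hg$time_ms >= response_ms[1] & hg$time_ms <= response_ms[2]
  resp <- rowMeans(hg$pc[, t_resp, ch, drop = FALSE], dims = 1)
  grp <- auditory_of(hg$events$condition)
  clear <- resp[grp == "clear"]
  noisy <- resp[grp == "noisy"]
  if (length(clear) < 2 || length(noisy) < 2)
    stopf("need >= 2 trials in each pooled auditory group")
  wt <- stats::t.test(clear, noisy, var.equal = FALSE)
  structure(
    list(electrode = electrode,
         mean_clear = mean(clear), sem_clear = stats::sd(clear) / sqrt(length(clear)),
         mean_noisy = mean(noisy), sem_noisy = stats::sd(noisy) / sqrt(length(noisy)),
         n_clear = length(clear), n_noisy = length(noisy),
         t = unname(wt$statistic), df = unname(wt$parameter), p = wt$p.value),
    class = "electrode_contrast"
  )
}

#' @export
print.electrode_contrast <- function(x, ...) {
  cat(sprintf(
    "<electrode_contrast> %s: clear %.1f%% +/- %.1f, noisy %.1f%% +/- %.1f, t(%.1f) = %+.2f, p = %.2g\n",
    x$electrode, x$mean_clear, x$sem_clear, x$mean_noisy, x$sem_noisy,
    x$df, x$t, x$p))
  invisible(x)
}

#' Preprocess and quantify an ECoG recording end to end
#'
#' Convenience chain: common average reference, line-noise removal, epoching,
#' multitaper high-gamma percent change.
#'
#' @param recording an `ecog_recording`.
#' @param window_ms epoch window.
#' @param ... passed to [multitaper_highgamma()].
#' @return a `highgamma_timecourse`.
#' @export
ecog_highgamma_pipeline <- function(recording, window_ms = c(-700, 800), ...) {
  rec <- common_average_reference(recording)
  rec <- remove_line_noise(rec)
  ep <- epoch_trials(rec, window_ms = window_ms)
  multitaper_highgamma(ep, ...)
}
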