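#' Default simulation parameters
#'
#' Bundles the generating amplitudes, noise levels and behavioral accuracies
#' of the synthetic study. Anterior electrodes prefer clear auditory speech
#' (peak high-gamma 300% vs 110%); posterior electrodes prefer noisy speech
#' (110% vs 190%, a fixture choice: posterior per-condition amplitudes are
#' only known at the level of "noisy > clear"). BOLD amplitudes follow the
#' same geometry at percent-signal scale (anterior 0.37/0.24, posterior
#' 0.33/0.40). The clear-minus-noisy difference of every profile crosses zero
#' exactly at the gyrus model's `true_boundary_mm`.
#'
#' @param ecog_amp named list of per-condition peak percent-change amplitudes
#'   for `anterior` and `posterior` (each a vector `clear`, `noisy`).
#' @param bold_amp same structure in % signal change.
#' @param transition_width_mm width of the sigmoidal anterior-to-posterior
#'   profile (default 4 mm: the contrast flips within ~10 mm).
#' @param ecog_noise list: `pink` (background scale, arbitrary units), `line`
#'   (60 Hz amplitude), `carrier` (baseline within-band RMS).
#' @param bold_noise list: `ar1` (AR(1) coefficient), `sd` (innovation SD, %
#'   signal), `drift` (max quadratic drift excursion, % signal), `motion_sd`
#'   (motion regressor scale), `motion_leak` (% signal per motion unit).
#' @param accuracies per-condition probability of a correct word report
#'   (clear conditions 0.99; noisy 0.87 with clear visual, 0.69 with blurred).
#' @param baseline_intensity raw scanner intensity about which BOLD
#'   fluctuates (default 1000; removed again by percent-signal scaling).
#' @return list of class `sim_params`.
#' @export
default_sim_params <- function(
    ecog_amp = list(anterior = c(clear = 300, noisy = 110),
                    posterior = c(clear = 110, noisy = 190)),
    bold_amp = list(anterior = c(clear = 0.37, noisy = 0.24),
                    posterior = c(clear = 0.33, noisy = 0.40)),
    transition_width_mm = 4,
    ecog_noise = list(pink = 1, line = 2, carrier = 1),
    bold_noise = list(ar1 = 0.3, sd = 0.5, drift = 0.6,
                      motion_sd = 0.05, motion_leak = 0.2),
    accuracies = c(AclearVclear = 0.99, AclearVblur = 0.99,
                   AnoisyVclear = 0.87, AnoisyVblur = 0.69),
    baseline_intensity = 1000) {
  stopifnot(all(unlist(ecog_amp) >= 0), all(unlist(bold_amp) >= 0))
  if (transition_width_mm <= 0) stopf("transition_width_mm must be positive")
  if (any(accuracies < 0 | accuracies > 1)) stopf("accuracies must be in [0,1]")
  structure(
    list(ecog_amp = ecog_amp, bold_amp = bold_amp,
         transition_width_mm = transition_width_mm,
         ecog_noise = ecog_noise, bold_noise = bold_noise,
         accuracies = accuracies, baseline_intensity = baseline_intensity),
    class = "sim_params"
  )
}

#' Per-condition response amplitude along the strip
#'
#' Each condition's amplitude interpolates between its anterior and posterior
#' values through a logistic transition. The logistic center is placed so
#' that the clear-minus-noisy difference crosses zero exactly at
#' `gyrus$true_boundary_mm` (the center itself is offset from the boundary
#' whenever the anterior and posterior difference magnitudes are unequal).
#'
#' @param position_mm positions along the strip.
#' @param gyrus a `gyrus_model`.
#' @param amp list with `anterior` and `posterior` named vectors
#'   (`clear`, `noisy`).
#' @param width_mm transition width.
#' @param condition condition label (auditory component selects the
#'   amplitude pair).
#' @return numeric amplitudes.
#' @export
amplitude_profile <- function(position_mm, gyrus, amp, width_mm, condition) {
  aud <- auditory_of(condition)
  d_ant <- amp$anterior[["clear"]] - amp$anterior[["noisy"]]
  d_post <- amp$posterior[["clear"]] - amp$posterior[["noisy"]]
  if (d_ant <= 0 || d_post >= 0)
    stopf("profiles must prefer clear anteriorly and noisy posteriorly")
  s_star <- -d_post / (d_ant - d_post)      # anterior weight at the boundary
  center <- gyrus$true_boundary_mm -
    width_mm * log((1 - s_star) / s_star)
  s <- 1 / (1 + exp((position_mm - center) / width_mm))  # 1 anterior, 0 posterior
  amp$posterior[[aud]] + (amp$anterior[[aud]] - amp$posterior[[aud]]) * s
}

# Sustained high-gamma burst envelope: silent for the first 100 ms after
# auditory onset, raised-cosine rise to 1 at 200 ms, plateau through 1.0 s,
# raised-cosine decay to 0 at 1.4 s.
burst_envelope <- function(t_s, latency_s = 0.1, peak_s = 0.2,
                           plateau_end_s = 1.0, off_s = 1.4) {
  e <- numeric(length(t_s))
  rise <- t_s > latency_s & t_s < peak_s
  e[rise] <- 0.5 * (1 - cos(pi * (t_s[rise] - latency_s) / (peak_s - latency_s)))
  e[t_s >= peak_s & t_s <= plateau_end_s] <- 1
  fall <- t_s > plateau_end_s & t_s < off_s
  e[fall] <- 0.5 * (1 + cos(pi * (t_s[fall] - plateau_end_s) / (off_s - plateau_end_s)))
  e
}

# Band-limited Gaussian noise via frequency-domain masking, normalized to a
# target RMS. Computed at a power-of-two length and truncated (FFTs at
# arbitrary lengths with large prime factors are prohibitively slow).
band_noise <- function(n, fs, band, rms) {
  m <- stats::nextn(n, 2)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)   # two-sided frequency axis
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y * rms / stats::sd(y)
}

# Pink (1/f amplitude) background with the high-gamma band notched out, so
# that within-band power is carried entirely by the modulated carrier.
pink_noise_notched <- function(n, fs, scale, notch = c(65, 115)) {
  if (scale <= 0) return(numeric(n))
  m <- stats::nextn(n, 2)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  w <- 1 / sqrt(pmax(f, 1))
  w[f >= notch[1] & f <= notch[2]] <- 0
  y <- Re(stats::fft(X * w, inverse = TRUE))[seq_len(n)] / m
  if (stats::sd(y) == 0) return(numeric(n))
  y * scale / stats::sd(y)
}

#' Simulate a multichannel ECoG recording with planted high-gamma responses
#'
#' Each electrode carries a band-limited (70-110 Hz) carrier of fixed
#' baseline power. On every trial the carrier is gain-modulated so that its
#' instantaneous band power exceeds baseline by exactly
#' `amplitude x envelope(t)` percent, where the amplitude depends on the
#' condition and on the electrode's position relative to the planted
#' boundary (sigmoidal profile), and the envelope rises within 100-200 ms of
#' auditory onset and is sustained through the word. Background pink noise
#' (notched over the high-gamma band) and a 60 Hz line component are added.
#'
#' @param gyrus a `gyrus_model`.
#' @param electrode_positions positions (mm) of the electrodes on the strip.
#' @param n_trials_per_condition trials per condition (default 40).
#' @param params a `sim_params` list.
#' @param seed RNG seed; the recording is a deterministic function of it.
#' @param sample_rate_hz sampling rate (default 2000).
#' @param iti_s mean inter-trial interval (default 3.5 s).
#' @param n_reference_channels additional off-strip channels with background
#'   activity but no speech response (default 24). Real arrays reference
#'   against the whole grid, not just the STG electrodes; with too few
#'   channels the common average would subtract an appreciable fraction of
#'   each electrode's own signal.
#' @return Object of class `ecog_recording`: `sample_rate_hz`, `channels`
#'   (data.frame `id`, `position_mm`, `on_strip`; off-strip reference
#'   channels have `position_mm = NA`), `samples` (channels x time matrix),
#'   `events` (data.frame `onset_s`, `condition`), `gyrus`.
#' @export
simulate_ecog <- function(gyrus, electrode_positions,
                          n_trials_per_condition = 40,
                          params = default_sim_params(),
                          seed = 1L,
                          sample_rate_hz = 2000,
                          iti_s = 3.5,
                          n_reference_channels = 24) {
  stopifnot(inherits(gyrus, "gyrus_model"))
  if (any(electrode_positions < 0 | electrode_positions > gyrus$length_mm))
    stopf("electrode position off the strip")
  if (n_trials_per_condition < 0) stopf("negative trial count")
  fs <- sample_rate_hz
  n_strip <- length(electrode_positions)
  n_ch <- n_strip + n_reference_channels

  with_seed(seed, {
    n_trials <- 4L * n_trials_per_condition
    conds <- if (n_trials > 0) sample(rep(condition_levels(), n_trials_per_condition))
             else character()
    gaps <- if (n_trials > 0) stats::runif(n_trials, iti_s - 0.25, iti_s + 0.25) else numeric()
    onsets <- 2 + cumsum(c(0, gaps))[seq_len(n_trials)]
    dur_s <- if (n_trials > 0) max(onsets) + 3 else 10
    n <- ceiling(dur_s * fs)
    t_rec <- (seq_len(n) - 1) / fs

    # line interference is common-mode across the array (shared phase)
    line_phase <- stats::runif(1, 0, 2 * pi)
    line <- params$ecog_noise$line * sin(2 * pi * 60 * t_rec + line_phase)

    samples <- matrix(0, nrow = n_ch, ncol = n)
    for (ch in seq_len(n_ch)) {
      on_strip <- ch <= n_strip
      carrier <- band_noise(n, fs, c(70, 110), rms = params$ecog_noise$carrier)
      if (on_strip) {
        pos <- electrode_positions[ch]
        pc <- numeric(n)   # planted percent-change in band power
        for (k in seq_along(onsets)) {
          amp <- amplitude_profile(pos, gyrus, params$ecog_amp,
                                   params$transition_width_mm, conds[k])
          i0 <- floor(onsets[k] * fs) + 1
          i1 <- min(n, ceiling((onsets[k] + 1.5) * fs))
          idx <- i0:i1
          pc[idx] <- pc[idx] + amp * burst_envelope(t_rec[idx] - onsets[k])
        }
        carrier <- carrier * sqrt(1 + pc / 100)
      }
      bg <- pink_noise_notched(n, fs, params$ecog_noise$pink)
      samples[ch, ] <- carrier + bg + line
    }

    structure(
      list(
        sample_rate_hz = fs,
        channels = data.frame(
          id = sprintf("E%02d", seq_len(n_ch)),
          position_mm = c(electrode_positions,
                          rep(NA_real_, n_reference_channels)),
          on_strip = c(rep(TRUE, n_strip), rep(FALSE, n_reference_channels)),
          stringsAsFactors = FALSE),
        samples = samples,
        events = data.frame(onset_s = onsets, condition = conds,
                            stringsAsFactors = FALSE),
        gyrus = gyrus
      ),
      class = "ecog_recording"
    )
  })
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              nrow(x$events)))
  invisible(x)
}
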