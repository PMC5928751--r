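test_that("common average reference equals the brute-force row-mean subtraction", {
  set.seed(1)
  x <- matrix(rnorm(4 * 100), 4, 100)
  rec <- list(samples = x, sample_rate_hz = 1000)
  out <- common_average_reference(rec)$samples
  expect_equal(out, sweep(x, 2, colMeans(x)), tolerance = 1e-12)
  # identical channels are zeroed; an antisymmetric pair is untouched
  same <- list(samples = rbind(x[1, ], x[1, ]), sample_rate_hz = 1000)
  expect_equal(max(abs(common_average_reference(same)$samples)), 0)
  anti <- list(samples = rbind(x[1, ], -x[1, ]), sample_rate_hz = 1000)
  expect_equal(common_average_reference(anti)$samples, anti$samples)
  one <- list(samples = x[1, , drop = FALSE], sample_rate_hz = 1000)
  expect_error(common_average_reference(one), "2 channels")
})

test_that("line-noise removal attenuates 60 Hz >= 20 dB and spares the band", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  tone <- 3 * sin(2 * pi * 60 * t + 1)
  rec <- list(samples = rbind(tone, tone * 0.5), sample_rate_hz = fs)
  out <- remove_line_noise(rec)$samples
  p_before <- oracle_band_power(tone, fs, c(59, 61))
  p_after <- oracle_band_power(out[1, ], fs, c(59, 61))
  expect_lt(10 * log10(p_after / p_before), -20)
  # DC input is untouched (orthogonal to the line basis)
  dc <- list(samples = matrix(2, 2, fs), sample_rate_hz = fs)
  expect_equal(remove_line_noise(dc)$samples, dc$samples, tolerance = 1e-10)
  # white-noise high-gamma band power changes < 5%
  set.seed(2)
  wn <- matrix(rnorm(2 * 4 * fs), 2)
  rec <- list(samples = wn, sample_rate_hz = fs)
  out <- remove_line_noise(rec)$samples
  for (ch in 1:2) {
    p0 <- oracle_band_power(wn[ch, ], fs, c(70, 110))
    p1 <- oracle_band_power(out[ch, ], fs, c(70, 110))
    expect_lt(abs(p1 - p0) / p0, 0.05)
  }
  expect_error(remove_line_noise(list(samples = wn, sample_rate_hz = 100)),
               "Nyquist")
})

test_that("epoching slices the recording exactly and drops edge events", {
  fs <- 1000
  set.seed(3)
  samples <- matrix(rnorm(2 * 10 * fs), 2)
  events <- data.frame(onset_s = c(0.0, 2, 3.5, 9.9),
                       condition = c("AclearVclear", "AclearVblur",
                                     "AnoisyVclear", "AnoisyVblur"))
  rec <- list(samples = samples, sample_rate_hz = fs, events = events,
              channels = data.frame(id = c("E01", "E02")))
  expect_message(ep <- epoch_trials(rec, window_ms = c(-700, 800)), "dropped 2")
  expect_length(ep$epochs, 2)
  expect_equal(ep$events$onset_s, c(2, 3.5))
  # direct-indexing oracle for the second kept epoch
  i0 <- round(3.5 * fs) + 1
  expect_equal(ep$epochs[[2]],
               samples[, (i0 - 700):(i0 + 800), drop = FALSE])
  expect_equal(ep$time_ms, -700:800)
})

test_that("multitaper percent change tracks an analytic amplitude step", {
  # a 90 Hz tone whose amplitude doubles in the response window: band power
  # quadruples, percent change +300% at the plateau
  fs <- 2000
  n_trials <- 6
  onsets <- 2 + (0:(n_trials - 1)) * 3
  t <- (0:((max(onsets) + 2) * fs - 1)) / fs
  gain <- rep(1, length(t))
  for (o in onsets) gain[t >= o + 0.2 & t <= o + 1.0] <- 2
  sig <- gain * sin(2 * pi * 90 * t)
  rec <- list(samples = rbind(sig, sig), sample_rate_hz = fs,
              events = data.frame(onset_s = onsets,
                                  condition = rep("AclearVclear", n_trials)),
              channels = data.frame(id = c("E01", "E02")))
  hg <- multitaper_highgamma(epoch_trials(rec))
  plateau <- hg$time_ms >= 350 & hg$time_ms <= 850
  m <- colMeans(hg$pc[, , 1])
  expect_equal(mean(m[plateau]), 300, tolerance = 0.02)
  # baseline percent change is ~0 by construction
  base <- hg$time_ms >= -500 & hg$time_ms <= -100
  expect_lt(abs(mean(m[base])), 2)
})

test_that("stationary noise yields near-zero percent change", {
  fs <- 2000
  set.seed(4)
  onsets <- 2 + (0:9) * 2.5
  n <- (max(onsets) + 2) * fs
  rec <- list(samples = matrix(rnorm(2 * n), 2), sample_rate_hz = fs,
              events = data.frame(onset_s = onsets,
                                  condition = rep("AnoisyVblur", 10)),
              channels = data.frame(id = c("E01", "E02")))
  hg <- multitaper_highgamma(epoch_trials(rec))
  resp <- hg$time_ms >= 0 & hg$time_ms <= 500
  expect_lt(abs(mean(hg$pc[, resp, 1])), 5)
})

test_that("pipeline is (power-)linear: amplitude scaling maps percent change as a^2", {
  # scaling the band-limited component by a maps (100 + pc) to a^2 (100 + pc)
  fs <- 2000
  n_trials <- 6
  onsets <- 2 + (0:(n_trials - 1)) * 3
  t <- (0:((max(onsets) + 2) * fs - 1)) / fs
  gain <- rep(1, length(t))
  for (o in onsets) gain[t >= o + 0.2 & t <= o + 1.0] <- 1.5
  base_sig <- sin(2 * pi * 88 * t)
  a <- 2
  mk <- function(scale_resp) {
    g2 <- 1 + (gain - 1) * scale_resp
    list(samples = rbind(base_sig * g2, base_sig * g2), sample_rate_hz = fs,
         events = data.frame(onset_s = onsets,
                             condition = rep("AclearVclear", n_trials)),
         channels = data.frame(id = c("E01", "E02")))
  }
  hg1 <- multitaper_highgamma(epoch_trials(mk(1)))
  hg2 <- multitaper_highgamma(epoch_trials(mk(a)))
  plateau <- hg1$time_ms >= 350 & hg1$time_ms <= 850
  pc1 <- mean(colMeans(hg1$pc[, , 1])[plateau])   # (1.5^2-1)*100 = 125
  pc2 <- mean(colMeans(hg2$pc[, , 1])[plateau])   # (2^2-1)*100 = 300
  expect_equal(pc1, 125, tolerance = 0.02)
  expect_equal(pc2, 300, tolerance = 0.02)
})

test_that("planted condition amplitudes are recovered from a noiseless recording", {
  fx <- small_ecog_noiseless()
  hg <- fx$hg
  plateau <- hg$time_ms >= 300 & hg$time_ms <= 700
  for (ch in 1:2) {
    pos <- fx$rec$channels$position_mm[ch]
    for (aud in c("clear", "noisy")) {
      truth <- amplitude_profile(pos, fx$gyrus, default_sim_params()$ecog_amp,
                                 4, if (aud == "clear") "AclearVclear" else "AnoisyVclear")
      tr <- auditory_of(hg$events$condition) == aud
      est <- mean(colMeans(hg$pc[tr, , ch])[plateau])
      # tolerance reflects carrier-power sampling noise at 40 trials/group
      expect_equal(est, truth, tolerance = 0.15)
    }
  }
})

test_that("electrode selection includes strong responders and spares null channels", {
  fx <- small_ecog_noiseless()
  g <- fx$gyrus
  rec <- simulate_ecog(g, c(45, 90), n_trials_per_condition = 10, seed = 41,
                       n_reference_channels = 2)
  hg <- multitaper_highgamma(epoch_trials(rec))
  sel <- select_responsive_electrodes(trial_power_summary(hg))
  expect_true(all(sel$included[sel$electrode %in% c("E01", "E02")]))
  expect_false(any(sel$included[sel$electrode %in% c("E03", "E04")]))
  expect_error(select_responsive_electrodes(
    data.frame(electrode = "E01", rel_base = 1, rel_resp = 2)), "fewer than 2")
})

test_that("condition contrast matches the direct Welch formula", {
  fx <- small_ecog_noiseless()
  ec <- electrode_condition_contrast(fx$hg, "E01")
  hg <- fx$hg
  t_resp <- hg$time_ms >= 0 & hg$time_ms <= 500
  resp <- rowMeans(hg$pc[, t_resp, 1])
  clear <- resp[auditory_of(hg$events$condition) == "clear"]
  noisy <- resp[auditory_of(hg$events$condition) == "noisy"]
  se2 <- var(clear) / length(clear) + var(noisy) / length(noisy)
  t_direct <- (mean(clear) - mean(noisy)) / sqrt(se2)
  df_direct <- se2^2 / ((var(clear) / length(clear))^2 / (length(clear) - 1) +
                          (var(noisy) / length(noisy))^2 / (length(noisy) - 1))
  expect_equal(ec$t, t_direct, tolerance = 1e-10)
  expect_equal(ec$df, df_direct, tolerance = 1e-10)
  expect_gt(ec$t, 0)
  expect_equal(ec$mean_clear, mean(clear))
  expect_equal(ec$sem_clear, sd(clear) / sqrt(length(clear)))
})

test_that("Welch t on the reported summary statistics reproduces the printed contrast", {
  # means 138 vs 49 with SEMs 13 and 5 give t = 89/sqrt(13^2+5^2) = 6.39;
  # the printed value (6.2) came from unrounded data
  t_summary <- (138 - 49) / sqrt(13^2 + 5^2)
  expect_equal(t_summary, 6.39, tolerance = 0.001)
  expect_equal(t_summary, 6.2, tolerance = 0.05)
})
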