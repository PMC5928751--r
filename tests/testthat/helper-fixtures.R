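# Shared in-code fixtures. Everything is generated at test time; the heavier
# objects are built once per test run and reused across test files.

noiseless_params <- function() {
  default_sim_params(
    ecog_noise = list(pink = 0, line = 0, carrier = 1),
    bold_noise = list(ar1 = 0, sd = 0, drift = 0, motion_sd = 0.05,
                      motion_leak = 0)
  )
}

# small noiseless BOLD session + schedule, shared
fixture_env <- new.env()

small_bold_noiseless <- function() {
  if (is.null(fixture_env$bold0)) {
    g <- make_gyrus()
    sched <- make_event_schedule(n_runs = 2, seed = 11)
    fixture_env$bold0 <- list(
      gyrus = g, sched = sched,
      ses = simulate_bold(g, sched, params = noiseless_params(), seed = 12,
                          n_off_gyrus = 4)
    )
  }
  fixture_env$bold0
}

small_bold_noisy <- function() {
  if (is.null(fixture_env$bold1)) {
    g <- make_gyrus()
    sched <- make_event_schedule(n_runs = 2, seed = 21)
    fixture_env$bold1 <- list(
      gyrus = g, sched = sched,
      ses = simulate_bold(g, sched, seed = 22, n_off_gyrus = 4)
    )
  }
  fixture_env$bold1
}

# two-electrode noiseless ECoG recording (anterior + posterior), analyzed
small_ecog_noiseless <- function() {
  if (is.null(fixture_env$ecog0)) {
    g <- make_gyrus()
    rec <- simulate_ecog(g, c(45, 90), n_trials_per_condition = 20,
                         params = noiseless_params(), seed = 31,
                         n_reference_channels = 0)
    fixture_env$ecog0 <- list(gyrus = g, rec = rec,
                              hg = multitaper_highgamma(epoch_trials(rec)))
  }
  fixture_env$ecog0
}

# direct (independent-path) multitaper band-power estimate used as an oracle:
# plain periodogram power in a window, no taper machinery shared with the
# implementation
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  mean(sp[f >= band[1] & f <= band[2]])
}
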