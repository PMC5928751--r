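#' Randomized rapid event-related schedule
#'
#' Builds the trial schedule of the audiovisual word experiment: each run
#' holds `volumes_per_run` volumes at `tr_s` seconds per volume, and
#' `trials_per_condition_per_run` trials of each of the four audiovisual
#' conditions, each trial `trial_duration_s` long. Trial onsets fall on the
#' TR lattice; trials never overlap and all end before the run does. The
#' remaining time is fixation baseline (96 s per run at the defaults).
#'
#' Onsets are randomized by shuffling trial blocks and single-TR baseline
#' fillers, a simple stand-in for an optimized event-related schedule.
#'
#' @param n_runs number of runs (default 5).
#' @param trials_per_condition_per_run trials of each condition per run
#'   (default 12; 48 trials/run, 60 repetitions of each condition in total).
#' @param tr_s repetition time in seconds (default 1.5).
#' @param volumes_per_run volumes per run (default 160).
#' @param trial_duration_s trial duration in seconds (default 3).
#' @param seed RNG seed for the randomized ordering.
#' @return An object of class `event_schedule`: list with `trials` (data.frame
#'   `run`, `onset_s`, `duration_s`, `condition`), `tr_s`, `volumes_per_run`,
#'   `n_runs`, `run_duration_s`, `baseline_s_per_run`.
#' @examples
#' sched <- make_event_schedule(seed = 1)
#' table(sched$trials$condition)  # 60 of each
#' sched$baseline_s_per_run      # 96
#' @export
make_event_schedule <- function(n_runs = 5,
                                trials_per_condition_per_run = 12,
                                tr_s = 1.5,
                                volumes_per_run = 160,
                                trial_duration_s = 3,
                                seed = 1L) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  if (trials_per_condition_per_run < 0) stopf("negative trial count")
  if (trial_duration_s %% tr_s != 0)
    stopf("trial_duration_s must be a multiple of tr_s (onsets lie on the TR lattice)")
  conds <- condition_levels()
  n_trials <- 4L * trials_per_condition_per_run
  trial_trs <- as.integer(round(trial_duration_s / tr_s))
  run_trs <- as.integer(volumes_per_run)
  filler_trs <- run_trs - n_trials * trial_trs
  if (filler_trs < 0)
    stopf("infeasible packing: %d trials x %g s exceed the %g s run",
          n_trials, trial_duration_s, run_trs * tr_s)
  run_duration_s <- run_trs * tr_s

  trials <- with_seed(seed, {
    out <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      items <- c(rep(conds, each = trials_per_condition_per_run),
                 rep(NA_character_, filler_trs))
      items <- sample(items)
      durs <- ifelse(is.na(items), 1L, trial_trs)
      starts <- cumsum(c(0L, durs[-length(durs)]))
      keep <- !is.na(items)
      out[[r]] <- data.frame(
        run = rep(r, sum(keep)),
        onset_s = starts[keep] * tr_s,
        duration_s = rep(trial_duration_s, sum(keep)),
        condition = items[keep],
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  if (is.null(trials)) {
    trials <- data.frame(run = integer(), onset_s = numeric(),
                         duration_s = numeric(), condition = character())
  }
  trials <- trials[order(trials$run, trials$onset_s), , drop = FALSE]
  rownames(trials) <- NULL

  structure(
    list(
      trials = trials,
      tr_s = tr_s,
      volumes_per_run = run_trs,
      n_runs = n_runs,
      run_duration_s = run_duration_s,
      baseline_s_per_run = run_duration_s - n_trials * trial_duration_s
    ),
    class = "event_schedule"
  )
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> %d run(s) x %d volumes @ TR %g s, %d trials, %g s baseline/run\n",
              x$n_runs, x$volumes_per_run, x$tr_s, nrow(x$trials),
              x$baseline_s_per_run))
  invisible(x)
}

#' Write / read a BIDS-style events table
#'
#' Columns `onset`, `duration`, `trial_type` (plus `run`), tab-separated.
#'
#' @param schedule an `event_schedule`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- data.frame(onset = schedule$trials$onset_s,
                   duration = schedule$trials$duration_s,
                   trial_type = schedule$trials$condition,
                   run = schedule$trials$run)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
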