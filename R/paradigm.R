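#' Event-related fingertip stimulation paradigms
#'
#' Generates randomized event-related (ER) runs of vibrotactile fingertip
#' stimulation: 30 trials per run (6 per fingertip), trial onsets synchronized
#' to volume acquisitions, inter-trial intervals drawn uniformly from
#' 4--12 s in 2 s steps, and trial order constrained so that each fingertip
#' occurs exactly once in every successive block of five trials.
#'
#' Sub-seeds: run `r` uses `seed + r - 1` so different runs differ but the
#' whole set is reproducible from the master seed.
#'
#' @param n_runs number of runs to generate.
#' @param seed master RNG seed.
#' @param tr_s volume repetition time in seconds.
#' @param n_trials_per_finger trials per fingertip per run.
#' @param iti_choices_s admissible inter-trial intervals (onset-to-onset), s.
#' @param tail_s quiet period appended after the last onset so the final
#'   response is sampled.
#' @return A list of `paradigm_er` objects, each with an `events` data frame
#'   (`onset_s`, `duration_s`, `finger`), `run_duration_s`, `tr_s` and
#'   `trial_model_duration_s`.
#' @export
make_er_paradigm <- function(n_runs = 1L, seed = 1L, tr_s = 2,
                             n_trials_per_finger = 6L,
                             iti_choices_s = c(4, 6, 8, 10, 12),
                             tail_s = 20) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  lapply(seq_len(n_runs), function(r) {
    set.seed(as.integer(seed) + r - 1L)
    fingers <- unlist(lapply(seq_len(n_trials_per_finger),
                             function(b) sample(1:5)))
    n_trials <- length(fingers)
    itis <- sample(iti_choices_s, n_trials - 1L, replace = TRUE)
    onsets <- cumsum(c(0, itis))
    run_duration <- ceiling((onsets[n_trials] + tail_s) / tr_s) * tr_s
    structure(list(
      events = data.frame(onset_s = onsets, duration_s = 1, finger = fingers),
      run_duration_s = run_duration,
      tr_s = tr_s,
      trial_model_duration_s = 1,
      seed = as.integer(seed) + r - 1L
    ), class = "paradigm_er")
  })
}

#' Validate an event-related paradigm
#'
#' Independent check of the ER design invariants: trial count, per-finger
#' balance, onset/volume synchrony, admissible inter-trial intervals, and the
#' block-of-five constraint (each finger exactly once per successive block).
#'
#' @param paradigm a `paradigm_er` object.
#' @param iti_choices_s admissible intervals.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_er_paradigm <- function(paradigm, iti_choices_s = c(4, 6, 8, 10, 12)) {
  ev <- paradigm$events
  if (nrow(ev) != 30L) stop("expected 30 events, got ", nrow(ev))
  tab <- table(factor(ev$finger, levels = 1:5))
  if (any(tab != 6L)) stop("each finger must occur exactly 6 times")
  if (any(ev$onset_s %% paradigm$tr_s != 0))
    stop("onsets must be multiples of tr_s")
  itis <- diff(ev$onset_s)
  if (!all(itis %in% iti_choices_s))
    stop("inter-trial interval outside the admissible set")
  for (b in seq_len(nrow(ev) %/% 5L)) {
    blk <- ev$finger[(5L * (b - 1L) + 1L):(5L * b)]
    if (!setequal(blk, 1:5))
      stop("block ", b, " is not a permutation of fingers 1..5")
  }
  invisible(TRUE)
}

#' Cyclic phase-encoding (traveling-wave) paradigm
#'
#' Builds the periodic localizer schedule: within each cycle the five
#' fingertips are stimulated in equal contiguous epochs, in order 1 to 5
#' (`forward`) or 5 to 1 (`reverse`, the exact time-mirror of forward within
#' each cycle). The stimulation frequency equals the number of cycles per run.
#'
#' @param cycle_period_s duration of one cycle; must be divisible by five
#'   epochs on the TR grid.
#' @param n_cycles number of cycles per run.
#' @param direction `"forward"` or `"reverse"`.
#' @param tr_s repetition time in seconds.
#' @return A `paradigm_pe` object with an `epochs` data frame
#'   (`onset_s`, `duration_s`, `finger`), `cycle_period_s`, `n_cycles`,
#'   `direction`, `run_duration_s` and `stim_freq_cycles_per_run`.
#' @export
make_pe_paradigm <- function(cycle_period_s = 40, n_cycles = 8,
                             direction = c("forward", "reverse"), tr_s = 2) {
  direction <- match.arg(direction)
  epoch <- cycle_period_s / 5
  if (cycle_period_s %% (5 * tr_s) != 0)
    stop("cycle_period_s must be divisible by 5 epochs on the TR grid")
  order_in_cycle <- if (direction == "forward") 1:5 else 5:1
  onsets <- rep((seq_len(n_cycles) - 1L) * cycle_period_s, each = 5L) +
    rep((0:4) * epoch, times = n_cycles)
  structure(list(
    epochs = data.frame(onset_s = onsets, duration_s = epoch,
                        finger = rep(order_in_cycle, times = n_cycles)),
    cycle_period_s = cycle_period_s,
    n_cycles = as.integer(n_cycles),
    direction = direction,
    tr_s = tr_s,
    run_duration_s = cycle_period_s * n_cycles,
    stim_freq_cycles_per_run = as.integer(n_cycles)
  ), class = "paradigm_pe")
}

#' Noise specification for BOLD simulation
#'
#' @param sigma marginal noise standard deviation in percent-signal units.
#' @param ar1_rho lag-1 autocorrelation of the AR(1) noise, in `[0, 1)`.
#' @param drift_amplitude amplitude of the slow sinusoidal drift (percent).
#' @param drift_period_s drift period; the default 128 s lies below the
#'   0.01 Hz high-pass cut-off so the filter stage can be tested for removal.
#' @param seed RNG seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma = 0.4, ar1_rho = 0.3, drift_amplitude = 1,
                       drift_period_s = 128, seed = 1L) {
  if (abs(ar1_rho) >= 1) stop("stationary AR(1) requires |ar1_rho| < 1")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, seed = as.integer(seed)),
            class = "noise_spec")
}
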