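# Forward BOLD model: linear convolution of the stimulus trains with a shared
# HRF, weighted per voxel by fingertip tuning, on a baseline of 100 so raw
# units convert trivially to percent signal.

#' Construct a BOLD run container
#'
#' @param data voxel x time numeric matrix.
#' @param grid_shape voxel counts per axis (prod = nrow(data)).
#' @param tr_s repetition time, seconds.
#' @param units `"raw"` or `"percent"`.
#' @param voxel_size_mm voxel edge lengths, mm.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, grid_shape, tr_s = 2, units = "raw",
                     voxel_size_mm = 1.5) {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("time dimension must be >= 2")
  if (nrow(data) != prod(grid_shape))
    stop("data rows must equal prod(grid_shape)")
  structure(list(data = data, grid_shape = as.integer(grid_shape),
                 tr_s = tr_s, units = units,
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3L)),
            class = "bold_run")
}

#' Simulate a BOLD run from a phantom and a paradigm
#'
#' `signal(v, t) = amplitude * sum_f tuning(v, f) * (stim_f \%*\% hrf)(t)`
#' where the convolved single-trial response is scaled so that a voxel with
#' tuning 1 peaks at `amplitude_percent` percent of the baseline (100) for an
#' event-related trial. Stationary AR(1) noise (marginal SD `noise$sigma`, in
#' percent units) and a slow sinusoidal drift are added on top.
#'
#' @param phantom a [make_somatotopic_phantom()] object.
#' @param paradigm a `paradigm_er` or `paradigm_pe` object.
#' @param timing HRF timing used for the generator kernel.
#' @param noise a [noise_spec()]; the seed makes the run reproducible.
#' @param amplitude_percent peak single-trial response of a tuning-1 voxel.
#' @param baseline raw baseline signal level.
#' @param hrf_duration_s support of the generator HRF kernel in seconds.
#' @return A `bold_run` (units `"raw"`).
#' @export
simulate_bold <- function(phantom, paradigm, timing = hrf_timing(),
                          noise = noise_spec(), amplitude_percent = 2,
                          baseline = 100, hrf_duration_s = 32) {
  events <- if (inherits(paradigm, "paradigm_pe")) paradigm$epochs else paradigm$events
  tr_s <- paradigm$tr_s
  dt_s <- timing$dt_s
  n_vols <- round(paradigm$run_duration_s / tr_s)
  nvox <- prod(phantom$grid_shape)
  hrf <- double_gamma(timing, hrf_duration_s)

  # peak of a single modelled trial for unit tuning, used to set scale
  trial_dur <- if (inherits(paradigm, "paradigm_pe")) events$duration_s[1L] else
    paradigm$trial_model_duration_s
  one <- data.frame(onset_s = 0, duration_s = trial_dur, finger = 1L)
  s1 <- stim_vector(one, 1L, hrf_duration_s + trial_dur, dt_s)
  peak1 <- max(stats::convolve(s1, rev(hrf$values), type = "open") * dt_s)
  scale <- amplitude_percent / peak1

  S <- matrix(0, 5L, n_vols)
  for (f in 1:5) {
    s <- stim_vector(events, f, paradigm$run_duration_s, dt_s)
    S[f, ] <- convolve_sample(s, hrf$values, n_vols, tr_s, dt_s) * scale
  }
  pct <- phantom$tuning %*% S  # nvox x n_vols, percent units

  t_vol <- (seq_len(n_vols) - 1L) * tr_s
  drift <- noise$drift_amplitude *
    sin(2 * pi * t_vol / noise$drift_period_s)

  eps <- matrix(0, nvox, n_vols)
  if (noise$sigma > 0) {
    set.seed(noise$seed)
    innov_sd <- noise$sigma * sqrt(1 - noise$ar1_rho^2)
    e <- matrix(stats::rnorm(nvox * n_vols, sd = innov_sd), n_vols, nvox)
    if (noise$ar1_rho != 0) {
      e <- apply(e, 2L, function(col) {
        as.numeric(stats::filter(col, noise$ar1_rho, method = "recursive",
                                 init = stats::rnorm(1, sd = noise$sigma)))
      })
    }
    eps <- t(e)
  }

  raw <- baseline * (1 + (sweep(pct, 2L, drift, `+`) + eps) / 100)
  bold_run(raw, phantom$grid_shape, tr_s = tr_s, units = "raw",
           voxel_size_mm = phantom$voxel_size_mm[1L])
}
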