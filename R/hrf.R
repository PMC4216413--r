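#' Hemodynamic response timing parameters
#'
#' Container for the canonical double-gamma timing: times-to-peak of the
#' positive response and the negative undershoot, the undershoot amplitude
#' ratio, and the sampling step. Each gamma is parameterized with unit
#' dispersion (rate 1/s, shape `t_peak + 1`) so its mode falls exactly at the
#' requested time-to-peak.
#'
#' @param t_peak_pos_s time-to-peak of the positive gamma, seconds.
#' @param t_peak_neg_s time-to-peak of the negative (undershoot) gamma.
#' @param undershoot_ratio amplitude of the undershoot gamma relative to the
#'   positive gamma (conventional canonical value 1/6).
#' @param dt_s sampling step in seconds.
#' @return An `hrf_timing` object.
#' @export
hrf_timing <- function(t_peak_pos_s = 6, t_peak_neg_s = 16,
                       undershoot_ratio = 1 / 6, dt_s = 0.1) {
  if (!(t_peak_pos_s > 0 && t_peak_pos_s < t_peak_neg_s))
    stop("need 0 < t_peak_pos_s < t_peak_neg_s")
  if (undershoot_ratio < 0) stop("undershoot_ratio must be >= 0")
  if (dt_s <= 0) stop("dt_s must be positive")
  structure(list(t_peak_pos_s = t_peak_pos_s, t_peak_neg_s = t_peak_neg_s,
                 undershoot_ratio = undershoot_ratio, dt_s = dt_s),
            class = "hrf_timing")
}

#' Peak times of the double-gamma curve
#'
#' Numeric argmax and subsequent argmin of the curve on a fine grid. Because
#' of the undershoot trade-off these differ from the gamma time-to-peak
#' parameters: the curve minimum falls later than the undershoot gamma's
#' mode (for the canonical (6, 16) timing the minimum is near 16.97 s).
#'
#' @param timing an [hrf_timing()] object.
#' @param dt_s evaluation grid step.
#' @return Named numeric: `pos`, `neg` (seconds).
#' @export
double_gamma_peak_times <- function(timing, dt_s = 0.01) {
  t <- seq(0, max(32, timing$t_peak_neg_s * 2), by = dt_s)
  h <- stats::dgamma(t, shape = timing$t_peak_pos_s + 1, rate = 1) -
    timing$undershoot_ratio *
      stats::dgamma(t, shape = timing$t_peak_neg_s + 1, rate = 1)
  ip <- which.max(h)
  im <- ip + which.min(h[ip:length(h)]) - 1L
  c(pos = t[ip], neg = t[im])
}

#' Gamma timing parameters whose curve peaks at given times
#'
#' Inverts [double_gamma_peak_times()]: finds the gamma time-to-peak
#' parameters such that the resulting double-gamma curve attains its maximum
#' and subsequent minimum at the requested times. Solved by alternating
#' bracketed root-finds (each peak time is monotone in its own gamma
#' parameter); targets outside the achievable range are clipped to the
#' bracket end.
#'
#' @param t_pos_s,t_neg_s target curve peak times (seconds).
#' @param undershoot_ratio undershoot amplitude ratio.
#' @param dt_s timing grid step of the returned object.
#' @return An [hrf_timing()] object.
#' @export
timing_from_peaks <- function(t_pos_s, t_neg_s, undershoot_ratio = 1 / 6,
                              dt_s = 0.1) {
  peaks <- function(p1, p2)
    double_gamma_peak_times(hrf_timing(p1, p2, undershoot_ratio, dt_s),
                            dt_s = 0.005)
  solve_pos <- function(p2) {
    f <- function(p) peaks(p, p2)[["pos"]] - t_pos_s
    lo <- 0.5
    hi <- min(t_pos_s + 5, p2 - 0.1)
    if (f(lo) >= 0) return(lo)
    if (f(hi) <= 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 0.005)$root
  }
  solve_neg <- function(p1) {
    # curves with p2 too close to p1 have no genuine undershoot and their
    # "minimum" sits on the evaluation-grid tail; treat those as invalid
    neg_of <- function(p) {
      v <- peaks(p1, p)[["neg"]]
      if (v > 30) Inf else v
    }
    grid <- seq(p1 + 0.5, max(t_neg_s + 8, p1 + 3), by = 0.25)
    c2 <- vapply(grid, neg_of, 1)
    if (all(!is.finite(c2))) return(max(t_neg_s, p1 + 1))
    # the min-time map can be non-monotone in p2 (two branches reach the
    # same minimum time); prefer the larger-p2, wider-undershoot branch
    near <- which(abs(c2 - t_neg_s) < 0.3)
    i <- if (length(near)) max(near) else which.min(abs(c2 - t_neg_s))
    fine <- seq(max(p1 + 0.3, grid[i] - 0.25), grid[i] + 0.25, by = 0.02)
    cf <- vapply(fine, neg_of, 1)
    fine[which.min(abs(cf - t_neg_s))]
  }
  p1 <- t_pos_s
  p2 <- max(t_neg_s - 1.5, p1 + 1)
  for (k in 1:3) {
    p1 <- solve_pos(p2)
    p2 <- solve_neg(p1)
    pk <- peaks(p1, p2)
    if (abs(pk[["pos"]] - t_pos_s) < 0.02 &&
        abs(pk[["neg"]] - t_neg_s) < 0.02) break
  }
  hrf_timing(p1, p2, undershoot_ratio, dt_s)
}

#' Canonical double-gamma HRF
#'
#' `h(t) = g(t; peak = t_peak_pos) - undershoot_ratio * g(t; peak = t_peak_neg)`
#' where each `g` is a gamma density with unit dispersion, peak-normalized so
#' `max h = 1`. `h(0) = 0` because both shapes exceed 1.
#'
#' @param timing an [hrf_timing()] object.
#' @param duration_s length of the sampled response; must exceed the
#'   undershoot time-to-peak.
#' @return An `hrf` object: list with `t` (sample times) and `values`.
#' @export
double_gamma <- function(timing = hrf_timing(), duration_s = 32) {
  if (duration_s <= timing$t_peak_neg_s)
    stop("duration_s must exceed t_peak_neg_s")
  t <- seq(0, duration_s, by = timing$dt_s)
  h <- stats::dgamma(t, shape = timing$t_peak_pos_s + 1, rate = 1) -
    timing$undershoot_ratio *
      stats::dgamma(t, shape = timing$t_peak_neg_s + 1, rate = 1)
  h <- h / max(h)
  structure(list(t = t, values = h, dt_s = timing$dt_s, timing = timing),
            class = "hrf")
}

#' Temporal derivative orthogonalized against the HRF
#'
#' Central finite-difference derivative of a sampled HRF, projected orthogonal
#' to the HRF itself (single Gram-Schmidt step), so the magnitude regressor
#' retains all shared variance.
#'
#' @param h an `hrf` object or numeric vector on a uniform grid.
#' @param dt_s sampling step, required when `h` is a bare vector.
#' @return Numeric vector of the same length, with `<result, h> = 0`.
#' @export
orthogonalized_derivative <- function(h, dt_s = NULL) {
  if (inherits(h, "hrf")) {
    v <- h$values
    dt_s <- h$dt_s
  } else {
    v <- as.numeric(h)
    if (is.null(dt_s)) stop("dt_s required for a bare numeric vector")
  }
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt_s)
  d[1L] <- (v[2L] - v[1L]) / dt_s
  d[n] <- (v[n] - v[n - 1L]) / dt_s
  hh <- sum(v * v)
  if (hh == 0 || all(d == 0)) {
    warning("constant input: derivative is identically zero")
    return(numeric(n))
  }
  d - (sum(d * v) / hh) * v
}

# Oversampled boxcar stimulus vector for one finger on a fine dt grid.
#' @keywords internal
#' @noRd
stim_vector <- function(events, finger, run_duration_s, dt_s) {
  n <- round(run_duration_s / dt_s)
  s <- numeric(n)
  ev <- events[events$finger == finger, , drop = FALSE]
  for (e in seq_len(nrow(ev))) {
    i0 <- round(ev$onset_s[e] / dt_s) + 1L
    i1 <- min(n, i0 + round(ev$duration_s[e] / dt_s) - 1L)
    if (i0 <= n) s[i0:i1] <- 1
  }
  s
}

# Convolve on a fine grid then pick out the volume-time samples.
#' @keywords internal
#' @noRd
convolve_sample <- function(stim, kernel, n_vols, tr_s, dt_s) {
  full <- stats::convolve(stim, rev(kernel), type = "open") * dt_s
  idx <- round((seq_len(n_vols) - 1L) * tr_s / dt_s) + 1L
  full[idx]
}

#' Canonical ER design matrix
#'
#' Per finger, a boxcar train at the event onsets is convolved with the
#' canonical double-gamma HRF (magnitude regressor) and with its temporal
#' derivative; the derivative column is then orthogonalized against its own
#' finger's magnitude column. Convolution is carried out on a 0.1 s grid (1 s
#' boxcars are sub-TR) and decimated to the volume times, giving 10 labelled
#' task regressors (2 per finger). No intercept is included; fitting functions
#' append per-run intercepts.
#'
#' @param paradigm a `paradigm_er` (or `paradigm_pe`) object.
#' @param timing an [hrf_timing()] object.
#' @param hrf_duration_s length of the convolution kernel.
#' @return A `design_matrix` object: `matrix` (volumes x 10), `labels` data
#'   frame (`finger`, `component`), `tr_s`, `run_lengths`.
#' @export
build_canonical_design <- function(paradigm, timing = hrf_timing(),
                                   hrf_duration_s = 32) {
  events <- if (inherits(paradigm, "paradigm_pe")) paradigm$epochs else paradigm$events
  tr_s <- paradigm$tr_s
  dt_s <- timing$dt_s
  if (any(events$onset_s < 0 | events$onset_s >= paradigm$run_duration_s))
    stop("event onsets outside the run")
  n_vols <- round(paradigm$run_duration_s / tr_s)
  hrf <- double_gamma(timing, hrf_duration_s)
  n <- length(hrf$values)
  dh <- numeric(n)
  dh[2:(n - 1L)] <- (hrf$values[3:n] - hrf$values[1:(n - 2L)]) / (2 * dt_s)
  dh[1L] <- (hrf$values[2L] - hrf$values[1L]) / dt_s
  dh[n] <- (hrf$values[n] - hrf$values[n - 1L]) / dt_s

  X <- matrix(0, n_vols, 10L)
  labels <- data.frame(finger = rep(1:5, each = 2L),
                       component = rep(c("magnitude", "derivative"), 5L))
  for (f in 1:5) {
    s <- stim_vector(events, f, paradigm$run_duration_s, dt_s)
    mag <- convolve_sample(s, hrf$values, n_vols, tr_s, dt_s)
    der <- convolve_sample(s, dh, n_vols, tr_s, dt_s)
    # orthogonalize the decimated derivative column against its magnitude column
    if (sum(mag^2) > 0) der <- der - (sum(der * mag) / sum(mag^2)) * mag
    X[, 2L * f - 1L] <- mag
    X[, 2L * f] <- der
  }
  colnames(X) <- paste0("f", labels$finger, "_",
                        substr(labels$component, 1, 3))
  structure(list(matrix = X, labels = labels, tr_s = tr_s,
                 run_lengths = n_vols, kind = "canonical", timing = timing),
            class = "design_matrix")
}

#' FIR (deconvolution) design matrix
#'
#' Indicator design for nonparametric HRF estimation: column `(f, k)` is 1 at
#' volumes exactly `k` TRs after each finger-`f` onset (`k = 0..n_lags-1`),
#' giving `5 * n_lags` columns (65 for the default 13 lags, modelling the
#' response 0--12 TRs after stimulation).
#'
#' @param paradigm a `paradigm_er` object with TR-aligned onsets.
#' @param n_lags number of modelled delays.
#' @return A `design_matrix` object with labels (`finger`, `component` =
#'   `lag_0..lag_{n_lags-1}`).
#' @export
build_fir_design <- function(paradigm, n_lags = 13L) {
  tr_s <- paradigm$tr_s
  ev <- paradigm$events
  if (any(ev$onset_s %% tr_s != 0))
    stop("FIR design requires TR-aligned onsets")
  n_vols <- round(paradigm$run_duration_s / tr_s)
  X <- matrix(0, n_vols, 5L * n_lags)
  labels <- data.frame(finger = rep(1:5, each = n_lags),
                       component = rep(paste0("lag_", 0:(n_lags - 1L)), 5L))
  for (f in 1:5) {
    onset_vols <- ev$onset_s[ev$finger == f] / tr_s  # 0-based volumes
    for (k in 0:(n_lags - 1L)) {
      rows <- onset_vols + k + 1L
      rows <- rows[rows >= 1L & rows <= n_vols]
      X[rows, (f - 1L) * n_lags + k + 1L] <- 1
    }
  }
  colnames(X) <- paste0("f", labels$finger, "_", labels$component)
  structure(list(matrix = X, labels = labels, tr_s = tr_s,
                 run_lengths = n_vols, kind = "fir", n_lags = as.integer(n_lags)),
            class = "design_matrix")
}

#' Concatenate designs of multiple runs
#'
#' Stacks per-run design matrices block-row-wise (regressors shared across
#' runs) and records run lengths so fitting can add per-run intercepts and
#' whiten within runs only.
#'
#' @param designs list of `design_matrix` objects with identical labels.
#' @return A single `design_matrix`.
#' @export
concat_designs <- function(designs) {
  stopifnot(length(designs) >= 1L)
  lab <- designs[[1L]]$labels
  for (d in designs[-1L])
    if (!identical(d$labels, lab)) stop("designs have mismatched labels")
  structure(list(
    matrix = do.call(rbind, lapply(designs, `[[`, "matrix")),
    labels = lab,
    tr_s = designs[[1L]]$tr_s,
    run_lengths = unlist(lapply(designs, `[[`, "run_lengths")),
    kind = designs[[1L]]$kind
  ), class = "design_matrix")
}

#' Export a design matrix as tab-separated text
#'
#' @param design a `design_matrix`.
#' @param file output path.
#' @export
write_design_tsv <- function(design, file) {
  utils::write.table(design$matrix, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
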