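# Pre-statistics conditioning: high-pass filtering then percent-signal
# conversion, in that order.

#' High-pass filter a BOLD run
#'
#' Zero-phase frequency-domain filter: every Fourier component with frequency
#' strictly below the cut-off (excluding DC) is removed; the per-voxel mean is
#' preserved. A brick-wall DFT filter is used rather than an IIR family so the
#' pass/stop behaviour is exactly testable.
#'
#' @param run a `bold_run` with units `"raw"`.
#' @param cutoff_hz cut-off frequency; must be below Nyquist.
#' @return The filtered `bold_run` (still `"raw"` units).
#' @export
highpass <- function(run, cutoff_hz = 0.01) {
  stopifnot(inherits(run, "bold_run"))
  n <- ncol(run$data)
  nyquist <- 1 / (2 * run$tr_s)
  if (cutoff_hz >= nyquist) stop("cutoff_hz must be below Nyquist")
  freq <- pmin(0:(n - 1L), n - (0:(n - 1L))) / (n * run$tr_s)
  kill <- freq > 0 & freq < cutoff_hz
  X <- stats::mvfft(t(run$data))
  X[kill, ] <- 0
  run$data <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  run
}

#' Convert a BOLD run to percent-signal change
#'
#' `x -> 100 * (x - mean) / mean` per voxel, so each output series has zero
#' temporal mean. Voxels with non-positive mean (inside the mask, if given)
#' are flagged invalid (`NA`) with a warning.
#'
#' @param run a `bold_run` with units `"raw"`.
#' @param mask optional logical array/vector restricting the validity check.
#' @return The converted `bold_run` with units `"percent"`.
#' @export
to_percent_signal <- function(run, mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (run$units != "raw") stop("units must be raw (transition raw -> percent only)")
  m <- rowMeans(run$data)
  bad <- m <= 0
  if (!is.null(mask)) bad <- bad & as.logical(mask)
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-positive mean set invalid")
    run$data[bad, ] <- NA_real_
    m[bad] <- NA_real_
  }
  run$data <- 100 * (run$data - m) / m
  run$units <- "percent"
  run
}
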