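# Traveling-wave analysis: sinusoid fit at the stimulation frequency,
# coherence/phase maps, fingertip ROI definition and ROI geometry.

#' Fit the stimulation-frequency sinusoid per voxel
#'
#' The DFT bin at the stimulation frequency gives each voxel's response
#' amplitude and phase; coherence is the amplitude at the stimulation
#' frequency divided by the root-sum-square amplitude over all positive
#' (non-DC) frequencies, so a pure sinusoid has coherence 1 and white noise
#' has low coherence. Phase is returned in `[0, 2*pi)` increasing with
#' response latency within the cycle, so it encodes the preferred fingertip.
#'
#' @param run a `bold_run` in percent units.
#' @param stim_freq_cycles_per_run integer stimulation frequency (cycles/run).
#' @return A `phase_maps` object: per-voxel `amplitude`, `phase` (NA where
#'   amplitude is 0), `coherence`, plus `stim_freq`, grid geometry and the
#'   run length `n_timepoints`.
#' @export
fit_sinusoid <- function(run, stim_freq_cycles_per_run) {
  stopifnot(inherits(run, "bold_run"))
  if (run$units != "percent") stop("fit_sinusoid expects percent-signal data")
  n <- ncol(run$data)
  f0 <- as.integer(stim_freq_cycles_per_run)
  if (f0 < 1L || f0 >= n / 2) stop("stimulation frequency at or above Nyquist bin")
  X <- stats::mvfft(t(run$data))          # time x voxel
  pos <- 2:(floor(n / 2) + 1L)            # positive-frequency bins incl. Nyquist
  amp_all2 <- abs(X[pos, , drop = FALSE])^2
  denom <- sqrt(colSums(amp_all2))
  z <- X[f0 + 1L, ]
  amplitude <- 2 * abs(z) / n
  coherence <- ifelse(denom > 0, abs(z) / denom, 0)
  phase <- (-Arg(z)) %% (2 * pi)
  phase[abs(z) == 0] <- NA_real_
  structure(list(amplitude = amplitude, phase = phase, coherence = coherence,
                 stim_freq = f0, n_timepoints = n,
                 grid_shape = run$grid_shape,
                 voxel_size_mm = run$voxel_size_mm),
            class = "phase_maps")
}

#' Uncorrected p-value for a coherence value
#'
#' Under the null of white Gaussian noise the squared coherence over `n_freq`
#' positive-frequency bins follows a Beta(1, n_freq - 1) distribution, giving
#' `p = (1 - C^2)^(n_freq - 1)`. Provided as a function of run length because
#' the coherence-to-p mapping depends on it.
#'
#' @param coherence coherence values in `[0, 1]`.
#' @param n_timepoints run length in volumes.
#' @return Upper-tail p-values.
#' @export
coherence_to_p <- function(coherence, n_timepoints) {
  n_freq <- floor(n_timepoints / 2)
  (1 - pmin(coherence, 1)^2)^(n_freq - 1L)
}

#' Average forward and reverse phase-encoding runs
#'
#' The reverse run is circularly time-reversed (sample 1 stays at time 0, so
#' sample times align on the periodic cycle) and averaged with the forward
#' run. Because reversal conjugates the hemodynamic transfer function, the
#' common hemodynamic phase delay cancels to first order and the combined
#' phase reflects stimulus timing only.
#'
#' @param fwd,rev `bold_run`s of equal length and TR.
#' @return The combined `bold_run`.
#' @export
combine_forward_reverse <- function(fwd, rev) {
  stopifnot(inherits(fwd, "bold_run"), inherits(rev, "bold_run"))
  n <- ncol(fwd$data)
  if (ncol(rev$data) != n || fwd$tr_s != rev$tr_s)
    stop("forward and reverse runs must match in length and TR")
  idx <- c(1L, n:2L)  # circular time reversal
  fwd$data <- (fwd$data + rev$data[, idx]) / 2
  fwd
}

#' Define fingertip ROIs from phase and coherence maps
#'
#' Phase values are divided into five bins of width `2*pi/5` (bin `f` is
#' `[2*pi*(f-1)/5, 2*pi*f/5)`, half-open so phase 0 belongs to bin 1). For
#' each finger, gray-matter voxels in the finger's bin with coherence above
#' the threshold are selected and the largest spatially contiguous component
#' (face-adjacency by default) is kept; smaller components are dropped with a
#' message.
#'
#' @param maps a `phase_maps` object.
#' @param gray_mask logical array/vector of gray-matter voxels.
#' @param coherence_threshold coherence cut-off (0.25 corresponds to an
#'   uncorrected p of about 0.006 at the localizer run lengths used here; see
#'   [coherence_to_p()]).
#' @param n_bins number of phase bins (one per finger).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return List of 5 `fingertip_roi` objects (possibly empty, with a warning).
#' @export
define_fingertip_rois <- function(maps, gray_mask, coherence_threshold = 0.25,
                                  n_bins = 5L, connectivity = 6) {
  gray <- as.logical(gray_mask)
  gs <- maps$grid_shape
  rois <- vector("list", n_bins)
  for (f in seq_len(n_bins)) {
    lo <- 2 * pi * (f - 1L) / n_bins
    hi <- 2 * pi * f / n_bins
    sel <- gray & !is.na(maps$phase) & maps$phase >= lo & maps$phase < hi &
      maps$coherence > coherence_threshold
    if (!any(sel)) {
      warning("empty phase bin for finger ", f)
      rois[[f]] <- fingertip_roi(f, integer(0), gs, maps$voxel_size_mm)
      next
    }
    comp <- label_components(array(sel, gs), connectivity)
    sizes <- tabulate(comp[comp > 0L])
    keep <- which.max(sizes)
    if (length(sizes) > 1L)
      message("finger ", f, ": keeping largest of ", length(sizes),
              " components (sizes ", paste(sort(sizes, TRUE), collapse = ","), ")")
    rois[[f]] <- fingertip_roi(f, which(comp == keep), gs, maps$voxel_size_mm)
  }
  rois
}

#' @keywords internal
#' @noRd
fingertip_roi <- function(finger, voxels, grid_shape, voxel_size_mm,
                          compartment = "whole") {
  structure(list(finger = as.integer(finger), voxels = as.integer(voxels),
                 compartment = compartment,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm),
            class = "fingertip_roi")
}

#' Centre of mass of an ROI in mm
#'
#' Unweighted mean of member voxel centres; 0-based voxel indices, voxel
#' centre at `index * voxel_size`.
#'
#' @param roi a `fingertip_roi`.
#' @return Length-3 numeric, mm coordinates.
#' @export
roi_center_of_mass <- function(roi) {
  if (length(roi$voxels) == 0L) stop("empty ROI has no centre of mass")
  ijk <- vox_unlinear(roi$voxels, roi$grid_shape)
  colMeans(sweep(ijk, 2L, roi$voxel_size_mm, `*`))
}

#' Expand fingertip ROIs into the analysis volume
#'
#' All brain voxels whose centre lies within `radius_voxels` voxels of any ROI
#' voxel (Euclidean lattice ball by default, Chebyshev cube by flag). This is
#' the small-volume restriction applied before the event-related statistics:
#' the traveling-wave localizer is blind to voxels responding equally to all
#' fingers, so the ROI union is padded.
#'
#' @param rois list of `fingertip_roi`s.
#' @param brain_mask logical array/vector.
#' @param radius_voxels expansion radius in voxel units.
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return Sorted integer vector of linear voxel indices.
#' @export
build_analysis_volume <- function(rois, brain_mask, radius_voxels = 5,
                                  metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  roi_vox <- sort(unique(unlist(lapply(rois, `[[`, "voxels"))))
  if (length(roi_vox) == 0L) stop("all ROIs are empty")
  gs <- rois[[which.max(vapply(rois, function(r) length(r$voxels), 1L))]]$grid_shape
  offsets <- if (metric == "euclidean") {
    ball_offsets(radius_voxels)
  } else {
    r <- floor(radius_voxels)
    as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  }
  vol <- dilate_indices(roi_vox, offsets, gs)
  vol[as.logical(brain_mask)[vol]]
}

#' Tab-separated ROI summary (voxel counts and centres of mass)
#'
#' @param rois list of `fingertip_roi`s.
#' @return Data frame with one row per ROI.
#' @export
roi_summary <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    com <- if (length(r$voxels)) roi_center_of_mass(r) else rep(NA_real_, 3L)
    data.frame(finger = r$finger, compartment = r$compartment,
               n_voxels = length(r$voxels),
               com_x_mm = com[1L], com_y_mm = com[2L], com_z_mm = com[3L])
  }))
}
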