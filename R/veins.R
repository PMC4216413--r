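# Vein mapping from susceptibility-weighted phase volumes:
# unwrap -> high-pass -> threshold -> dilate, plus vein-proximity labelling.

# 1D Itoh unwrap: integrate wrapped forward differences.
#' @keywords internal
#' @noRd
unwrap_1d <- function(v) {
  if (length(v) < 2L) return(v)
  v[1L] + c(0, cumsum(wrap_phase(diff(v))))
}

#' Spatially unwrap a phase volume
#'
#' Sequential path-following (Itoh) unwrapping: wrapped finite differences are
#' integrated along the third axis for the anchor line, along the second axis
#' for the anchor plane, and along the first axis for every remaining line,
#' with each line tied to the unwrapped anchor by a multiple of 2*pi. Exact
#' (up to the global 2*pi offset of the first voxel) whenever the true phase
#' changes by less than pi between neighbouring voxels along the integration
#' paths.
#'
#' @param phase_volume 3D array of wrapped phase in `(-pi, pi]` (a
#'   `vein_phantom` is also accepted).
#' @return 3D array of spatially continuous phase.
#' @export
unwrap_phase <- function(phase_volume) {
  if (inherits(phase_volume, "vein_phantom"))
    phase_volume <- phase_volume$phase_volume
  ph <- phase_volume
  dims <- dim(ph)
  out <- array(NA_real_, dims)
  anchor_line <- unwrap_1d(ph[1L, 1L, ])
  for (k in seq_len(dims[3L])) {
    col <- unwrap_1d(ph[1L, , k])
    col <- col + (anchor_line[k] - col[1L])
    for (j in seq_len(dims[2L])) {
      line <- unwrap_1d(ph[, j, k])
      out[, j, k] <- line + (col[j] - line[1L])
    }
  }
  out
}

# Separable Gaussian smoothing with odd (antisymmetric) reflection padding,
# which preserves constants and linear ramps exactly at the edges.
#' @keywords internal
#' @noRd
gaussian_smooth3d <- function(vol, sigma_vox) {
  dims <- dim(vol)
  out <- vol
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    kern <- stats::dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    n <- dims[a]
    perm <- c(a, setdiff(1:3, a))
    v <- aperm(out, perm)
    dimv <- dim(v)
    m <- matrix(v, dimv[1L])
    li <- pmin(pmax(seq(r + 1L, 2L), 1L), n)       # mirror indices, clipped
    ri <- pmin(pmax(seq(n - 1L, n - r), 1L), n)
    padded <- rbind(
      matrix(2 * rep(m[1L, ], each = r) - m[li, , drop = FALSE], r),
      m,
      matrix(2 * rep(m[n, ], each = r) - m[ri, , drop = FALSE], r))
    sm <- matrix(0, n, ncol(m))
    for (t in seq_along(kern))
      sm <- sm + kern[t] * padded[(t - 1L) + seq_len(n), , drop = FALSE]
    out <- aperm(array(sm, dimv), order(perm))
  }
  out
}

#' High-pass filter an unwrapped phase volume
#'
#' Subtracts a Gaussian-smoothed copy (FWHM `fwhm_mm`), emphasizing abrupt
#' phase changes such as the susceptibility deviations in and around veins
#' while removing the smooth background field.
#'
#' @param unwrapped 3D array of unwrapped phase.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 10).
#' @param voxel_size_mm voxel size in mm.
#' @return 3D array, `unwrapped - smooth(unwrapped)`.
#' @export
highpass_phase <- function(unwrapped, fwhm_mm = 10, voxel_size_mm = 1.5) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  vx <- rep(voxel_size_mm, length.out = 3L)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vx
  unwrapped - gaussian_smooth3d(unwrapped, sigma_vox)
}

#' Vein mask from a filtered phase volume
#'
#' Thresholds the absolute filtered phase and dilates the supra-threshold
#' voxels with a spherical structuring element of radius `dilation_mm`
#' (the binary reading of "convolving with a 2 mm kernel"). The default
#' threshold of 0.3 rad was calibrated once on the vein phantom and is
#' documented in the methods vignette.
#'
#' @param filtered 3D array of high-pass-filtered phase.
#' @param threshold_rad detection threshold in radians (> 0).
#' @param voxel_size_mm voxel size in mm.
#' @param dilation_mm dilation radius in mm.
#' @return A `vein_mask` object: logical `mask` array, `pre_dilation` array,
#'   `threshold_rad`, `dilation_mm`.
#' @export
vein_mask <- function(filtered, threshold_rad = 0.3, voxel_size_mm = 1.5,
                      dilation_mm = 2) {
  if (threshold_rad <= 0) stop("threshold_rad must be positive")
  vx <- rep(voxel_size_mm, length.out = 3L)
  core <- abs(filtered) > threshold_rad
  dims <- dim(filtered)
  idx <- which(core)
  mask <- array(FALSE, dims)
  if (length(idx)) {
    off <- ball_offsets(dilation_mm, vx)
    mask[dilate_indices(idx, off, dims)] <- TRUE
  }
  structure(list(mask = mask, pre_dilation = core,
                 threshold_rad = threshold_rad, dilation_mm = dilation_mm,
                 voxel_size_mm = vx), class = "vein_mask")
}

#' Voxels within a given distance of a vein
#'
#' Euclidean centre-to-centre proximity: a voxel belongs to the output when
#' its centre lies within `distance_mm` of any vein-mask voxel centre. At the
#' default 0.5 mm with 1.5 mm voxels no neighbouring centre qualifies, so the
#' proximity mask equals the vein mask itself.
#'
#' @param mask a `vein_mask` or logical 3D array.
#' @param distance_mm proximity radius in mm (>= 0).
#' @param voxel_size_mm voxel size, required when `mask` is a bare array.
#' @return Logical 3D array.
#' @export
near_vein <- function(mask, distance_mm = 0.5, voxel_size_mm = 1.5) {
  if (inherits(mask, "vein_mask")) {
    vx <- mask$voxel_size_mm
    mask <- mask$mask
  } else {
    vx <- rep(voxel_size_mm, length.out = 3L)
  }
  if (distance_mm < 0) stop("distance_mm must be >= 0")
  dims <- dim(mask)
  out <- array(FALSE, dims)
  idx <- which(mask)
  if (length(idx)) {
    off <- ball_offsets(distance_mm, vx)
    out[dilate_indices(idx, off, dims)] <- TRUE
  }
  out
}
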