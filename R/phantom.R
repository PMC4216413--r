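#' Synthetic somatotopic phantom
#'
#' Builds a voxel grid that emulates the fingertip map of primary somatosensory
#' cortex: five parallel finger-preference bands laid out along the first grid
#' axis, with per-voxel tuning weights that fall off as a Gaussian of distance
#' from each band centre. The grid is split along the second axis into an
#' *anterior* compartment with narrow tuning (high fingertip specificity, as in
#' the posterior bank of the central sulcus) and a *posterior* compartment with
#' broad tuning (large overlap, as on the post-central gyrus).
#'
#' Tuning is `exp(-d^2 / (2 sigma^2))` where `d` is the mm distance along the
#' band axis from the voxel centre to the finger's band centre and `sigma`
#' depends on the voxel's compartment. Band centres are spaced
#' `band_spacing_mm` apart (default 5.5 mm, the typical adjacent-digit
#' centre-of-mass separation on the cortical surface).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param anterior_fraction fraction of the second axis assigned to the
#'   anterior compartment.
#' @param sigma_tuning_anterior,sigma_tuning_posterior Gaussian tuning widths
#'   in mm; anterior must normally be the narrower.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param band_spacing_mm spacing between adjacent finger band centres in mm.
#' @param gray_tuning_min tuning floor below which a voxel is not gray matter.
#' @param gray_y_fraction_max fraction of the second axis covered by gray
#'   matter; brain voxels beyond it emulate the analysis-volume cortex
#'   posterior to the fingertip ROIs.
#' @param seed integer seed recorded in the object (tuning is deterministic).
#' @return An object of class `phantom`: grid geometry, `tuning` (voxel x 5
#'   matrix in `[0,1]`), per-voxel `compartment` labels, logical `gray_mask`
#'   and `brain_mask` arrays, `preferred_finger` (argmax of tuning, NA outside
#'   gray matter) and the band centres in mm.
#' @export
make_somatotopic_phantom <- function(grid_shape = c(32L, 32L, 8L),
                                     anterior_fraction = 0.5,
                                     sigma_tuning_anterior = 3,
                                     sigma_tuning_posterior = 6,
                                     voxel_size_mm = 1.5,
                                     band_spacing_mm = 5.5,
                                     gray_tuning_min = 0.05,
                                     gray_y_fraction_max = 0.85,
                                     seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be three positive integers")
  if (sigma_tuning_anterior <= 0 || sigma_tuning_posterior <= 0)
    stop("tuning sigmas must be positive")
  vx <- rep(voxel_size_mm, length.out = 3L)
  ijk <- vox_coords(grid_shape)
  nvox <- nrow(ijk)

  x_mm <- ijk[, 1L] * vx[1L]
  x_mid <- (grid_shape[1L] - 1L) * vx[1L] / 2
  band_centers_mm <- x_mid + (1:5 - 3) * band_spacing_mm

  y_idx <- ijk[, 2L]
  anterior <- y_idx < anterior_fraction * grid_shape[2L]
  sigma <- ifelse(anterior, sigma_tuning_anterior, sigma_tuning_posterior)

  tuning <- matrix(0, nvox, 5L)
  for (f in 1:5) {
    d <- x_mm - band_centers_mm[f]
    tuning[, f] <- exp(-d^2 / (2 * sigma^2))
  }

  # brain: everything but a one-voxel shell (where the shell fits)
  brain <- rep(TRUE, nvox)
  for (a in 1:3) {
    if (grid_shape[a] > 4L)
      brain <- brain & ijk[, a] > 0L & ijk[, a] < grid_shape[a] - 1L
  }
  gray <- brain & apply(tuning, 1L, max) >= gray_tuning_min &
    y_idx < gray_y_fraction_max * grid_shape[2L]

  compartment <- rep("none", nvox)
  compartment[gray & anterior] <- "anterior"
  compartment[gray & !anterior] <- "posterior"

  # ties (voxels equidistant from two band centres) break toward the middle
  # finger: the aggregate traveling-wave response of an equidistant voxel is
  # dominated by its inner flank (the distant-finger tails are asymmetric), so
  # the localizer assigns such voxels to the inner bin
  preferred <- rep(NA_integer_, nvox)
  preferred[gray] <- apply(tuning[gray, , drop = FALSE], 1L, function(w) {
    cand <- which(w == max(w))
    cand[which.min(abs(cand - 3L))]
  })

  structure(list(
    grid_shape = grid_shape,
    voxel_size_mm = vx,
    tuning = tuning,
    compartment = compartment,
    gray_mask = array(gray, grid_shape),
    brain_mask = array(brain, grid_shape),
    preferred_finger = preferred,
    band_centers_mm = band_centers_mm,
    band_spacing_mm = band_spacing_mm,
    sigma_tuning = c(anterior = sigma_tuning_anterior,
                     posterior = sigma_tuning_posterior),
    seed = as.integer(seed)
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("somatotopic phantom:", paste(x$grid_shape, collapse = "x"),
      "voxels at", x$voxel_size_mm[1L], "mm\n")
  cat("  gray voxels:", sum(x$gray_mask),
      sprintf("(anterior %d / posterior %d)\n",
              sum(x$compartment == "anterior"),
              sum(x$compartment == "posterior")))
  invisible(x)
}

#' Synthetic susceptibility-phase phantom with vein-like features
#'
#' Generates a wrapped phase volume emulating a T2*-weighted phase image: a
#' smooth low-frequency background (a linear ramp that may span several multiples
#' of 2*pi before wrapping) plus localized, tube-shaped high-spatial-frequency
#' phase deviations at recorded vein locations. The returned ground-truth vein
#' mask supports sensitivity/specificity evaluation of the vein-mapping chain.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param n_veins number of straight vein tubes to insert.
#' @param background_gradient total background phase span in radians across the
#'   first axis (before wrapping).
#' @param vein_amplitude_rad peak phase deviation at a vein core.
#' @param vein_radius_mm radius of the vein cross-section.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param seed RNG seed for vein placement.
#' @return Object of class `vein_phantom`: `phase_volume` (radians, wrapped to
#'   `(-pi, pi]`), `true_phase` (unwrapped), `true_vein_mask`, geometry.
#' @export
make_vein_phantom <- function(grid_shape = c(32L, 32L, 8L),
                              n_veins = 3L,
                              background_gradient = 4 * pi,
                              vein_amplitude_rad = 1.2,
                              vein_radius_mm = 1.2,
                              voxel_size_mm = 1.5,
                              seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (n_veins < 0L) stop("n_veins must be >= 0")
  vx <- rep(voxel_size_mm, length.out = 3L)
  ijk <- vox_coords(grid_shape)
  pos_mm <- sweep(ijk, 2L, vx, `*`)

  span <- max(1L, grid_shape[1L] - 1L) * vx[1L]
  bg <- background_gradient * pos_mm[, 1L] / span

  dev <- numeric(nrow(ijk))
  vein_mask <- logical(nrow(ijk))
  if (n_veins > 0L) {
    set.seed(seed)
    for (v in seq_len(n_veins)) {
      # straight tube running through the volume along the third axis,
      # at a random in-plane position
      cx <- stats::runif(1, 0.15, 0.85) * (grid_shape[1L] - 1L) * vx[1L]
      cy <- stats::runif(1, 0.15, 0.85) * (grid_shape[2L] - 1L) * vx[2L]
      sgn <- sample(c(-1, 1), 1L)
      r2 <- (pos_mm[, 1L] - cx)^2 + (pos_mm[, 2L] - cy)^2
      prof <- exp(-r2 / (2 * (vein_radius_mm / 1.5)^2))
      dev <- dev + sgn * vein_amplitude_rad * prof
      vein_mask <- vein_mask | r2 <= vein_radius_mm^2
    }
  }
  true_phase <- bg + dev
  structure(list(
    grid_shape = grid_shape,
    voxel_size_mm = vx,
    phase_volume = array(wrap_phase(true_phase), grid_shape),
    true_phase = array(true_phase, grid_shape),
    true_vein_mask = array(vein_mask, grid_shape),
    n_veins = as.integer(n_veins),
    seed = as.integer(seed)
  ), class = "vein_phantom")
}
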