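# Overlap and specificity quantification: activation masks, exactly-k count
# maps and threshold sweeps, overlap ratios, anterior/posterior ROI division,
# ROI-averaged estimates and cross-subject normalization.

#' Per-finger activation masks from adjusted p-values
#'
#' @param stat a `stat_maps` object (see [run_er_stage()]) carrying per-finger
#'   FWE- and FDR-adjusted p-values over the analysis volume.
#' @param alpha significance level.
#' @param correction `"fwe"` or `"fdr"`.
#' @return List of 5 logical vectors aligned to `stat$voxels`.
#' @export
activation_masks <- function(stat, alpha = 0.05, correction = c("fwe", "fdr")) {
  correction <- match.arg(correction)
  field <- paste0("p_", correction)
  lapply(1:5, function(f) {
    p <- stat$maps[[f]][[field]]
    !is.na(p) & p < alpha
  })
}

#' Per-voxel count of activating fingers
#'
#' @param masks list of 5 congruent logical vectors.
#' @return Integer vector of counts 0..5.
#' @export
overlap_count_map <- function(masks) {
  stopifnot(length(masks) == 5L)
  Reduce(`+`, lapply(masks, as.integer))
}

#' Overlap ratio of two activation masks
#'
#' Number of voxels activated by both conditions divided by the mean number
#' activated by each, within a reference voxel set:
#' `|A & B & W| / ((|A & W| + |B & W|) / 2)`. This equals the Dice
#' coefficient; the value is in `[0, 1]` and defined as 0 (logged) when
#' neither mask activates.
#'
#' @param mask_a,mask_b logical vectors.
#' @param within logical vector or index set defining the reference region.
#' @return Overlap ratio in `[0, 1]`.
#' @export
overlap_ratio <- function(mask_a, mask_b, within) {
  if (!is.logical(within)) {
    w <- logical(length(mask_a))
    w[within] <- TRUE
    within <- w
  }
  na <- sum(mask_a & within)
  nb <- sum(mask_b & within)
  if (na + nb == 0L) {
    message("overlap_ratio: both masks empty in the reference region; ratio 0")
    return(0)
  }
  sum(mask_a & mask_b & within) / ((na + nb) / 2)
}

#' Proportion of exactly-k-finger voxels across statistical thresholds
#'
#' For each Z threshold, voxels of the reference set significantly active
#' (FDR-adjusted Z at or above threshold) in at least one condition are
#' partitioned by how many conditions activate them; the fractions over
#' `k = 1..5` sum to 1 whenever any voxel survives. With
#' `denominator = "all"`, fractions are taken over the whole reference set
#' instead.
#'
#' @param stat a `stat_maps` object.
#' @param roi_voxels linear voxel indices of the reference set.
#' @param z_grid Z thresholds to sweep.
#' @param denominator `"active"` (default) or `"all"`.
#' @return Data frame (`z`, `k`, `fraction`, `n_active`).
#' @export
overlap_proportions_by_threshold <- function(stat, roi_voxels,
                                             z_grid = seq(0, 6, by = 0.5),
                                             denominator = c("active", "all")) {
  denominator <- match.arg(denominator)
  rows <- match(roi_voxels, stat$voxels)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0L) return(data.frame())
  zmat <- sapply(1:5, function(f) stat$maps[[f]]$z_fdr[rows])
  out <- list()
  for (z in z_grid) {
    counts <- rowSums(zmat >= z, na.rm = TRUE)
    n_active <- sum(counts >= 1L)
    denom <- if (denominator == "active") n_active else length(rows)
    for (k in 1:5) {
      out[[length(out) + 1L]] <- data.frame(
        z = z, k = k,
        fraction = if (denom > 0) sum(counts == k) / denom else NA_real_,
        n_active = n_active)
    }
  }
  do.call(rbind, out)
}

#' Split fingertip ROIs into anterior and posterior compartments
#'
#' @param rois list of `fingertip_roi`s (compartment `"whole"`).
#' @param boundary_labels character vector over the full grid with values
#'   `"anterior"` / `"posterior"` for every ROI voxel (ground truth for
#'   phantoms, or a user-supplied label map).
#' @return List of `fingertip_roi`s, two per input ROI, with counts preserved.
#' @export
split_rois <- function(rois, boundary_labels) {
  out <- list()
  for (roi in rois) {
    lab <- boundary_labels[roi$voxels]
    if (any(!lab %in% c("anterior", "posterior")))
      stop("unlabeled voxel(s) in ROI for finger ", roi$finger)
    for (comp in c("anterior", "posterior")) {
      out[[length(out) + 1L]] <- fingertip_roi(
        roi$finger, roi$voxels[lab == comp], roi$grid_shape,
        roi$voxel_size_mm, compartment = comp)
    }
  }
  out
}

#' ROI-averaged magnitude estimates per stimulation condition
#'
#' Mean magnitude coefficient across the voxels of each ROI for each
#' stimulated finger: the 5 x 5 (ROI x condition) response table per
#' compartment. Empty compartments yield missing values (logged), never
#' zeros.
#'
#' @param fit a canonical-design `glm_fit`.
#' @param rois list of `fingertip_roi`s.
#' @return Data frame (`roi_finger`, `compartment`, `stim_finger`,
#'   `mean_beta`).
#' @export
roi_average_betas <- function(fit, rois) {
  out <- list()
  for (roi in rois) {
    rows <- match(roi$voxels, fit$voxels)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L)
      message("empty ROI (finger ", roi$finger, ", ", roi$compartment,
              "): missing values")
    for (f in 1:5) {
      col <- which(fit$design$labels$finger == f &
                     fit$design$labels$component == "magnitude")
      out[[length(out) + 1L]] <- data.frame(
        roi_finger = roi$finger, compartment = roi$compartment,
        stim_finger = f,
        mean_beta = if (length(rows)) mean(fit$beta[rows, col]) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Normalize ROI response tables across subjects
#'
#' Each subject's values are divided by that subject's maximum and multiplied
#' by the group-mean maximum, removing between-subject contrast-to-noise
#' differences while preserving within-subject rank order.
#'
#' @param tables list of per-subject data frames from [roi_average_betas()].
#' @return List of normalized tables.
#' @export
normalize_across_subjects <- function(tables) {
  stopifnot(length(tables) >= 1L)
  maxima <- vapply(tables, function(tb) max(tb$mean_beta, na.rm = TRUE), 1)
  if (any(maxima <= 0)) stop("non-positive subject maximum")
  target <- mean(maxima)
  Map(function(tb, mx) {
    tb$mean_beta <- tb$mean_beta * (target / mx)
    tb
  }, tables, maxima)
}

#' Adjacent-pair overlap ratio table
#'
#' The Table-4-shaped report: overlap ratios for the four adjacent fingertip
#' pairs within each compartment voxel set, plus the across-pair average row
#' (always recomputed from the pair rows).
#'
#' @param masks list of 5 activation masks (logical over `stat$voxels`).
#' @param regions named list of reference voxel sets (logical over the same
#'   index space), e.g. anterior / posterior / posterior-to-ROIs.
#' @return Data frame with rows `D1&D2 .. D4&D5` and `Average`, one column
#'   per region, ratios in percent.
#' @export
overlap_ratio_table <- function(masks, regions) {
  pairs <- cbind(1:4, 2:5)
  tab <- data.frame(pair = c(sprintf("D%d&D%d", pairs[, 1L], pairs[, 2L]),
                             "Average"))
  for (rn in names(regions)) {
    vals <- vapply(seq_len(4L), function(i) {
      100 * overlap_ratio(masks[[pairs[i, 1L]]], masks[[pairs[i, 2L]]],
                          regions[[rn]])
    }, 1)
    tab[[rn]] <- c(vals, mean(vals))
  }
  tab
}

#' Across-pair average row of a printed overlap table
#'
#' Recomputes the `Average` row of an overlap-ratio table from its four pair
#' rows (the report machinery never stores averages independently).
#'
#' @param table data frame whose first column names the pairs and whose
#'   remaining columns hold ratios, with or without an existing Average row.
#' @return Named numeric vector of across-pair means per column.
#' @export
overlap_table_average <- function(table) {
  rows <- !grepl("^Average$", table[[1L]], ignore.case = TRUE)
  colMeans(table[rows, -1L, drop = FALSE])
}
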