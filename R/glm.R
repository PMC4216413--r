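# Event-related GLMs: ordinary least squares, per-subject HRF timing
# estimation, tile-wise Tukey-tapered noise autocorrelation, generalized least
# squares by prewhitening, one-sided contrast tests, and FIR deconvolution.

# Full fitting matrix: task regressors plus one intercept per run.
#' @keywords internal
#' @noRd
full_design_matrix <- function(design) {
  X <- design$matrix
  runs <- design$run_lengths
  ints <- matrix(0, sum(runs), length(runs))
  row0 <- 0L
  for (r in seq_along(runs)) {
    ints[row0 + seq_len(runs[r]), r] <- 1
    row0 <- row0 + runs[r]
  }
  colnames(ints) <- paste0("intercept_run", seq_along(runs))
  cbind(X, ints)
}

#' @keywords internal
#' @noRd
check_full_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  qrx
}

#' @keywords internal
#' @noRd
ols_core <- function(X, Y, design, method, noise = NULL, voxels = NULL,
                     grid_shape = NULL) {
  qrx <- check_full_rank(X)
  beta <- qr.coef(qrx, Y)                   # p x V
  res <- Y - X %*% beta                     # T x V
  dof <- nrow(X) - qrx$rank
  sigma2 <- colSums(res^2) / dof
  XtXinv_diag <- diag(chol2inv(qr.R(qrx)))
  stderr <- sqrt(outer(sigma2, XtXinv_diag))  # V x p
  colnames(stderr) <- colnames(X)
  structure(list(design = design, col_labels = colnames(X),
                 beta = t(beta), stderr = stderr, residuals = t(res),
                 sigma2 = sigma2, dof = dof, method = method, noise = noise,
                 voxels = voxels, grid_shape = grid_shape),
            class = "glm_fit")
}

#' Ordinary least-squares GLM fit
#'
#' Fits `y = X beta + e` per voxel, with one intercept appended per run.
#' Rank-deficient designs abort with the names of the dependent columns.
#'
#' @param design a `design_matrix`.
#' @param run a `bold_run` (percent units expected).
#' @param voxels optional linear voxel indices to fit (default: all).
#' @return A `glm_fit`: `beta`/`stderr` (voxel x regressor), `residuals`
#'   (voxel x time), residual `dof = n_time - rank(X)`, `method = "OLS"`.
#' @export
fit_ols <- function(design, run, voxels = NULL) {
  stopifnot(inherits(design, "design_matrix"), inherits(run, "bold_run"))
  if (sum(design$run_lengths) != ncol(run$data))
    stop("design rows do not match run length")
  if (is.null(voxels)) voxels <- seq_len(nrow(run$data))
  X <- full_design_matrix(design)
  Y <- t(run$data[voxels, , drop = FALSE])
  ols_core(X, Y, design, "OLS", voxels = voxels, grid_shape = run$grid_shape)
}

#' Estimate the noise autocorrelation with Tukey tapers
#'
#' Residual time series are averaged within square in-slice tiles (default
#' 20 x 20 voxels, excluding out-of-brain voxels). Per run, the sample
#' autocovariances of each tile-average series are corrected for the
#' downward bias that least-squares fitting induces in residual
#' autocorrelations (the residual autocovariance expectation is a known
#' linear map, through the hat matrix, of the true autocovariances; that map
#' is inverted on the first `M` lags). Corrected autocovariances are pooled
#' across runs, normalized, and smoothed with a Tukey taper
#' `0.5 * (1 + cos(pi * k / M))` for lags `k <= M` (zero beyond). Every
#' voxel inherits its tile's ACF; tiles without brain voxels inherit the
#' nearest populated tile (logged).
#'
#' @param fit a `glm_fit` whose residuals estimate the noise.
#' @param brain_mask logical array/vector over the full grid.
#' @param tile in-slice tile shape (voxels) along the first two axes.
#' @param taper_M taper length in lags; default `round(2 * sqrt(T_run))`.
#' @param bias_correct apply the hat-matrix bias correction (default TRUE).
#' @return A `noise_model`: raw and tapered per-tile ACFs, `taper_M`,
#'   `tile_shape` and the full-grid `tile_assignment`.
#' @export
estimate_noise_acf <- function(fit, brain_mask, tile = c(20L, 20L),
                               taper_M = NULL, bias_correct = TRUE) {
  gs <- fit$grid_shape
  runs <- fit$design$run_lengths
  if (is.null(taper_M)) taper_M <- round(2 * sqrt(mean(runs)))
  taper_M <- min(taper_M, min(runs) - 2L)
  brain <- as.logical(brain_mask)

  ijk <- vox_unlinear(seq_len(prod(gs)), gs)
  tile_i <- ijk[, 1L] %/% tile[1L]
  tile_j <- ijk[, 2L] %/% tile[2L]
  n_ti <- max(tile_i) + 1L
  n_tj <- max(tile_j) + 1L
  tile_assignment <- 1L + tile_i + n_ti * (tile_j + n_tj * ijk[, 3L])
  n_tiles <- n_ti * n_tj * gs[3L]

  # map fitted voxels into tiles
  fitted_tiles <- tile_assignment[fit$voxels]
  fitted_brain <- brain[fit$voxels]

  # residual-autocovariance bias map D (shared by all tiles), from the full
  # concatenated design: E[c_k] = sum_l D[k, l] * gamma_l, with c_k the
  # same-run k-lag residual autocovariance sum and gamma the true noise
  # autocovariances (the noise is independent across runs)
  n_total <- sum(runs)
  run_id <- rep(seq_along(runs), runs)
  same_run_pairs <- function(k) {
    t0 <- seq_len(n_total - k)
    t0[run_id[t0] == run_id[t0 + k]]
  }
  Dmat <- NULL
  if (bias_correct && ncol(fit$design$matrix) > 0) {
    Xfull <- full_design_matrix(fit$design)
    qx <- qr(Xfull)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    A <- diag(n_total) - tcrossprod(Q)
    Dmat <- matrix(0, taper_M + 1L, taper_M + 1L)
    for (l in 0:taper_M) {
      if (l == 0L) {
        Bmat <- A  # A is idempotent: A I A = A
      } else {
        src <- same_run_pairs(l)
        AE <- matrix(0, n_total, n_total)
        AE[, src + l] <- A[, src]   # A %*% E_l (within-run shifts only)
        P <- AE %*% A
        Bmat <- P + t(P)
      }
      for (k in 0:taper_M) {
        t0 <- same_run_pairs(k)
        Dmat[k + 1L, l + 1L] <- sum(Bmat[cbind(t0, t0 + k)])
      }
    }
  }

  acf_raw <- matrix(NA_real_, taper_M + 1L, n_tiles)
  tile_centers <- matrix(NA_real_, n_tiles, 3L)
  for (tl in seq_len(n_tiles)) {
    members <- which(fitted_tiles == tl & fitted_brain)
    all_members <- which(tile_assignment == tl)
    tile_centers[tl, ] <- colMeans(vox_unlinear(all_members, gs))
    if (length(members) == 0L) next
    avg <- colMeans(fit$residuals[members, , drop = FALSE])
    ck <- vapply(0:taper_M, function(k) {
      t0 <- same_run_pairs(k)
      sum(avg[t0] * avg[t0 + k])
    }, 1)
    gamma <- ck
    if (!is.null(Dmat)) {
      g <- tryCatch(solve(Dmat, ck), error = function(e) ck)
      if (g[1L] > 0) gamma <- g
    }
    a <- gamma / gamma[1L]
    acf_raw[, tl] <- pmax(pmin(a, 1), -1)
  }
  empty <- which(is.na(acf_raw[1L, ]))
  filled <- which(!is.na(acf_raw[1L, ]))
  if (length(filled) == 0L) stop("no tile contains brain voxels")
  if (length(empty) > 0L) {
    message(length(empty), " empty tile(s) inherit the nearest populated tile")
    for (tl in empty) {
      d2 <- rowSums(sweep(tile_centers[filled, , drop = FALSE], 2L,
                          tile_centers[tl, ], `-`)^2)
      acf_raw[, tl] <- acf_raw[, filled[which.min(d2)]]
    }
  }
  w <- 0.5 * (1 + cos(pi * (0:taper_M) / taper_M))
  acf_tapered <- acf_raw * w
  structure(list(acf_raw = acf_raw, acf_tapered = acf_tapered,
                 taper_M = taper_M, tile_shape = tile,
                 tile_assignment = tile_assignment, grid_shape = gs),
            class = "noise_model")
}

# Lower Cholesky factor of the Toeplitz correlation built from a tapered ACF,
# with a nearest-positive-definite eigenvalue-floor repair if needed.
#' @keywords internal
#' @noRd
toeplitz_chol <- function(acf_tapered, n) {
  rho <- numeric(n)
  m <- min(length(acf_tapered), n)
  rho[seq_len(m)] <- acf_tapered[seq_len(m)]
  V <- stats::toeplitz(rho)
  L <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(L)) {
    eg <- eigen(V, symmetric = TRUE)
    floor_val <- 1e-6 * max(eg$values)
    message("noise correlation repaired: eigenvalues floored at ",
            signif(floor_val, 3))
    V <- eg$vectors %*% (pmax(eg$values, floor_val) * t(eg$vectors))
    L <- t(chol((V + t(V)) / 2))
  }
  L
}

#' Generalized least-squares GLM fit by prewhitening
#'
#' For each noise tile, the tapered ACF defines a Toeplitz correlation matrix
#' per run; design and data are whitened with its inverse Cholesky factor
#' (independently within each run) and fitted by OLS. With an identity noise
#' model GLS reproduces OLS exactly.
#'
#' @param design a `design_matrix`.
#' @param run a `bold_run`.
#' @param noise a `noise_model` from [estimate_noise_acf()], or `NULL` for
#'   white noise (identity whitening).
#' @param voxels optional linear voxel indices to fit.
#' @return A `glm_fit` with `method = "GLS"` (residuals are whitened-space).
#' @export
fit_gls <- function(design, run, noise = NULL, voxels = NULL) {
  stopifnot(inherits(design, "design_matrix"), inherits(run, "bold_run"))
  if (is.null(voxels)) voxels <- seq_len(nrow(run$data))
  X <- full_design_matrix(design)
  Y <- t(run$data[voxels, , drop = FALSE])
  runs <- design$run_lengths
  if (is.null(noise)) {
    fit <- ols_core(X, Y, design, "GLS", voxels = voxels,
                    grid_shape = run$grid_shape)
    return(fit)
  }
  tiles <- noise$tile_assignment[voxels]
  beta <- matrix(NA_real_, length(voxels), ncol(X))
  stderr <- matrix(NA_real_, length(voxels), ncol(X))
  resid <- matrix(NA_real_, length(voxels), nrow(X))
  sigma2 <- numeric(length(voxels))
  dof <- NULL
  for (tl in unique(tiles)) {
    vsel <- which(tiles == tl)
    # whiten within each run segment
    Xw <- X
    Yw <- Y[, vsel, drop = FALSE]
    row0 <- 0L
    for (r in seq_along(runs)) {
      rows <- row0 + seq_len(runs[r])
      row0 <- row0 + runs[r]
      L <- toeplitz_chol(noise$acf_tapered[, tl], runs[r])
      Xw[rows, ] <- forwardsolve(L, X[rows, , drop = FALSE])
      Yw[rows, ] <- forwardsolve(L, Yw[rows, , drop = FALSE])
    }
    sub <- ols_core(Xw, Yw, design, "GLS")
    beta[vsel, ] <- sub$beta
    stderr[vsel, ] <- sub$stderr
    resid[vsel, ] <- sub$residuals
    sigma2[vsel] <- sub$sigma2
    dof <- sub$dof
  }
  colnames(stderr) <- colnames(X)
  structure(list(design = design, col_labels = colnames(X), beta = beta,
                 stderr = stderr, residuals = resid, sigma2 = sigma2,
                 dof = dof, method = "GLS", noise = noise, voxels = voxels,
                 grid_shape = run$grid_shape),
            class = "glm_fit")
}

#' One-sided t-test on a finger's magnitude estimate
#'
#' `t = beta_magnitude / stderr_magnitude` with `dof = n_time - rank(X)`;
#' for `side = "greater"`, `p = 1 - F_t(t; dof)`. Invalid voxels (NA fit)
#' get `p = 1`.
#'
#' @param fit a `glm_fit` from a canonical design.
#' @param finger finger 1..5.
#' @param side `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with per-voxel `t` and `p` vectors (aligned to `fit$voxels`).
#' @export
contrast_ttest <- function(fit, finger, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  col <- which(fit$design$labels$finger == finger &
                 fit$design$labels$component == "magnitude")
  if (length(col) != 1L) stop("no magnitude column for finger ", finger)
  t <- fit$beta[, col] / fit$stderr[, col]
  p <- switch(side,
    greater = stats::pt(t, fit$dof, lower.tail = FALSE),
    less = stats::pt(t, fit$dof),
    two.sided = 2 * stats::pt(abs(t), fit$dof, lower.tail = FALSE)
  )
  bad <- !is.finite(t)
  if (any(bad)) {
    t[bad] <- NA_real_
    p[bad] <- 1
  }
  list(t = t, p = p, dof = fit$dof, finger = finger, side = side)
}

#' Estimate subject-specific HRF timing from a step-1 fit
#'
#' In each fingertip ROI, the estimated HRF for the ROI's own finger is
#' reconstructed as `beta_mag * h(t) + beta_deriv * h'(t)` from ROI-mean
#' coefficients on a 0.01 s grid; the time of the positive peak (argmax) and
#' of the subsequent negative peak (argmin after the positive peak) are read
#' off and averaged across the five ROIs. ROIs whose reconstructed response is
#' nowhere positive are excluded with a warning. Note that the undershoot
#' trade-off shifts the curve minimum later than the undershoot gamma's
#' time-to-peak, so the returned negative peak is a property of the curve, not
#' the gamma parameter (peak times are reported as measured, the conventional
#' presentation).
#'
#' @param fit the step-1 OLS `glm_fit` (canonical design).
#' @param rois list of `fingertip_roi`s.
#' @param timing0 the [hrf_timing()] used in step 1.
#' @return An `hrf_timing` whose peak times are the across-ROI means, plus a
#'   `per_roi` attribute with the individual estimates.
#' @export
estimate_subject_timing <- function(fit, rois, timing0 = hrf_timing()) {
  fine <- hrf_timing(timing0$t_peak_pos_s, timing0$t_peak_neg_s,
                     timing0$undershoot_ratio, dt_s = 0.01)
  h <- double_gamma(fine, 32)
  d <- orthogonalized_derivative(h)
  nonempty <- Filter(function(r) length(r$voxels) > 0L, rois)
  if (length(nonempty) == 0L) stop("all ROIs are empty")
  est <- matrix(NA_real_, length(nonempty), 2L)
  for (i in seq_along(nonempty)) {
    roi <- nonempty[[i]]
    rows <- match(roi$voxels, fit$voxels)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) next
    cols <- which(fit$design$labels$finger == roi$finger)
    mag_col <- cols[fit$design$labels$component[cols] == "magnitude"]
    der_col <- cols[fit$design$labels$component[cols] == "derivative"]
    bm <- mean(fit$beta[rows, mag_col])
    bd <- mean(fit$beta[rows, der_col])
    hhat <- bm * h$values + bd * d
    if (all(hhat <= 0)) {
      warning("ROI for finger ", roi$finger,
              " has a non-positive response; excluded")
      next
    }
    ipos <- which.max(hhat)
    ineg <- ipos + which.min(hhat[ipos:length(hhat)]) - 1L
    est[i, ] <- c(h$t[ipos], h$t[ineg])
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  if (nrow(est) == 0L) stop("no usable ROI for timing estimation")
  out <- hrf_timing(mean(est[, 1L]), mean(est[, 2L]),
                    timing0$undershoot_ratio, timing0$dt_s)
  attr(out, "per_roi") <- est
  out
}

#' FIR HRF deconvolution
#'
#' OLS fit of the FIR (time-shifted indicator) design; the coefficients per
#' finger are the estimated HRF sampled at TR delays.
#'
#' @param fir_design a `design_matrix` from [build_fir_design()].
#' @param run a `bold_run`.
#' @param voxels optional voxel subset.
#' @return A `deconv_fit`: arrays `estimates` and `stderr` of dimension
#'   voxel x finger x lag, `lag_s`, plus the underlying `glm_fit`.
#' @export
fit_deconvolution <- function(fir_design, run, voxels = NULL) {
  stopifnot(identical(fir_design$kind, "fir"))
  fit <- fit_ols(fir_design, run, voxels)
  n_lags <- length(unique(fir_design$labels$component))
  task <- seq_len(nrow(fir_design$labels))
  est <- array(fit$beta[, task, drop = FALSE],
               c(nrow(fit$beta), n_lags, 5L))
  se <- array(fit$stderr[, task, drop = FALSE],
              c(nrow(fit$beta), n_lags, 5L))
  # columns are ordered finger-major (finger blocks of n_lags)
  est <- aperm(est, c(1L, 3L, 2L))
  se <- aperm(se, c(1L, 3L, 2L))
  structure(list(estimates = est, stderr = se,
                 lag_s = (0:(n_lags - 1L)) * fir_design$tr_s,
                 fit = fit), class = "deconv_fit")
}

#' ROI-mean deconvolved HRF curves
#'
#' @param deconv a `deconv_fit`.
#' @param rois list of `fingertip_roi`s.
#' @return Long data frame (`roi_finger`, `stim_finger`, `lag_s`, `estimate`,
#'   `stderr`), the tabular analogue of per-ROI HRF plots.
#' @export
roi_mean_hrf <- function(deconv, rois) {
  out <- list()
  for (roi in rois) {
    rows <- match(roi$voxels, deconv$fit$voxels)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) next
    for (f in 1:5) {
      out[[length(out) + 1L]] <- data.frame(
        roi_finger = roi$finger, stim_finger = f, lag_s = deconv$lag_s,
        estimate = apply(deconv$estimates[rows, f, , drop = FALSE], 3L, mean),
        stderr = apply(deconv$stderr[rows, f, , drop = FALSE], 3L, mean)
      )
    }
  }
  do.call(rbind, out)
}
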