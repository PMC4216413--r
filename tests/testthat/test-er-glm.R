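# Small helper: an exact-percent run from a phantom (avoids the temporal-mean
# rescaling of to_percent_signal on noiseless data).
exact_percent <- function(run) {
  run$data <- 100 * (run$data / 100 - 1)
  run$units <- "percent"
  run
}

test_that("OLS: exact recovery, rank errors, null t-distribution", {
  ph <- distinct_band_phantom()
  par <- make_er_paradigm(1, seed = 21)[[1]]
  run <- exact_percent(simulate_bold(ph, par, noise = silent_noise()))
  des <- build_canonical_design(par)
  fit <- fit_ols(des, run)
  # noiseless: residuals vanish and betas interpolate exactly
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(fit$dof, ncol(run$data) - 11L)  # 10 task + 1 intercept

  # duplicated column -> informative error
  des_bad <- des
  des_bad$matrix[, 2] <- 2 * des_bad$matrix[, 1]
  colnames(des_bad$matrix)[2] <- "dup"
  expect_error(fit_ols(des_bad, run), "rank deficient.*dup")

  # pure-noise voxels: t-statistics follow Student-t(dof); KS against a
  # brute-force Monte-Carlo oracle of the same linear model
  set.seed(5)
  n <- nrow(des$matrix)
  nv <- 4000
  noise_run <- flat_run(matrix(stats::rnorm(nv * n), nv, n), 2)
  nf <- fit_ols(des, noise_run)
  tstat <- nf$beta[, 1] / nf$stderr[, 1]
  X <- cbind(des$matrix, 1)
  set.seed(6)
  oracle <- replicate(4000, {
    y <- stats::rnorm(n)
    f <- stats::lm.fit(X, y)
    s2 <- sum(f$residuals^2) / (n - ncol(X))
    f$coefficients[1] / sqrt(s2 * solve(crossprod(X))[1, 1])
  })
  expect_gt(stats::ks.test(tstat, oracle)$p.value, 0.01)
  expect_gt(stats::ks.test(tstat, stats::pt, df = nf$dof)$p.value, 0.01)
})

test_that("noise ACF estimation: taper closed form, AR(1) and white-noise bounds", {
  # taper multiplier at k = M is exactly 0, at k = 0 exactly 1
  M <- 20
  w <- 0.5 * (1 + cos(pi * (0:M) / M))
  expect_equal(w[1], 1)
  expect_equal(w[M + 1], 0)

  gs <- c(20L, 20L, 1L)
  nvox <- prod(gs)
  Tn <- 10000
  des <- structure(list(matrix = matrix(0, Tn, 0),
                        labels = data.frame(finger = integer(0),
                                            component = character(0)),
                        tr_s = 2, run_lengths = Tn, kind = "canonical"),
                   class = "design_matrix")
  # AR(1) rho = 0.5 residual series shared by a whole tile
  set.seed(8)
  ar <- as.numeric(stats::filter(stats::rnorm(Tn), 0.5, "recursive"))
  fit <- structure(list(design = des,
                        residuals = matrix(rep(ar, each = nvox), nvox, Tn),
                        voxels = seq_len(nvox), grid_shape = gs),
                   class = "glm_fit")
  nm <- estimate_noise_acf(fit, array(TRUE, gs), taper_M = 30)
  expect_equal(nm$acf_raw[1, 1], 1)
  expect_lt(abs(nm$acf_raw[2, 1] - 0.5), 0.02)
  expect_equal(nm$acf_tapered[31, 1], 0)
  expect_true(all(abs(nm$acf_raw) <= 1))

  # white-noise residuals: all lag >= 1 raw ACF below 3 / sqrt(T)
  set.seed(9)
  wn <- stats::rnorm(Tn)
  fitw <- structure(list(design = des,
                         residuals = matrix(rep(wn, each = nvox), nvox, Tn),
                         voxels = seq_len(nvox), grid_shape = gs),
                    class = "glm_fit")
  nw <- estimate_noise_acf(fitw, array(TRUE, gs), taper_M = 30)
  expect_true(all(abs(nw$acf_raw[-1, 1]) < 3 / sqrt(Tn)))

  # a tile with no brain voxels inherits its nearest populated neighbour
  gs2 <- c(40L, 20L, 1L)
  brain <- array(TRUE, gs2)
  brain[21:40, , 1] <- FALSE
  fit2 <- structure(list(design = des,
                         residuals = matrix(rep(ar, each = prod(gs2)),
                                            prod(gs2), Tn),
                         voxels = seq_len(prod(gs2)), grid_shape = gs2),
                    class = "glm_fit")
  expect_message(n2 <- estimate_noise_acf(fit2, brain, taper_M = 10),
                 "inherit")
  expect_equal(n2$acf_raw[, 2], n2$acf_raw[, 1])
})

test_that("GLS equals OLS under identity noise and matches closed-form variances", {
  par <- make_er_paradigm(1, seed = 22)[[1]]
  des <- build_canonical_design(par)
  n <- nrow(des$matrix)
  set.seed(11)
  run <- flat_run(matrix(stats::rnorm(20 * n), 20, n), 2)
  f_ols <- fit_ols(des, run)
  f_gls <- fit_gls(des, run, noise = NULL)
  expect_identical(f_ols$beta, f_gls$beta)
  expect_identical(f_ols$stderr, f_gls$stderr)

  # known AR(1) correlation: GLS stderr matches (X' V^-1 X)^-1 diagonal
  rho <- 0.6
  gs <- c(2L, 2L, 1L)
  acf_true <- rho^(0:(n - 1))
  noise <- structure(list(acf_tapered = matrix(acf_true, ncol = 1),
                          taper_M = n - 1, tile_shape = c(20L, 20L),
                          tile_assignment = rep(1L, 4), grid_shape = gs),
                     class = "noise_model")
  set.seed(12)
  innov <- matrix(stats::rnorm(4 * n, sd = sqrt(1 - rho^2)), n, 4)
  eps <- apply(innov, 2, function(e)
    as.numeric(stats::filter(e, rho, "recursive",
                             init = stats::rnorm(1))))
  run2 <- bold_run(t(eps), gs, 2, units = "percent")
  fg <- fit_gls(des, run2, noise)
  V <- stats::toeplitz(acf_true)
  X <- cbind(des$matrix, 1)
  closed <- solve(t(X) %*% solve(V) %*% X)
  # per-voxel stderr = sqrt(diag(closed) * sigma2_hat)
  for (v in 1:4) {
    expect_equal(unname(fg$stderr[v, ]),
                 unname(sqrt(diag(closed) * fg$sigma2[v])), tolerance = 1e-8)
  }
})

test_that("GLS calibrates one-sided error under AR(1) noise where OLS does not", {
  # 100 x 100 x 1 grid of null AR(1) voxels, rho = 0.4, tile-estimated ACF
  par <- make_er_paradigm(1, seed = 23)[[1]]
  des <- build_canonical_design(par)
  n <- nrow(des$matrix)
  gs <- c(100L, 100L, 1L)
  nv <- prod(gs)
  rho <- 0.4
  set.seed(13)
  eps <- matrix(stats::rnorm(nv * n, sd = sqrt(1 - rho^2)), n, nv)
  eps <- apply(eps, 2, function(e)
    as.numeric(stats::filter(e, rho, "recursive",
                             init = stats::rnorm(1))))
  run <- bold_run(t(eps), gs, 2, units = "percent")
  f1 <- fit_ols(des, run)
  nm <- estimate_noise_acf(f1, array(TRUE, gs))
  fg <- fit_gls(des, run, nm)
  p_gls <- contrast_ttest(fg, 1)$p
  p_ols <- contrast_ttest(f1, 1)$p
  rate_gls <- mean(p_gls < 0.05)
  rate_ols <- mean(p_ols < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / nv)
  expect_lt(abs(rate_gls - 0.05), ci + 0.005)
  expect_gt(rate_ols, 0.05 + ci)   # naive OLS is anticonservative here
})

test_that("contrast test: symmetry at beta 0 and power at large effects", {
  par <- make_er_paradigm(1, seed = 24)[[1]]
  des <- build_canonical_design(par)
  n <- nrow(des$matrix)
  # beta exactly zero: t = 0, p = 0.5 (construct residual-orthogonal data)
  run0 <- flat_run(matrix(stats::rnorm(n), 1), 2)
  f0 <- fit_ols(des, run0)
  f0$beta[1, 1] <- 0
  tt <- contrast_ttest(f0, 1)
  expect_equal(unname(tt$t[1]), 0)
  expect_equal(unname(tt$p[1]), 0.5)
  # 10-sigma injected effect: p < 1e-6 everywhere
  set.seed(14)
  sig <- matrix(rep(des$matrix[, 1], each = 50) * 10 +
                  stats::rnorm(50 * n) * stats::sd(des$matrix[, 1]),
                50, n, byrow = FALSE)
  fs <- fit_ols(des, flat_run(sig, 2))
  expect_true(all(contrast_ttest(fs, 1)$p < 1e-6))
})

test_that("subject timing estimation recovers curve peaks", {
  ph <- distinct_band_phantom()
  pair <- localizer_pair(ph)
  cfg <- study_config(1)
  loc <- suppressMessages(run_localizer_stage(
    list(pair$fwd), list(pair$rev), 8, ph$gray_mask, ph$brain_mask, cfg))

  # beta_deriv = 0 in all ROIs: returns the peaks of the canonical curve
  # itself (numeric oracle from the closed form; the undershoot trade-off
  # moves the curve minimum past the 16 s gamma peak)
  par <- make_er_paradigm(2, seed = 25)
  runs <- lapply(par, function(p)
    exact_percent(simulate_bold(ph, p, noise = silent_noise())))
  data <- do.call(cbind, lapply(runs, `[[`, "data"))
  run_all <- bold_run(data, ph$grid_shape, 2, units = "percent")
  des <- concat_designs(lapply(par, build_canonical_design))
  fit <- fit_ols(des, run_all)
  est <- estimate_subject_timing(fit, loc$rois)
  oracle <- curve_peaks(6, 16)
  expect_equal(est$t_peak_pos_s, oracle[["pos"]], tolerance = 0.02)
  expect_equal(est$t_peak_neg_s, oracle[["neg"]], tolerance = 0.02)

  # per-ROI estimates average arithmetically
  per_roi <- attr(est, "per_roi")
  expect_equal(mean(per_roi[, 1]), est$t_peak_pos_s)

  # beta_mag = 1, beta_deriv = 0.3: peak shifts earlier; fine-grid oracle
  fine <- hrf_timing(dt_s = 0.01)
  h <- double_gamma(fine, 32)
  d <- orthogonalized_derivative(h)
  comb <- h$values + 0.3 * d
  t_oracle <- h$t[which.max(comb)]
  expect_lt(t_oracle, 6)
  fit2 <- fit
  mag_cols <- which(des$labels$component == "magnitude")
  der_cols <- which(des$labels$component == "derivative")
  fit2$beta[, mag_cols] <- 1
  fit2$beta[, der_cols] <- 0.3
  est2 <- estimate_subject_timing(fit2, loc$rois)
  expect_equal(est2$t_peak_pos_s, t_oracle, tolerance = 0.011)

  expect_error(estimate_subject_timing(
    fit, list(somatomap:::fingertip_roi(1, integer(0), ph$grid_shape, 1.5))),
    "empty")
})

test_that("FIR deconvolution: exact recovery, noise floor, linearity", {
  # generator HRF truncated to 24 s so its support fits the 13-lag window
  # (0-12 TRs); an HRF extending beyond the modelled window cannot be
  # represented by the FIR basis
  ph <- distinct_band_phantom()
  par <- make_er_paradigm(1, seed = 26)[[1]]
  run <- exact_percent(simulate_bold(ph, par, noise = silent_noise(),
                                     hrf_duration_s = 24))
  fir <- build_fir_design(par)
  dec <- fit_deconvolution(fir, run)

  # the true HRF at TR samples, scaled exactly as the generator scales it
  hrf <- double_gamma(hrf_timing(), 24)
  box <- as.numeric(seq(0, 25 - 0.1, by = 0.1) < 1)
  resp <- stats::convolve(box, rev(hrf$values), type = "open") * 0.1
  scale <- 2 / max(resp)
  true_lags <- resp[seq(1, by = 20, length.out = 13)] * scale

  v <- which.max(ph$tuning[, 3])  # near-unit tuning voxel
  expect_lt(max(abs(dec$estimates[v, 3, ] - ph$tuning[v, 3] * true_lags)),
            1e-10)
  # all fingers, all strong-tuning voxels
  for (f in 1:5) {
    vf <- which(ph$tuning[, f] > 0.8)
    expect_lt(max(abs(dec$estimates[vf, f, ] -
                        outer(ph$tuning[vf, f], true_lags))), 1e-10)
  }
  # tuning-0 voxel: estimates at the numerical noise floor
  v0 <- which.min(rowSums(ph$tuning))
  expect_lt(max(abs(dec$estimates[v0, , ])), 1e-8)
  # doubling the amplitude doubles every lag estimate
  run2 <- exact_percent(simulate_bold(ph, par, noise = silent_noise(),
                                      amplitude_percent = 4,
                                      hrf_duration_s = 24))
  dec2 <- fit_deconvolution(fir, run2)
  expect_equal(dec2$estimates, 2 * dec$estimates, tolerance = 1e-8)
})

test_that("timing recovery at SNR 5 with subject-5 generator timing", {
  # data generated with gamma timing (3.08, 9.18); the pipeline's iterated
  # two-step must recover the numeric-oracle curve peaks within 0.25 s at
  # the phantom's default SNR of 5 (and the inverted gamma parameters
  # within 0.25 s of the generator's)
  gen_timing <- hrf_timing(3.08, 9.18)
  oracle <- curve_peaks(3.08, 9.18)
  ph <- distinct_band_phantom()
  pair <- localizer_pair(ph, timing = gen_timing)
  cfg <- study_config(1)
  loc <- suppressMessages(run_localizer_stage(
    list(pair$fwd), list(pair$rev), 8, ph$gray_mask, ph$brain_mask, cfg))
  pars <- make_er_paradigm(4, seed = 31)
  runs <- lapply(seq_along(pars), function(r)
    simulate_bold(ph, pars[[r]], timing = gen_timing,
                  noise = noise_spec(sigma = 0.4, ar1_rho = 0.3,
                                     seed = 40 + r)))
  er <- suppressMessages(run_er_stage(runs, pars, loc$rois,
                                      loc$analysis_volume, ph$brain_mask,
                                      cfg))
  expect_equal(er$subject_timing$t_peak_pos_s, oracle[["pos"]],
               tolerance = 0.25)
  expect_equal(er$subject_timing$t_peak_neg_s, oracle[["neg"]],
               tolerance = 0.25)
  inv <- timing_from_peaks(er$subject_timing$t_peak_pos_s,
                           er$subject_timing$t_peak_neg_s)
  expect_equal(inv$t_peak_pos_s, 3.08, tolerance = 0.25)
  expect_equal(inv$t_peak_neg_s, 9.18, tolerance = 0.25)
})

test_that("timing inversion is consistent with the peak-time map", {
  for (tg in list(c(6, 16), c(3.78, 11.61), c(5.63, 16.41))) {
    pk <- double_gamma_peak_times(hrf_timing(tg[1], tg[2]))
    inv <- timing_from_peaks(pk[["pos"]], pk[["neg"]])
    pk2 <- double_gamma_peak_times(inv)
    expect_equal(pk2[["pos"]], pk[["pos"]], tolerance = 0.03)
    expect_equal(pk2[["neg"]], pk[["neg"]], tolerance = 0.05)
  }
})
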