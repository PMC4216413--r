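test_that("coherence and phase behave as the spectral definitions dictate", {
  tr <- 2
  n <- 160
  t <- (0:(n - 1)) * tr
  f0 <- 8  # cycles per run
  # pure sinusoid at the stimulation frequency: coherence 1, phase recovered
  x <- cos(2 * pi * f0 * t / (n * tr) - 1.3)
  run <- flat_run(rbind(x, 2 * x), tr)
  maps <- fit_sinusoid(run, f0)
  expect_equal(unname(maps$coherence), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(maps$phase), c(1.3, 1.3), tolerance = 1e-9)
  # coherence invariant to scaling; phase invariant too
  expect_equal(unname(maps$amplitude[2]), unname(2 * maps$amplitude[1]),
               tolerance = 1e-9)

  # white noise: coherence matches the Beta(1, n_freq - 1) null obtained by
  # brute-force simulation, and phase is uniform (Rayleigh test)
  set.seed(42)
  nv <- 10000
  noise <- matrix(stats::rnorm(nv * n), nv, n)
  m2 <- fit_sinusoid(flat_run(noise, tr), f0)
  # Monte-Carlo null oracle: coherence of independent white-noise series
  # computed directly from first principles (DFT ratio), different seed
  set.seed(99)
  ref <- replicate(4000, {
    X <- stats::fft(stats::rnorm(n))
    pos <- 2:(n / 2 + 1)
    abs(X[f0 + 1]) / sqrt(sum(abs(X[pos])^2))
  })
  expect_gt(suppressWarnings(stats::ks.test(m2$coherence, ref)$p.value), 0.01)
  # Rayleigh test statistic for phase uniformity
  R <- abs(mean(exp(1i * m2$phase)))
  expect_lt(nv * R^2, 7)  # ~ chi2_2 / 2 under uniformity; 7 ~ p > 0.001

  # injected sinusoid in noise at high SNR: phase recovered within 0.05
  y <- 10 * cos(2 * pi * f0 * t / (n * tr) - 1.3) + stats::rnorm(n)
  m3 <- fit_sinusoid(flat_run(matrix(y, 1), tr), f0)
  expect_equal(m3$phase[1], 1.3, tolerance = 0.05)

  expect_error(fit_sinusoid(run, n / 2), "Nyquist")
})

test_that("forward/reverse combination cancels the hemodynamic delay", {
  tr <- 2
  n <- 160
  t <- (0:(n - 1)) * tr
  f0 <- 8
  w <- 2 * pi * f0 / (n * tr)
  theta <- 2.1
  # delays up to 4 s cancel: fwd phase theta+delta, rev phase theta-delta
  for (delay_s in c(0, 1.7, 4)) {
    delta <- w * delay_s
    fwd <- flat_run(matrix(cos(w * t - theta - delta), 1), tr)
    # the reverse-order run seen forward has phase -(theta) - delta;
    # construct it so that circular time reversal aligns the cycle
    rev <- flat_run(matrix(cos(w * t + theta - delta), 1), tr)
    cmb <- combine_forward_reverse(fwd, rev)
    m <- fit_sinusoid(cmb, f0)
    expect_equal(m$phase[1], theta, tolerance = 1e-9)
  }

  # a time-symmetric series is its own reverse: output = input
  s <- cos(w * t)  # symmetric about t = 0 on the circular grid
  out <- combine_forward_reverse(flat_run(matrix(s, 1), tr),
                                 flat_run(matrix(s, 1), tr))
  expect_equal(out$data[1, ], s, tolerance = 1e-12)

  # white-noise inputs: output variance is half the input variance
  set.seed(7)
  a <- matrix(stats::rnorm(2000 * n), 2000, n)
  b <- matrix(stats::rnorm(2000 * n), 2000, n)
  cmb <- combine_forward_reverse(flat_run(a, tr), flat_run(b, tr))
  expect_equal(mean(apply(cmb$data, 1, stats::var)), 0.5, tolerance = 0.05)

  expect_error(combine_forward_reverse(flat_run(a, tr),
                                       flat_run(b[, 1:10], tr)), "match")
})

test_that("fingertip ROIs recover phantom preferred fingers (noiseless)", {
  ph <- distinct_band_phantom()
  pair <- localizer_pair(ph)
  cfg <- study_config(1)
  loc <- suppressMessages(run_localizer_stage(
    list(pair$fwd), list(pair$rev), 8, ph$gray_mask, ph$brain_mask, cfg))
  sizes <- vapply(loc$rois, function(r) length(r$voxels), 1L)
  expect_true(all(sizes > 0))
  # 100 percent of ROI voxels carry the ground-truth preferred finger
  for (r in loc$rois)
    expect_true(all(ph$preferred_finger[r$voxels] == r$finger))
  # disjoint and connected
  all_vox <- unlist(lapply(loc$rois, `[[`, "voxels"))
  expect_equal(length(all_vox), length(unique(all_vox)))

  # coherence below threshold everywhere -> five empty ROIs
  maps0 <- loc$maps
  maps0$coherence[] <- 0.1
  w <- testthat::capture_warnings(
    r0 <- define_fingertip_rois(maps0, ph$gray_mask))
  expect_length(w, 5)
  expect_true(all(grepl("empty", w)))
  expect_true(all(vapply(r0, function(r) length(r$voxels) == 0L, TRUE)))

  # phase exactly 0 goes to bin 1 (half-open convention)
  maps1 <- loc$maps
  maps1$phase[] <- 0
  maps1$coherence[] <- 0.9
  suppressMessages(r1 <- suppressWarnings(
    define_fingertip_rois(maps1, ph$gray_mask)))
  expect_gt(length(r1[[1]]$voxels), 0)
  expect_true(all(vapply(r1[2:5], function(r) length(r$voxels) == 0L, TRUE)))
})

test_that("ROI disjointness/connectivity hold across noisy seeds, and ROI size grows with SNR", {
  cfg <- study_config(1)
  sizes_by_snr <- numeric(0)
  for (s in 1:6) {
    ph <- make_somatotopic_phantom(seed = s)
    pair <- list(
      fwd = simulate_bold(ph, make_pe_paradigm(40, 8, "forward"),
                          noise = noise_spec(sigma = 1, seed = 2 * s)),
      rev = simulate_bold(ph, make_pe_paradigm(40, 8, "reverse"),
                          noise = noise_spec(sigma = 1, seed = 2 * s + 1)))
    loc <- suppressMessages(suppressWarnings(run_localizer_stage(
      list(pair$fwd), list(pair$rev), 8, ph$gray_mask, ph$brain_mask, cfg)))
    vox <- unlist(lapply(loc$rois, `[[`, "voxels"))
    expect_equal(length(vox), length(unique(vox)))  # disjoint
    for (r in loc$rois) {
      if (length(r$voxels) == 0) next
      m <- array(FALSE, ph$grid_shape)
      m[r$voxels] <- TRUE
      lab <- somatomap:::label_components(m, 6)
      expect_equal(max(lab), 1L)  # single connected component
    }
  }
  # ROI voxel counts increase with SNR at fixed threshold
  ph <- make_somatotopic_phantom(seed = 99)
  tot <- vapply(c(0.25, 1, 4), function(amp) {
    pair <- list(
      fwd = simulate_bold(ph, make_pe_paradigm(40, 8, "forward"),
                          noise = noise_spec(sigma = 1, seed = 11),
                          amplitude_percent = amp),
      rev = simulate_bold(ph, make_pe_paradigm(40, 8, "reverse"),
                          noise = noise_spec(sigma = 1, seed = 12),
                          amplitude_percent = amp))
    loc <- suppressMessages(suppressWarnings(run_localizer_stage(
      list(pair$fwd), list(pair$rev), 8, ph$gray_mask, ph$brain_mask,
      study_config(1))))
    sum(vapply(loc$rois, function(r) length(r$voxels), 1L))
  }, 1)
  expect_true(all(diff(tot) > 0))
})

test_that("analysis volume is the brain-clipped lattice-ball dilation", {
  gs <- c(21L, 21L, 21L)
  roi <- somatomap:::fingertip_roi(1, somatomap:::vox_linear(
    matrix(c(10L, 10L, 10L), 1), gs), gs, 1.5)
  brain <- array(TRUE, gs)
  vol <- build_analysis_volume(list(roi), brain, 5)
  # brute-force lattice ball count
  ijk <- somatomap:::vox_coords(gs)
  d2 <- (ijk[, 1] - 10)^2 + (ijk[, 2] - 10)^2 + (ijk[, 3] - 10)^2
  expect_equal(sort(vol), which(d2 <= 25))
  # radius 0: the ROI itself
  expect_equal(build_analysis_volume(list(roi), brain, 0), roi$voxels)
  # half-space brain mask clips the ball
  half <- brain
  half[, 1:10, ] <- FALSE
  vol_h <- build_analysis_volume(list(roi), half, 5)
  expect_equal(sort(vol_h), which(d2 <= 25 & ijk[, 2] >= 10))
})

test_that("centre of mass matches brute force and the stated convention", {
  gs <- c(10L, 10L, 10L)
  roi1 <- somatomap:::fingertip_roi(1, somatomap:::vox_linear(
    matrix(c(2L, 3L, 4L), 1), gs), gs, 1.5)
  expect_equal(roi_center_of_mass(roi1), c(3, 4.5, 6), ignore_attr = TRUE)
  # random 50-voxel set equals the brute-force mean
  set.seed(3)
  vox <- sample(prod(gs), 50)
  roi2 <- somatomap:::fingertip_roi(2, vox, gs, 2)
  expect_equal(roi_center_of_mass(roi2),
               colMeans(somatomap:::vox_unlinear(vox, gs) * 2),
               ignore_attr = TRUE)
  expect_error(roi_center_of_mass(
    somatomap:::fingertip_roi(3, integer(0), gs, 1.5)), "empty")
})
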