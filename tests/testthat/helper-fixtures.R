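# Shared synthetic fixtures, built in code at test time.

# A small noiseless world with distinct (non-overlapping) finger bands.
distinct_band_phantom <- function(seed = 3L) {
  make_somatotopic_phantom(sigma_tuning_anterior = 1.5,
                           sigma_tuning_posterior = 1.50001, seed = seed)
}

silent_noise <- function(seed = 1L) noise_spec(0, 0, 0, seed = seed)

# Noiseless forward/reverse localizer pair for a phantom.
localizer_pair <- function(phantom, cycle = 40, n_cycles = 8,
                           timing = hrf_timing(), seed = 1L) {
  list(
    fwd = simulate_bold(phantom, make_pe_paradigm(cycle, n_cycles, "forward"),
                        timing = timing, noise = silent_noise(seed)),
    rev = simulate_bold(phantom, make_pe_paradigm(cycle, n_cycles, "reverse"),
                        timing = timing, noise = silent_noise(seed + 1L))
  )
}

# Wrap a voxel x time matrix in a bold_run on a flat grid.
flat_run <- function(mat, tr_s = 2, units = "percent") {
  bold_run(mat, c(nrow(mat), 1L, 1L), tr_s = tr_s, units = units)
}

# Numeric oracle: argmax and subsequent argmin of the closed-form
# double-gamma curve on a fine grid, independent of the package's sampling.
curve_peaks <- function(t_pos, t_neg, ratio = 1 / 6, dt = 0.001) {
  t <- seq(0, 32, by = dt)
  h <- stats::dgamma(t, shape = t_pos + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = t_neg + 1, rate = 1)
  ip <- which.max(h)
  im <- ip + which.min(h[ip:length(h)]) - 1L
  c(pos = t[ip], neg = t[im])
}
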