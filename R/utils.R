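# Internal geometry / indexing helpers shared across modules.

#' @keywords internal
#' @noRd
vox_coords <- function(grid_shape) {
  # 0-based voxel indices, column-major order matching as.vector(array).
  as.matrix(expand.grid(
    i = seq_len(grid_shape[1]) - 1L,
    j = seq_len(grid_shape[2]) - 1L,
    k = seq_len(grid_shape[3]) - 1L
  ))
}

#' @keywords internal
#' @noRd
vox_linear <- function(ijk, grid_shape) {
  # ijk: matrix of 0-based indices -> 1-based linear index (column-major)
  1L + ijk[, 1L] + grid_shape[1L] * (ijk[, 2L] + grid_shape[2L] * ijk[, 3L])
}

#' @keywords internal
#' @noRd
vox_unlinear <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  i <- idx0 %% grid_shape[1L]
  j <- (idx0 %/% grid_shape[1L]) %% grid_shape[2L]
  k <- idx0 %/% (grid_shape[1L] * grid_shape[2L])
  cbind(i = i, j = j, k = k)
}

# Offsets (0-centred integer triples) within a Euclidean radius, measured either
# in voxel units (mm_scale = c(1,1,1)) or in mm (mm_scale = voxel size).
#' @keywords internal
#' @noRd
ball_offsets <- function(radius, mm_scale = c(1, 1, 1)) {
  r_vox <- floor(radius / mm_scale)
  off <- as.matrix(expand.grid(
    di = -r_vox[1L]:r_vox[1L],
    dj = -r_vox[2L]:r_vox[2L],
    dk = -r_vox[3L]:r_vox[3L]
  ))
  d2 <- (off[, 1L] * mm_scale[1L])^2 + (off[, 2L] * mm_scale[2L])^2 +
    (off[, 3L] * mm_scale[3L])^2
  off[d2 <= radius^2 + 1e-12, , drop = FALSE]
}

# Dilate a set of linear voxel indices by a set of offsets, clipped to the grid.
#' @keywords internal
#' @noRd
dilate_indices <- function(idx, offsets, grid_shape) {
  if (length(idx) == 0L) return(integer(0))
  ijk <- vox_unlinear(idx, grid_shape)
  out <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    s <- cbind(ijk[, 1L] + offsets[o, 1L],
               ijk[, 2L] + offsets[o, 2L],
               ijk[, 3L] + offsets[o, 3L])
    keep <- s[, 1L] >= 0L & s[, 1L] < grid_shape[1L] &
      s[, 2L] >= 0L & s[, 2L] < grid_shape[2L] &
      s[, 3L] >= 0L & s[, 3L] < grid_shape[3L]
    out[[o]] <- vox_linear(s[keep, , drop = FALSE], grid_shape)
  }
  sort(unique(unlist(out)))
}

# Wrap angles into (-pi, pi].
#' @keywords internal
#' @noRd
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi + 1e-15] <- pi  # map -pi to +pi so range is (-pi, pi]
  w
}

# Connected-component labelling of a logical 3D array (6- or 26-connectivity).
#' @keywords internal
#' @noRd
label_components <- function(mask, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  dims <- dim(mask)
  if (connectivity == 6) {
    nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  }
  labels <- integer(length(mask))
  current <- 0L
  todo <- which(mask)
  seen <- logical(length(mask))
  for (seed in todo) {
    if (seen[seed]) next
    current <- current + 1L
    queue <- seed
    seen[seed] <- TRUE
    while (length(queue) > 0L) {
      v <- queue
      queue <- integer(0)
      labels[v] <- current
      ijk <- vox_unlinear(v, dims)
      for (n in seq_len(nrow(nb))) {
        s <- cbind(ijk[, 1L] + nb[n, 1L], ijk[, 2L] + nb[n, 2L],
                   ijk[, 3L] + nb[n, 3L])
        keep <- s[, 1L] >= 0L & s[, 1L] < dims[1L] &
          s[, 2L] >= 0L & s[, 2L] < dims[2L] &
          s[, 3L] >= 0L & s[, 3L] < dims[3L]
        cand <- vox_linear(s[keep, , drop = FALSE], dims)
        cand <- cand[mask[cand] & !seen[cand]]
        if (length(cand)) {
          seen[cand] <- TRUE
          queue <- c(queue, cand)
        }
      }
      queue <- unique(queue)
    }
  }
  array(labels, dims)
}
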