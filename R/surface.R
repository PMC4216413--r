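# Cortical-surface utilities: mesh container, geodesic (Dijkstra) distance,
# depth projections and additive colour blending.

#' Construct a surface mesh
#'
#' @param vertices numeric n x 3 matrix of mm coordinates.
#' @param triangles optional integer m x 3 matrix of 1-based vertex indices;
#'   edges are derived from triangle sides.
#' @param edges optional integer e x 2 matrix of vertex pairs (used when no
#'   triangles are given).
#' @return A `surface_mesh` with Euclidean edge lengths.
#' @export
surface_mesh <- function(vertices, triangles = NULL, edges = NULL) {
  vertices <- as.matrix(vertices)
  if (is.null(edges)) {
    if (is.null(triangles)) stop("provide triangles or edges")
    tri <- as.matrix(triangles)
    edges <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  }
  edges <- t(apply(as.matrix(edges), 1L, sort))
  edges <- unique(edges)
  len <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                         vertices[edges[, 2L], , drop = FALSE])^2))
  if (any(len <= 0)) stop("edge lengths must be positive")
  structure(list(vertices = vertices, triangles = triangles,
                 edges = edges, edge_lengths = len),
            class = "surface_mesh")
}

#' Regular planar grid mesh (synthetic stand-in for a cortical patch)
#'
#' Builds an nx x ny vertex grid at fixed height `z_mm` in the volume's mm
#' frame, triangulated into right triangles. Used to exercise surface-based
#' distance computations on phantom studies.
#'
#' @param nx,ny vertex counts.
#' @param spacing_mm vertex spacing.
#' @param z_mm height of the plane.
#' @return A `surface_mesh`.
#' @export
make_grid_mesh <- function(nx, ny, spacing_mm = 1.5, z_mm = 0) {
  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  vertices <- cbind(g$i * spacing_mm, g$j * spacing_mm, z_mm)
  id <- function(i, j) i + nx * j + 1L
  tris <- list()
  for (j in 0:(ny - 2L)) for (i in 0:(nx - 2L)) {
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
    tris[[length(tris) + 1L]] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  surface_mesh(vertices, do.call(rbind, tris))
}

#' Geodesic (Dijkstra) distance between two mesh vertices
#'
#' Length of the shortest edge path; respects the folding geometry that a
#' straight-line (Euclidean) distance ignores.
#'
#' @param mesh a `surface_mesh`.
#' @param v_start,v_end vertex ids.
#' @return Distance in mm.
#' @export
dijkstra_distance <- function(mesh, v_start, v_end) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = mesh$edge_lengths)
  d <- igraph::distances(g, v = v_start, to = v_end)[1L, 1L]
  if (!is.finite(d)) stop("vertices are in different connected components")
  d
}

#' Nearest mesh vertex to a point
#'
#' Ties are broken by the lowest vertex id (logged).
#'
#' @param mesh a `surface_mesh`.
#' @param point_mm length-3 mm coordinates.
#' @return Vertex id.
#' @export
nearest_vertex <- function(mesh, point_mm) {
  d2 <- rowSums(sweep(mesh$vertices, 2L, point_mm, `-`)^2)
  i <- which.min(d2)
  if (sum(abs(d2 - d2[i]) < 1e-12) > 1L)
    message("nearest_vertex: tie broken by lowest id")
  i
}

#' Maximum-intensity projection across cortical depths
#'
#' @param stack numeric vertex x depth matrix (11 depths: white/gray
#'   interface, 9 intermediates, pial surface); NAs mark missing depths.
#' @return Per-vertex maximum over available depths (NA when all missing).
#' @export
depth_max_projection <- function(stack) {
  stack <- as.matrix(stack)
  if (ncol(stack) != 11L)
    warning("depth stack has ", ncol(stack), " depths, expected 11")
  apply(stack, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}

#' Phase of the complex average across cortical depths
#'
#' `arg(sum_d A_d * exp(1i * phi_d))`, mapped to `[0, 2*pi)`; vertices with
#' zero total amplitude get NA.
#'
#' @param amp_stack,phase_stack congruent vertex x depth matrices.
#' @return Per-vertex phase in `[0, 2*pi)`.
#' @export
depth_phase_average <- function(amp_stack, phase_stack) {
  amp_stack <- as.matrix(amp_stack)
  phase_stack <- as.matrix(phase_stack)
  stopifnot(identical(dim(amp_stack), dim(phase_stack)))
  z <- rowSums(amp_stack * exp(1i * phase_stack), na.rm = TRUE)
  out <- Arg(z) %% (2 * pi)
  out[abs(z) == 0] <- NA_real_
  out
}

#' Construct an RGBA layer
#'
#' @param rgb n x 3 matrix of colour channels in `[0, 1]`.
#' @param alpha per-pixel transparency in `[0, 1]`.
#' @return An `rgba_layer`.
#' @export
rgba_layer <- function(rgb, alpha = 1) {
  rgb <- as.matrix(rgb)
  alpha <- rep(alpha, length.out = nrow(rgb))
  if (any(rgb < 0 | rgb > 1) || any(alpha < 0 | alpha > 1))
    stop("channels and alpha must lie in [0, 1]")
  structure(list(rgb = rgb, alpha = alpha), class = "rgba_layer")
}

#' Additively blend activation map layers
#'
#' Each layer's channels are premultiplied by its alpha, then layers are
#' folded pairwise with `C = C_A * (1 - C_B) + C_B` per channel (equivalently
#' `C_A + C_B - C_A * C_B`, commutative and associative, so the fold order is
#' irrelevant) and clamped to `[0, 1]`. Voxels activated by several
#' conditions converge toward white.
#'
#' @param layers ordered list of `rgba_layer`s.
#' @return n x 3 composite RGB matrix.
#' @export
blend_layers <- function(layers) {
  stopifnot(length(layers) >= 1L)
  pm <- lapply(layers, function(l) l$rgb * l$alpha)
  out <- Reduce(function(a, b) a * (1 - b) + b, pm)
  pmin(pmax(out, 0), 1)
}
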