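# Discrete Laplacians on the cytoplasm voxel grid and the SR strand network.

# n_vox x 6 matrix of field indices of the 6-neighbours of every cytoplasm
# voxel (0 where the neighbour is outside the cytoplasm: zero-flux boundary).
build_grid_neighbors <- function(mask) {
  dims <- dim(mask)
  vox <- which(mask)
  fidx <- integer(prod(dims))
  fidx[vox] <- seq_along(vox)
  co <- vox_coords(vox, dims)
  nb <- matrix(0L, nrow = length(vox), ncol = 6)
  colc <- 0L
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    colc <- colc + 1L
    cc <- co
    cc[, ax] <- cc[, ax] + s
    inside <- cc[, ax] >= 0L & cc[, ax] < dims[ax]
    idx <- lin_index(cc[inside, 1], cc[inside, 2], cc[inside, 3], dims)
    nb[inside, colc] <- fidx[idx]     # 0 when outside the cytoplasm mask
  }
  nb
}

#' Six-neighbour finite-difference Laplacian on the cytoplasm grid
#'
#' Second difference over the 6 face neighbours with zero-flux (reflecting)
#' boundaries: a missing neighbour contributes nothing, so a uniform field
#' has zero Laplacian everywhere and diffusion conserves mass.
#'
#' @param field numeric vector over cytoplasm voxels (mask order) or a 3-D
#'   array on the full grid.
#' @param geom a `cell_geometry`.
#' @return Laplacian in the same shape as `field` (1/um^2 units times field).
#' @export
laplacian_grid <- function(field, geom) {
  as_array <- is.array(field)
  f <- if (as_array) field[geom$mask] else field
  stopifnot(length(f) == sum(geom$mask))
  nb <- geom$nbr_cache %||% build_grid_neighbors(geom$mask)
  h2 <- geom$pitch_um^2
  lap <- numeric(length(f))
  for (cc in 1:6) {
    has <- nb[, cc] > 0L
    lap[has] <- lap[has] + (f[nb[has, cc]] - f[has])
  }
  lap <- lap / h2
  if (as_array) {
    out <- array(0, dim = geom$dims)
    out[geom$mask] <- lap
    out
  } else lap
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Graph Laplacian on the SR strand network
#'
#' Coupling occurs only through the explicit neighbour list: nodes that are
#' spatially adjacent but not linked exchange nothing.
#'
#' @param field numeric vector over strand nodes.
#' @param net a `strand_network`.
#' @return Per-node Laplacian (spacing taken as the lattice pitch).
#' @export
laplacian_network <- function(field, net) {
  stopifnot(length(field) == nrow(net$coords))
  h2 <- net$pitch_um^2
  lap <- numeric(length(field))
  deg <- lengths(net$nbr)
  sum_nb <- vapply(seq_along(field), function(q) {
    w <- net$nbr[[q]]
    if (length(w)) sum(field[w]) else 0
  }, numeric(1))
  (sum_nb - deg * field) / h2
}
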