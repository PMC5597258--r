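#' Skeletonize a 3-D binary mask to one-voxel-wide strands
#'
#' Sequential 3-D medial-axis (curve) thinning: simple border voxels are
#' deleted in ascending lexicographic order until no deletable voxel remains;
#' endpoints are preserved. Deterministic for a given mask.
#'
#' @param mask logical 3-D array.
#' @return logical 3-D array of the same dimensions containing the skeleton.
#' @export
skeletonize_3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  skeletonize3d_cpp(mask, as.integer(dim(mask)))
}

#' Reduce the full-resolution SR to a 3-D network of 1-D strands
#'
#' The SR component of a full-resolution volume is thinned to one-voxel-wide
#' strands, and the skeleton is mapped onto the coarse simulation lattice.
#' A coarse node exists wherever at least one skeleton voxel maps into a
#' coarse voxel; a link between coarse nodes (i, j) exists iff two 26-adjacent
#' skeleton voxels map one into i and one into j with i and j 6-adjacent on
#' the coarse lattice. Spatially adjacent nodes without such a skeleton
#' connection are NOT coupled. Each node is assigned the same volume, the
#' total full-resolution SR volume divided by the node count, so the reduction
#' conserves SR volume exactly.
#'
#' @param vol a `full_res_volume`.
#' @param coarse_pitch_nm isotropic coarse lattice pitch in nm (default 350).
#' @return A `strand_network`: list with `coords` (n x 3, 0-based coarse voxel
#'   indices), `nbr` (adjacency list), `node_voxel` (1-based linear indices
#'   into the coarse grid), `v_vox_nsr` (um^3 per node), `coarse_dims`,
#'   `pitch_um`, `total_sr_volume_um3`, `n_components`.
#' @export
reduce_sr_to_strands <- function(vol, coarse_pitch_nm = 350) {
  stopifnot(inherits(vol, "full_res_volume"))
  sr_mask <- vol$flags == 2L | vol$flags == 3L
  if (!any(sr_mask)) stop("volume contains no SR voxels")
  dims <- vol$dims
  total_vol <- sum(sr_mask) * prod(vol$pitch_nm) / 1e9  # um^3

  skel <- skeletonize_3d(array(sr_mask, dim = dims))
  skel_idx <- which(skel)
  co <- vox_coords(skel_idx, dims)

  cdims <- as.integer(ceiling(dims * vol$pitch_nm / coarse_pitch_nm))
  cc <- cbind(pmin(cdims[1] - 1L, as.integer(floor(co[, 1] * vol$pitch_nm[1] / coarse_pitch_nm))),
              pmin(cdims[2] - 1L, as.integer(floor(co[, 2] * vol$pitch_nm[2] / coarse_pitch_nm))),
              pmin(cdims[3] - 1L, as.integer(floor(co[, 3] * vol$pitch_nm[3] / coarse_pitch_nm))))
  cvox <- lin_index(cc[, 1], cc[, 2], cc[, 3], cdims)

  node_voxel <- sort(unique(cvox))
  node_of_cvox <- integer(prod(cdims))
  node_of_cvox[node_voxel] <- seq_along(node_voxel)
  node_id <- node_of_cvox[cvox]          # per skeleton voxel
  n_nodes <- length(node_voxel)

  # skeleton adjacency across coarse boundaries -> links
  skel_lin <- rep(0L, prod(dims))
  skel_lin[skel_idx] <- seq_along(skel_idx)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[order(offs$dz, offs$dy, offs$dx), ][1:13, ]  # half the offsets
  pairs <- list()
  for (r in seq_len(nrow(offs))) {
    i <- co[, 1] + offs$dx[r]; j <- co[, 2] + offs$dy[r]; k <- co[, 3] + offs$dz[r]
    ok <- i >= 0 & j >= 0 & k >= 0 & i < dims[1] & j < dims[2] & k < dims[3]
    nb <- integer(length(skel_idx))
    nb[ok] <- skel_lin[lin_index(i[ok], j[ok], k[ok], dims)]
    hit <- which(nb > 0L)
    if (length(hit))
      pairs[[length(pairs) + 1L]] <- cbind(hit, nb[hit])
  }
  links <- matrix(integer(0), ncol = 2)
  if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    na <- node_id[pr[, 1]]; nb <- node_id[pr[, 2]]
    diffnode <- na != nb
    if (any(diffnode)) {
      na <- na[diffnode]; nb <- nb[diffnode]
      d <- abs(vox_coords(node_voxel[na], cdims) - vox_coords(node_voxel[nb], cdims))
      face <- rowSums(d) == 1L       # 6-adjacent on the coarse lattice only
      links <- cbind(na[face], nb[face])
    }
  }
  nbr <- links_to_adj(links, n_nodes)
  comp <- adj_components(nbr)

  structure(list(
    coords = vox_coords(node_voxel, cdims),
    nbr = nbr,
    node_voxel = node_voxel,
    v_vox_nsr = total_vol / n_nodes,
    coarse_dims = cdims,
    pitch_um = coarse_pitch_nm / 1000,
    total_sr_volume_um3 = total_vol,
    n_components = max(comp),
    component = comp
  ), class = "strand_network")
}

#' @export
print.strand_network <- function(x, ...) {
  cat("strand_network:", nrow(x$coords), "nodes,", n_links(x$nbr), "links,",
      x$n_components, "component(s)\n")
  cat("  coarse grid:", paste(x$coarse_dims, collapse = " x "), "@",
      x$pitch_um, "um; v_vox_nsr =", signif(x$v_vox_nsr, 4), "um^3\n")
  invisible(x)
}
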