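#' Synthesize a full-resolution voxel volume of t-tubules, SR and jSR markers
#'
#' Generates a binary voxel volume emulating the morphology of serial
#' block-face electron-microscopy reconstructions of a ventricular myocyte
#' portion: a regular-with-jitter lattice of transverse tubules (in-plane
#' tubes at z-disk planes plus sparse longitudinal connectors), a spanning
#' mesh of thin sarcoplasmic-reticulum strands, and junctional-SR markers
#' placed stochastically at SR voxels apposed to the t-tubule membrane.
#'
#' Voxel flags are mutually exclusive: 0 background, 1 t-tubule, 2 network SR,
#' 3 jSR marker (a jSR marker voxel is SR tissue carrying a dyad marker).
#'
#' @param dims integer length-3 lattice size (x, y, z).
#' @param pitch_nm numeric length-3 voxel pitch in nm per axis. The default
#'   emulates the 13.5 x 13.5 x 50 nm class of SBF-SEM acquisitions; coarser
#'   pitches are accepted for smaller test volumes.
#' @param tt_spacing t-tubule lattice spacing in um (z-disk period and
#'   in-plane tube spacing).
#' @param sr_strand_spacing SR strand lattice spacing in um.
#' @param jsr_rate probability in [0, 1] that a TT-adjacent SR voxel carries a
#'   jSR marker.
#' @param seed integer seed; identical arguments and seed give identical
#'   volumes.
#' @param tt_radius_nm,sr_radius_nm tube radii in nm.
#' @param jitter_frac relative jitter applied to lattice positions.
#' @return An object of class `full_res_volume`: list with `flags` (integer
#'   3-D array), `pitch_nm`, `dims`, and `meta` (including `extent_um`).
#' @export
synthesize_structure <- function(dims, pitch_nm = c(13.5, 13.5, 50),
                                 tt_spacing = 1.8, sr_strand_spacing = 0.7,
                                 jsr_rate = 0.1, seed = 1,
                                 tt_radius_nm = 130, sr_radius_nm = 40,
                                 jitter_frac = 0.08) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), length(pitch_nm) == 3,
            all(pitch_nm > 0))
  if (jsr_rate < 0 || jsr_rate > 1) stop("jsr_rate must be in [0, 1]")
  if (tt_spacing * 1000 < max(pitch_nm))
    stop("tt_spacing (", tt_spacing, " um) is smaller than the voxel pitch; ",
         "tube lattices cannot be resolved at this resolution")
  if (sr_strand_spacing * 1000 < max(pitch_nm))
    stop("sr_strand_spacing (", sr_strand_spacing,
         " um) is smaller than the voxel pitch")

  extent_um <- dims * pitch_nm / 1000
  flags <- array(0L, dim = dims)

  with_local_seed(seed, {
    r_vox <- pmax(0L, as.integer(floor(tt_radius_nm / pitch_nm)))
    rs_vox <- pmax(0L, as.integer(floor(sr_radius_nm / pitch_nm)))

    jit <- function(x, period) x + runif(length(x), -1, 1) * jitter_frac * period
    lattice_um <- function(extent, period) {
      p <- seq(period / 2, extent, by = period)
      if (!length(p)) p <- extent / 2
      jit(p, period)
    }
    to_vox <- function(pos_um, axis) {
      v <- as.integer(floor(pos_um * 1000 / pitch_nm[axis]))
      v[v >= 0 & v < dims[axis]]
    }
    span <- function(centre, r, axis) {
      max(0L, centre - r):min(dims[axis] - 1L, centre + r)
    }

    # --- transverse-tubule lattice -------------------------------------
    z_disks <- to_vox(lattice_um(extent_um[3], tt_spacing), 3)
    ypos_all <- list(); xpos_all <- list()
    for (kz in z_disks) {
      zz <- span(kz, r_vox[3], 3) + 1L
      ypos <- to_vox(lattice_um(extent_um[2], tt_spacing), 2)
      xpos <- to_vox(lattice_um(extent_um[1], tt_spacing), 1)
      ypos_all[[length(ypos_all) + 1L]] <- ypos
      xpos_all[[length(xpos_all) + 1L]] <- xpos
      for (yc in ypos) flags[, span(yc, r_vox[2], 2) + 1L, zz] <- 1L
      for (xc in xpos) flags[span(xc, r_vox[1], 1) + 1L, , zz] <- 1L
    }
    # sparse longitudinal connectors at alternating lattice crossings
    if (length(z_disks)) {
      yl <- ypos_all[[1]]; xl <- xpos_all[[1]]
      for (iy in seq_along(yl)) for (ix in seq_along(xl)) {
        if ((ix + iy) %% 2L != 0L) next
        flags[span(xl[ix], r_vox[1], 1) + 1L,
              span(yl[iy], r_vox[2], 2) + 1L, ] <- 1L
      }
    }

    # --- SR strand mesh (assigned only to non-TT voxels) ----------------
    put_sr <- function(ix, iy, iz) {
      blk <- flags[ix, iy, iz, drop = FALSE]
      blk[blk == 0L] <- 2L
      flags[ix, iy, iz] <<- blk
    }
    sx <- to_vox(lattice_um(extent_um[1], sr_strand_spacing), 1)
    sy <- to_vox(lattice_um(extent_um[2], sr_strand_spacing), 2)
    sz <- to_vox(lattice_um(extent_um[3], sr_strand_spacing), 3)
    # longitudinal strands (along z) on the x-y lattice
    for (xc in sx) for (yc in sy)
      put_sr(span(xc, rs_vox[1], 1) + 1L, span(yc, rs_vox[2], 2) + 1L,
             seq_len(dims[3]))
    # in-plane strands on the z lattice
    for (zc in sz) {
      zz <- span(zc, rs_vox[3], 3) + 1L
      for (yc in sy) put_sr(seq_len(dims[1]), span(yc, rs_vox[2], 2) + 1L, zz)
      for (xc in sx) put_sr(span(xc, rs_vox[1], 1) + 1L, seq_len(dims[2]), zz)
    }

    # --- jSR markers at SR voxels 26-adjacent to a TT voxel -------------
    cand <- tt_adjacent_sr(flags, dims)
    if (length(cand) && jsr_rate > 0) {
      hit <- cand[runif(length(cand)) < jsr_rate]
      flags[hit] <- 3L
    }
  })

  structure(list(
    flags = flags, pitch_nm = as.numeric(pitch_nm), dims = dims,
    meta = list(extent_um = extent_um, tt_spacing = tt_spacing,
                sr_strand_spacing = sr_strand_spacing, jsr_rate = jsr_rate,
                seed = seed)
  ), class = "full_res_volume")
}

#' Construct a full-resolution volume from a flag array
#'
#' Builds a `full_res_volume` from an explicit flag array (0 background,
#' 1 t-tubule, 2 network SR, 3 jSR marker), validating the type invariants:
#' flags are mutually exclusive by construction, the pitch must be strictly
#' positive and the lattice at least one voxel per axis.
#'
#' @param flags integer 3-D array of voxel flags in `0:3`.
#' @param pitch_nm numeric length-3 voxel pitch in nm.
#' @return A `full_res_volume`.
#' @export
full_res_volume <- function(flags, pitch_nm) {
  dims <- dim(flags)
  stopifnot(length(dims) == 3, all(dims >= 1), length(pitch_nm) == 3,
            all(pitch_nm > 0), all(flags %in% 0:3))
  structure(list(
    flags = array(as.integer(flags), dim = dims),
    pitch_nm = as.numeric(pitch_nm), dims = as.integer(dims),
    meta = list(extent_um = dims * pitch_nm / 1000)
  ), class = "full_res_volume")
}

# linear indices of SR voxels having a TT voxel in their 26-neighbourhood
tt_adjacent_sr <- function(flags, dims) {
  sr_idx <- which(flags == 2L | flags == 3L)
  if (!length(sr_idx)) return(integer(0))
  co <- vox_coords(sr_idx, dims)
  near_tt <- rep(FALSE, length(sr_idx))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    i <- co[, 1] + dx; j <- co[, 2] + dy; k <- co[, 3] + dz
    ok <- i >= 0 & j >= 0 & k >= 0 & i < dims[1] & j < dims[2] & k < dims[3]
    idx <- lin_index(i[ok], j[ok], k[ok], dims)
    hit <- which(ok)[flags[idx] == 1L]
    near_tt[hit] <- TRUE
  }
  sr_idx[near_tt]
}

#' @export
print.full_res_volume <- function(x, ...) {
  cat("full_res_volume:", paste(x$dims, collapse = " x "), "voxels @",
      paste(x$pitch_nm, collapse = " x "), "nm\n")
  cat("  extent:", paste(round(x$meta$extent_um, 3), collapse = " x "), "um\n")
  tab <- tabulate(x$flags + 1L, nbins = 4L)
  cat("  voxels: background", tab[1], "| TT", tab[2], "| SR", tab[3],
      "| jSR markers", tab[4], "\n")
  invisible(x)
}
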