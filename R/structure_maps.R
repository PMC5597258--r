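#' Derive coarse simulation maps from a full-resolution volume
#'
#' Builds the coarse-lattice cell geometry used by the simulator: the
#' cytoplasm occupancy grid (the volume enclosed by the outer surface,
#' down-sampled to the coarse pitch), the surface-sarcolemma map `SS_M`
#' (outer-shell voxels), the t-tubule map `TT_M` (cytoplasm voxels
#' intersecting TT flags), the SR strand network (via
#' [reduce_sr_to_strands()]), and the dyad map (coarse voxels containing at
#' least one jSR marker; markers falling in the same coarse voxel merge into
#' one dyad). Each dyad is attached to the SR node in its own voxel when one
#' exists, otherwise to the nearest node of the network.
#'
#' @param vol a `full_res_volume`.
#' @param coarse_pitch_nm coarse lattice pitch in nm (default 350, isotropic).
#' @param v_cyto_vox cytoplasm volume per coarse voxel in um^3. The default
#'   0.0314 um^3 is ~75% of (0.35 um)^3, accounting for mitochondria and
#'   myofilaments.
#' @param v_ds,v_jsr dyadic cleft and jSR volumes per dyad (um^3).
#' @param n_ryr,n_ltcc channel counts per dyad (homogeneous defaults 100, 15).
#' @return A `cell_geometry` object.
#' @export
derive_maps <- function(vol, coarse_pitch_nm = 350, v_cyto_vox = 0.0314,
                        v_ds = 1e-3, v_jsr = 2e-2, n_ryr = 100L, n_ltcc = 15L) {
  stopifnot(inherits(vol, "full_res_volume"))
  dims <- vol$dims
  cdims <- as.integer(ceiling(dims * vol$pitch_nm / coarse_pitch_nm))
  if (prod(cdims) < 1) stop("no cytoplasm voxels at this coarse pitch")
  mask <- array(TRUE, dim = cdims)

  coarse_of <- function(idx) {
    co <- vox_coords(idx, dims)
    cc <- cbind(pmin(cdims[1] - 1L, as.integer(floor(co[, 1] * vol$pitch_nm[1] / coarse_pitch_nm))),
                pmin(cdims[2] - 1L, as.integer(floor(co[, 2] * vol$pitch_nm[2] / coarse_pitch_nm))),
                pmin(cdims[3] - 1L, as.integer(floor(co[, 3] * vol$pitch_nm[3] / coarse_pitch_nm))))
    lin_index(cc[, 1], cc[, 2], cc[, 3], cdims)
  }

  tt_m <- sort(unique(coarse_of(which(vol$flags == 1L))))
  ss_m <- shell_voxels(mask)

  sr <- if (any(vol$flags == 2L | vol$flags == 3L))
    reduce_sr_to_strands(vol, coarse_pitch_nm) else NULL

  jsr_vox <- sort(unique(coarse_of(which(vol$flags == 3L))))
  dyads <- make_dyad_table(jsr_vox, cdims, sr, v_ds, v_jsr, n_ryr, n_ltcc)

  structure(list(
    dims = cdims, pitch_um = coarse_pitch_nm / 1000, mask = mask,
    v_cyto_vox = v_cyto_vox, ss_m = ss_m, tt_m = tt_m, sr = sr,
    dyads = dyads, mode = "detailed",
    meta = list(source_dims = dims, source_pitch_nm = vol$pitch_nm)
  ), class = "cell_geometry")
}

make_dyad_table <- function(voxels, cdims, sr, v_ds, v_jsr, n_ryr, n_ltcc) {
  n <- length(voxels)
  co <- vox_coords(voxels, cdims)
  sr_node <- rep(NA_integer_, n)
  if (!is.null(sr) && n) {
    node_of_vox <- integer(prod(cdims))
    node_of_vox[sr$node_voxel] <- seq_along(sr$node_voxel)
    sr_node <- node_of_vox[voxels]
    missing <- which(sr_node == 0L)
    for (m in missing) {  # attach to the nearest strand node
      d2 <- colSums((t(sr$coords) - co[m, ])^2)
      sr_node[m] <- which.min(d2)
    }
  }
  data.frame(voxel = as.integer(voxels), i = co[, 1], j = co[, 2], k = co[, 3],
             sr_node = as.integer(sr_node), v_ds = rep(v_ds, n),
             v_jsr = rep(v_jsr, n), n_ryr = rep(as.integer(n_ryr), n),
             n_ltcc = rep(as.integer(n_ltcc), n))
}

# outer-shell voxels of an occupancy mask (1-based linear indices)
shell_voxels <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  co <- vox_coords(idx, dims)
  shell <- rep(FALSE, length(idx))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- co
    nb[, ax] <- nb[, ax] + s
    out <- nb[, ax] < 0L | nb[, ax] >= dims[ax]
    inside <- !out
    nbidx <- lin_index(nb[inside, 1], nb[inside, 2], nb[inside, 3], dims)
    shell[out] <- TRUE
    shell[which(inside)[!mask[nbidx]]] <- TRUE
  }
  idx[shell]
}

#' Dyad, SR and membrane mapping functions
#'
#' Accessors for the mapping functions relating dyads (`theta`), SR strand
#' nodes (`theta_sr`) and membrane voxels (`theta_mem`) to cytoplasm voxel
#' indices, with their inverses. All maps satisfy
#' `theta_inv(theta(m)) == m` on their domains.
#'
#' @param geom a `cell_geometry`.
#' @return A list of vectorised functions `theta`, `theta_inv`, `theta_sr`,
#'   `theta_sr_inv`, `theta_mem`, `theta_mem_inv` (inverses return `NA` off
#'   their domain).
#' @export
theta_maps <- function(geom) {
  nvox <- prod(geom$dims)
  dy_inv <- integer(nvox)
  dy_inv[geom$dyads$voxel] <- seq_len(nrow(geom$dyads))
  mem <- sort(unique(c(geom$ss_m, geom$tt_m)))
  mem_inv <- integer(nvox)
  mem_inv[mem] <- seq_along(mem)
  sr_inv <- integer(nvox)
  if (!is.null(geom$sr)) sr_inv[geom$sr$node_voxel] <- seq_along(geom$sr$node_voxel)
  na_if0 <- function(x) { x[x == 0L] <- NA_integer_; x }
  list(
    theta = function(m) geom$dyads$voxel[m],
    theta_inv = function(n) na_if0(dy_inv[n]),
    theta_sr = function(q) geom$sr$node_voxel[q],
    theta_sr_inv = function(n) na_if0(sr_inv[n]),
    theta_mem = function(p) mem[p],
    theta_mem_inv = function(n) na_if0(mem_inv[n])
  )
}

#' Tessellate a quarter cross-section into a whole-cell geometry
#'
#' Reflects the quarter portion in the two cross-sectional planes to build a
#' full cross-section, then mirrors the cross-section `n_long` times along the
#' longitudinal (z) axis. All maps are transformed consistently: membrane and
#' dyad maps are reflected with the grid, the surface-sarcolemma map is
#' recomputed on the tessellated grid (seam faces are interior), and SR strand
#' links are created across every reflection seam between mirror-adjacent
#' nodes so the network SR is continuous along the cell.
#'
#' @param quarter a `cell_geometry` (the quarter portion).
#' @param n_long number of longitudinal copies (>= 1); the output z-dimension
#'   is `n_long` times the input z-dimension.
#' @return A `cell_geometry` of dimensions `(2 nx, 2 ny, n_long * nz)`.
#' @export
tessellate_whole_cell <- function(quarter, n_long) {
  stopifnot(inherits(quarter, "cell_geometry"), n_long >= 1)
  n_long <- as.integer(n_long)
  d <- quarter$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cs_dims <- c(2L * nx, 2L * ny, nz)
  out_dims <- c(2L * nx, 2L * ny, n_long * nz)

  # --- occupancy mask -------------------------------------------------
  q <- quarter$mask
  rev1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  rev2 <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
  rev3 <- function(a) a[, , dim(a)[3]:1, drop = FALSE]
  cs <- array(FALSE, cs_dims)
  cs[1:nx, 1:ny, ] <- q
  cs[(nx + 1):(2 * nx), 1:ny, ] <- rev1(q)
  cs[1:nx, (ny + 1):(2 * ny), ] <- rev2(q)
  cs[(nx + 1):(2 * nx), (ny + 1):(2 * ny), ] <- rev1(rev2(q))
  mask <- array(FALSE, out_dims)
  for (cpy in seq_len(n_long) - 1L) {
    blk <- if (cpy %% 2L == 0L) cs else rev3(cs)
    mask[, , (cpy * nz + 1):((cpy + 1) * nz)] <- blk
  }

  # coordinate transforms (0-based coords)
  quad_tf <- function(co, qd) {
    if (qd == 2L || qd == 4L) co[, 1] <- 2L * nx - 1L - co[, 1]
    if (qd == 3L || qd == 4L) co[, 2] <- 2L * ny - 1L - co[, 2]
    co
  }
  long_tf <- function(co, cpy) {
    co[, 3] <- if (cpy %% 2L == 0L) cpy * nz + co[, 3] else
      cpy * nz + (nz - 1L - co[, 3])
    co
  }
  tf_all <- function(co) {
    out <- vector("list", 4L * n_long)
    t <- 0L
    for (cpy in seq_len(n_long) - 1L) for (qd in 1:4) {
      t <- t + 1L
      out[[t]] <- long_tf(quad_tf(co, qd), cpy)
    }
    do.call(rbind, out)
  }

  # --- TT map ---------------------------------------------------------
  tt_co <- vox_coords(quarter$tt_m, d)
  tt_m <- if (length(quarter$tt_m))
    sort(unique(lin_index_m(tf_all(tt_co), out_dims))) else integer(0)

  # --- SR strand network ---------------------------------------------
  sr <- if (!is.null(quarter$sr))
    tessellate_network(quarter$sr, d, n_long, out_dims) else NULL

  # --- dyads ----------------------------------------------------------
  dy <- quarter$dyads
  n0 <- if (!is.null(quarter$sr)) nrow(quarter$sr$coords) else 0L
  dyads_list <- list()
  t <- 0L
  for (cpy in seq_len(n_long) - 1L) for (qd in 1:4) {
    t <- t + 1L
    co <- long_tf(quad_tf(cbind(dy$i, dy$j, dy$k), qd), cpy)
    block <- dy
    block$i <- co[, 1]; block$j <- co[, 2]; block$k <- co[, 3]
    block$voxel <- lin_index(co[, 1], co[, 2], co[, 3], out_dims)
    if (n0 > 0L) block$sr_node <- dy$sr_node + (t - 1L) * n0
    dyads_list[[t]] <- block
  }
  dyads <- do.call(rbind, dyads_list)
  dyads <- dyads[order(dyads$voxel), , drop = FALSE]
  rownames(dyads) <- NULL

  structure(list(
    dims = out_dims, pitch_um = quarter$pitch_um, mask = mask,
    v_cyto_vox = quarter$v_cyto_vox, ss_m = shell_voxels(mask), tt_m = tt_m,
    sr = sr, dyads = dyads, mode = quarter$mode,
    meta = c(quarter$meta, list(n_long = n_long, quarter_dims = d))
  ), class = "cell_geometry")
}

lin_index_m <- function(co, dims) lin_index(co[, 1], co[, 2], co[, 3], dims)

tessellate_network <- function(net, d, n_long, out_dims) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n0 <- nrow(net$coords)
  links0 <- adj_to_links(net$nbr)
  co0 <- net$coords

  # cross-section: 4 reflected copies + seam links
  cs_coords <- vector("list", 4)
  cs_links <- list()
  for (qd in 1:4) {
    co <- co0
    if (qd == 2L || qd == 4L) co[, 1] <- 2L * nx - 1L - co[, 1]
    if (qd == 3L || qd == 4L) co[, 2] <- 2L * ny - 1L - co[, 2]
    cs_coords[[qd]] <- co
    if (nrow(links0)) cs_links[[length(cs_links) + 1L]] <- links0 + (qd - 1L) * n0
  }
  bx <- which(co0[, 1] == nx - 1L)   # x seam
  by <- which(co0[, 2] == ny - 1L)   # y seam
  if (length(bx)) {
    cs_links[[length(cs_links) + 1L]] <- cbind(bx, bx + n0)            # Q1-Q2
    cs_links[[length(cs_links) + 1L]] <- cbind(bx + 2L * n0, bx + 3L * n0)  # Q3-Q4
  }
  if (length(by)) {
    cs_links[[length(cs_links) + 1L]] <- cbind(by, by + 2L * n0)       # Q1-Q3
    cs_links[[length(cs_links) + 1L]] <- cbind(by + n0, by + 3L * n0)  # Q2-Q4
  }
  cs_co <- do.call(rbind, cs_coords)
  cs_ln <- if (length(cs_links)) do.call(rbind, cs_links) else matrix(integer(0), ncol = 2)
  n1 <- 4L * n0

  # longitudinal copies + seam links
  all_coords <- vector("list", n_long)
  all_links <- list()
  for (cpy in seq_len(n_long) - 1L) {
    co <- cs_co
    co[, 3] <- if (cpy %% 2L == 0L) cpy * nz + co[, 3] else
      cpy * nz + (nz - 1L - co[, 3])
    all_coords[[cpy + 1L]] <- co
    if (nrow(cs_ln)) all_links[[length(all_links) + 1L]] <- cs_ln + cpy * n1
    if (cpy < n_long - 1L) {
      kb <- if (cpy %% 2L == 0L) nz - 1L else 0L
      bz <- which(cs_co[, 3] == kb)
      if (length(bz))
        all_links[[length(all_links) + 1L]] <-
          cbind(bz + cpy * n1, bz + (cpy + 1L) * n1)
    }
  }
  coords <- do.call(rbind, all_coords)
  links <- if (length(all_links)) do.call(rbind, all_links) else matrix(integer(0), ncol = 2)
  nbr <- links_to_adj(links, nrow(coords))
  comp <- adj_components(nbr)

  structure(list(
    coords = coords, nbr = nbr,
    node_voxel = lin_index_m(coords, out_dims),
    v_vox_nsr = net$v_vox_nsr,
    coarse_dims = out_dims, pitch_um = net$pitch_um,
    total_sr_volume_um3 = net$v_vox_nsr * nrow(coords),
    n_components = max(comp), component = comp
  ), class = "strand_network")
}

#' Build the semi-idealised counterpart of a detailed geometry
#'
#' Keeps the cytoplasm grid but switches the model to continuous membrane and
#' SR fluxes (every voxel carries membrane and uptake flux; the network SR is
#' replaced by a full-grid 6-neighbour network with the same total SR volume)
#' and distributes dyads evenly on a regular lattice matching the detailed
#' model's mean inter-dyad spacing. The integer lattice spacings per axis are
#' chosen to reproduce the detailed dyad count (within ~5%); for near-regular
#' dyad distributions this spacing coincides with the mean nearest-neighbour
#' distance rounded to voxels. Applying the operation to its own output
#' returns an identical geometry (semi-idealised inputs pass through).
#'
#' @param geom a `cell_geometry` with at least 2 dyads.
#' @return A `cell_geometry` with `mode = "semi-idealised"`.
#' @export
build_semi_idealized <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"), nrow(geom$dyads) >= 2)
  if (identical(geom$mode, "semi-idealised")) return(geom)
  d <- geom$dims
  n_target <- nrow(geom$dyads)

  lattice_axis <- function(n, s) seq(s %/% 2L, n - 1L, by = s)
  # choose integer spacings (sx, sy, sz) whose lattice best reproduces the
  # detailed dyad count, preferring near-isotropic spacings on ties
  best <- NULL; best_err <- Inf; best_spread <- Inf
  smax <- pmin(d, 14L)
  for (sx in seq_len(smax[1])) for (sy in seq_len(smax[2])) for (sz in seq_len(smax[3])) {
    cnt <- length(lattice_axis(d[1], sx)) * length(lattice_axis(d[2], sy)) *
      length(lattice_axis(d[3], sz))
    err <- abs(cnt - n_target) / n_target
    spread <- max(sx, sy, sz) - min(sx, sy, sz)
    if (err < best_err - 1e-12 ||
        (abs(err - best_err) < 1e-12 && spread < best_spread)) {
      best <- c(sx, sy, sz); best_err <- err; best_spread <- spread
    }
  }
  s <- best
  co <- as.matrix(expand.grid(i = lattice_axis(d[1], s[1]),
                              j = lattice_axis(d[2], s[2]),
                              k = lattice_axis(d[3], s[3])))
  vox <- lin_index(co[, 1], co[, 2], co[, 3], d)
  vox <- sort(vox[geom$mask[vox]])

  total_sr <- if (!is.null(geom$sr)) geom$sr$total_sr_volume_um3 else
    0.1 * geom$v_cyto_vox * sum(geom$mask)
  sr <- grid_network(geom$mask, total_sr, geom$pitch_um)

  dyads <- make_dyad_table(vox, d, sr,
                           v_ds = geom$dyads$v_ds[1], v_jsr = geom$dyads$v_jsr[1],
                           n_ryr = geom$dyads$n_ryr[1], n_ltcc = geom$dyads$n_ltcc[1])
  out <- geom
  out$sr <- sr
  out$dyads <- dyads
  out$mode <- "semi-idealised"
  out$meta$lattice_spacing_vox <- s
  out$ss_m <- shell_voxels(geom$mask)
  out
}

# full-grid 6-neighbour network over the occupancy mask
grid_network <- function(mask, total_volume, pitch_um) {
  dims <- dim(mask)
  vox <- which(mask)
  node_of <- integer(prod(dims))
  node_of[vox] <- seq_along(vox)
  co <- vox_coords(vox, dims)
  links <- list()
  for (ax in 1:3) {
    nb <- co
    nb[, ax] <- nb[, ax] + 1L
    inside <- nb[, ax] < dims[ax]
    nbidx <- lin_index(nb[inside, 1], nb[inside, 2], nb[inside, 3], dims)
    ok <- mask[nbidx]
    links[[ax]] <- cbind(node_of[vox[inside][ok]], node_of[nbidx[ok]])
  }
  links <- do.call(rbind, links)
  nbr <- links_to_adj(links, length(vox))
  structure(list(
    coords = co, nbr = nbr, node_voxel = vox,
    v_vox_nsr = total_volume / length(vox),
    coarse_dims = dims, pitch_um = pitch_um,
    total_sr_volume_um3 = total_volume,
    n_components = 1L, component = rep(1L, length(vox))
  ), class = "strand_network")
}

#' Perturb dyad density or SR network connectivity
#'
#' Either rescales the dyad count (`dyad_density_factor`; removal is uniform
#' without replacement down to `round(factor * N)` dyads, addition places new
#' dyads at SR-node voxels intersecting the t-tubule map that lack a dyad) or
#' deletes the neighbour links of a randomly selected fraction of SR nodes
#' (`sr_link_removal_fraction`), symmetrically. Heavy link removal may
#' disconnect the SR; the component count is recomputed and reported, and the
#' simulation still runs on a disconnected network.
#'
#' @param geom a `cell_geometry`.
#' @param spec list with one of `dyad_density_factor` (> 0) or
#'   `sr_link_removal_fraction` (in [0, 1)).
#' @param seed integer seed.
#' @return The perturbed `cell_geometry` (with `meta$removed_links` set when
#'   links were removed).
#' @export
perturb_structure <- function(geom, spec, seed = 1) {
  stopifnot(inherits(geom, "cell_geometry"), is.list(spec))
  out <- geom
  with_local_seed(seed, {
    if (!is.null(spec$dyad_density_factor)) {
      f <- spec$dyad_density_factor
      if (f <= 0) stop("dyad_density_factor must be > 0")
      n <- nrow(geom$dyads)
      target <- as.integer(round(f * n))
      if (target <= n) {
        keep <- sort(sample.int(n, target))
        out$dyads <- geom$dyads[keep, , drop = FALSE]
        rownames(out$dyads) <- NULL
      } else {
        need <- target - n
        cand <- intersect(geom$sr$node_voxel, geom$tt_m)
        cand <- setdiff(cand, geom$dyads$voxel)
        if (length(cand) < need) {
          warning("only ", length(cand), " SR/TT junction sites available; ",
                  "adding all of them (requested ", need, ")")
          add <- cand
        } else add <- sort(sample(cand, need))
        newdy <- make_dyad_table(add, geom$dims, geom$sr,
                                 v_ds = geom$dyads$v_ds[1],
                                 v_jsr = geom$dyads$v_jsr[1],
                                 n_ryr = geom$dyads$n_ryr[1],
                                 n_ltcc = geom$dyads$n_ltcc[1])
        out$dyads <- rbind(geom$dyads, newdy)
        out$dyads <- out$dyads[order(out$dyads$voxel), , drop = FALSE]
        rownames(out$dyads) <- NULL
      }
    }
    if (!is.null(spec$sr_link_removal_fraction)) {
      fr <- spec$sr_link_removal_fraction
      if (fr < 0 || fr >= 1) stop("sr_link_removal_fraction must be in [0, 1)")
      sr <- geom$sr
      nnode <- nrow(sr$coords)
      nsel <- as.integer(round(fr * nnode))
      if (nsel > 0) {
        sel <- sample.int(nnode, nsel)
        before <- n_links(sr$nbr)
        nbr <- sr$nbr
        for (q in sel) {
          for (w in nbr[[q]]) nbr[[w]] <- setdiff(nbr[[w]], q)
          nbr[[q]] <- integer(0)
        }
        sr$nbr <- nbr
        comp <- adj_components(nbr)
        sr$n_components <- max(comp)
        sr$component <- comp
        out$sr <- sr
        out$meta$removed_links <- before - n_links(nbr)
      } else out$meta$removed_links <- 0
    }
  })
  out
}

#' Nearest-neighbour inter-dyad distances
#'
#' Euclidean distance between voxel centres (scaled by the lattice pitch)
#' from each dyad to its closest other dyad, plus a histogram whose counts
#' sum to the dyad count.
#'
#' @param dyads a `cell_geometry` or a dyad table with columns `i`, `j`, `k`.
#' @param pitch_um lattice pitch in um (taken from the geometry when one is
#'   supplied).
#' @param binwidth histogram bin width in um.
#' @return list with `distances` (um, one per dyad) and `histogram`
#'   (a `hist` object), class `nn_distances`.
#' @export
nearest_neighbor_distances <- function(dyads, pitch_um = 0.35, binwidth = 0.1) {
  if (inherits(dyads, "cell_geometry")) {
    pitch_um <- dyads$pitch_um
    dyads <- dyads$dyads
  }
  n <- nrow(dyads)
  if (n < 2) stop("at least 2 dyads are required")
  xyz <- (cbind(dyads$i, dyads$j, dyads$k) + 0.5) * pitch_um
  nnd <- numeric(n)
  chunk <- 2000L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    d2 <- outer(rowSums(xyz[lo:hi, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[lo:hi, , drop = FALSE] %*% t(xyz)
    d2[cbind(seq_len(hi - lo + 1L), lo:hi)] <- Inf
    nnd[lo:hi] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  h <- graphics::hist(nnd, breaks = seq(0, max(nnd) + binwidth, by = binwidth),
                      plot = FALSE)
  structure(list(distances = nnd, histogram = h), class = "nn_distances")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell_geometry (", x$mode, "): ",
      paste(x$dims, collapse = " x "), " voxels @ ", x$pitch_um, " um\n", sep = "")
  cat("  cytoplasm voxels:", sum(x$mask), "| SS_M:", length(x$ss_m),
      "| TT_M:", length(x$tt_m), "\n")
  cat("  dyads:", nrow(x$dyads), "| SR nodes:",
      if (is.null(x$sr)) 0 else nrow(x$sr$coords), "\n")
  invisible(x)
}
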