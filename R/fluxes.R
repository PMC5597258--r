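# Local reaction fluxes, rapid buffering, map-gated reaction terms and force.

#' Instantaneous cytosolic buffering factor
#'
#' Rapid-buffering approximation for the configured instantaneous buffers:
#' `beta = 1 / (1 + sum_i B_i K_i / (K_i + Ca)^2)`. Troponin is handled
#' dynamically through its own binding flux and is not included here.
#'
#' @param ca_cyto cytosolic Ca2+ (uM), scalar or vector.
#' @param params full parameter list.
#' @return Buffering factor in (0, 1], same shape as `ca_cyto`.
#' @export
buffering_beta <- function(ca_cyto, params = default_params()) {
  stopifnot(all(ca_cyto >= 0))
  b <- params$transport$buffers
  denom <- rep(1, length(ca_cyto))
  for (i in seq_along(b$b)) denom <- denom + b$b[i] * b$k[i] / (b$k[i] + ca_cyto)^2
  1 / denom
}

# NCX Ca2+ flux (uM/ms, positive = Ca2+ entry) at local cytosolic Ca2+,
# with allosteric activation by cytosolic Ca2+ (deactivated near rest).
ncx_flux <- function(vm, ca_um, tp, const) {
  n <- tp$ncx
  x <- vm / const$rtof
  ca_mm <- ca_um * 1e-3
  num <- exp(n$gamma * x) * const$nai^3 * const$cao -
    exp((n$gamma - 1) * x) * const$nao^3 * ca_mm * n$alpha
  den <- (n$km_nai^3 + const$nao^3) * (n$km_ca + const$cao) *
    (1 + n$ksat * exp((n$gamma - 1) * x))
  allo <- ca_um^2 / (ca_um^2 + n$k_allo^2)
  tp$kncx * allo * num / den
}

# SERCA uptake (uM/ms) at local cytosolic Ca2+
serca_flux <- function(ca_um, tp, jup_scale = 1) {
  jup_scale * tp$vup * ca_um^tp$hup / (ca_um^tp$hup + tp$kup^tp$hup)
}

# background Ca2+ influx (uM/ms), linear in the driving force
cab_flux <- function(vm, ca_um, tp, const) {
  e_ca <- 0.5 * const$rtof * log(const$cao / (ca_um * 1e-3))
  tp$gcab * (e_ca - vm)
}

# PMCA extrusion (uM/ms, negative = efflux)
pca_flux <- function(ca_um, tp) -tp$gpca * ca_um / (ca_um + tp$kpca)

# troponin binding flux (uM/ms removed from free Ca) and occupancy derivative
trpn_flux <- function(ca_um, occ, tp) {
  on <- tp$trpn$kon * ca_um * (1 - occ)
  off <- tp$trpn$koff * occ
  list(j = tp$trpn$btot * (on - off), docc = on - off)
}

#' Local membrane, SR and subspace fluxes at one voxel
#'
#' Evaluates every reaction flux at the LOCAL concentrations of cytoplasm
#' voxel `n`: subspace exchange `J_SS = (Ca_rbSS - Ca_cyto)/tau_ss`, Hill-type
#' SERCA uptake with linear SR leak, the voltage- and
#' concentration-dependent NCX flux, the saturable sarcolemmal pump, the
#' background influx and dynamic troponin binding. Fluxes are in uM/ms
#' referred to the cytoplasm voxel volume, positive into the cytosol.
#'
#' @param n cytoplasm voxel index (mask order).
#' @param fields list with `ca_cyto`, `ca_rbss` (uM vectors over voxels),
#'   `ca_nsr` (mM vector over strand nodes), `trpn` (occupancy).
#' @param vm membrane potential (mV).
#' @param params full parameter list.
#' @param geom a `cell_geometry`.
#' @return Named list `j_up`, `j_leak`, `j_naca`, `j_pca`, `j_cab`, `j_ss`,
#'   `j_trpn`.
#' @export
local_fluxes <- function(n, fields, vm, params = default_params(), geom) {
  tp <- params$transport
  ca <- fields$ca_cyto[n]
  rb <- fields$ca_rbss[n]
  node <- NA_integer_
  if (!is.null(geom$sr)) {
    fx <- geom_cache(geom)
    node <- fx$sr_node_of_vox[n]
  }
  ca_nsr_um <- if (!is.na(node) && node > 0L) fields$ca_nsr[node] * 1000 else 0
  tr <- trpn_flux(ca, fields$trpn[n], tp)
  list(
    j_up = serca_flux(ca, tp),
    j_leak = tp$gleak * ca_nsr_um,
    j_naca = ncx_flux(vm, ca, tp, params$const),
    j_pca = pca_flux(ca, tp),
    j_cab = cab_flux(vm, ca, tp, params$const),
    j_ss = (rb - ca) / tp$tau_ss,
    j_trpn = tr$j
  )
}

# cached per-geometry index structures (field index, maps, flux scalings)
geom_cache <- function(geom) {
  if (!is.null(geom$fx)) return(geom$fx)
  n_vox <- sum(geom$mask)
  fidx <- integer(prod(geom$dims))
  fidx[which(geom$mask)] <- seq_len(n_vox)
  continuous <- geom$mode != "detailed"
  mem_vox <- sort(unique(c(geom$ss_m, geom$tt_m)))
  is_mem <- rep(FALSE, n_vox)
  if (continuous) is_mem[] <- TRUE else is_mem[fidx[mem_vox]] <- TRUE
  sr_node_of_vox <- integer(n_vox)
  if (!is.null(geom$sr))
    sr_node_of_vox[fidx[geom$sr$node_voxel]] <- seq_along(geom$sr$node_voxel)
  f_mem <- if (continuous) 1 else n_vox / max(1L, sum(is_mem))
  n_sr_vox <- sum(sr_node_of_vox > 0L)
  f_sr <- if (continuous || n_sr_vox == 0L) 1 else n_vox / n_sr_vox
  list(n_vox = n_vox, fidx = fidx, is_mem = is_mem,
       sr_node_of_vox = sr_node_of_vox, f_mem = f_mem, f_sr = f_sr,
       dyad_fvox = fidx[geom$dyads$voxel])
}

#' Map-gated reaction terms for the three diffusive domains
#'
#' Implements the four-case cytoplasm dispatch (membrane-only, SR-only, both,
#' neither), the network-SR reaction with the jSR refill flux injected at
#' dyad-coupled nodes, and the subspace reaction with the dyadic cleft flux
#' injected at dyad voxels, all with explicit volume ratios. In
#' semi-idealised or idealised mode every voxel carries membrane and SR flux
#' (the continuous form); in detailed mode the membrane and uptake flux
#' densities are scaled by the ratio of cytoplasm voxels to map voxels so the
#' whole-cell flux is independent of map coverage.
#'
#' @param fields field list (see [local_fluxes()]).
#' @param geom a `cell_geometry`.
#' @param vm membrane potential (mV).
#' @param params full parameter list.
#' @param dyad_flux optional list with per-dyad `j_ds` (uM/ms, cleft volume)
#'   and `j_jsr` (mM/ms, jSR volume) from [update_dyad()].
#' @param jup_scale,ncx_scale protocol scalings of the SERCA and NCX maxima.
#' @return list `phi_cyto`, `phi_rbss` (uM/ms per voxel), `phi_nsr` (mM/ms
#'   per node) and `docc` (troponin occupancy derivative), plus the summed
#'   membrane fluxes used for current conversion.
#' @export
reaction_terms <- function(fields, geom, vm, params = default_params(),
                           dyad_flux = NULL, jup_scale = 1, ncx_scale = 1) {
  tp <- params$transport
  fx <- geom_cache(geom)
  ca <- fields$ca_cyto
  rb <- fields$ca_rbss
  occ <- fields$trpn
  v_rbss <- tp$v_rbss_frac * tp$v_cyto_vox

  j_ss <- (rb - ca) / tp$tau_ss
  tr <- trpn_flux(ca, occ, tp)

  # membrane fluxes (gated to the membrane maps)
  j_naca <- j_pca <- j_cab <- numeric(fx$n_vox)
  im <- fx$is_mem
  j_naca[im] <- ncx_scale * fx$f_mem * ncx_flux(vm, ca[im], tp, params$const)
  j_pca[im] <- fx$f_mem * pca_flux(ca[im], tp)
  j_cab[im] <- fx$f_mem * cab_flux(vm, ca[im], tp, params$const)

  # SR uptake minus leak (gated to the SR map)
  j_sr_net <- numeric(fx$n_vox)
  has_sr <- fx$sr_node_of_vox > 0L
  if (any(has_sr)) {
    nd <- fx$sr_node_of_vox[has_sr]
    j_sr_net[has_sr] <- fx$f_sr *
      (serca_flux(ca[has_sr], tp, jup_scale) -
         tp$gleak * fields$ca_nsr[nd] * 1000)
  } else if (!is.null(geom$sr)) {
    stop("SR map is empty but a strand network is present")
  }

  phi_cyto <- j_naca + j_pca + j_cab - j_sr_net +
    (v_rbss / tp$v_cyto_vox) * j_ss - tr$j
  phi_rbss <- -j_ss
  phi_nsr <- numeric(length(fields$ca_nsr))
  if (any(has_sr)) {
    nd <- fx$sr_node_of_vox[has_sr]
    phi_nsr[nd] <- phi_nsr[nd] + j_sr_net[has_sr] *
      (tp$v_cyto_vox / geom$sr$v_vox_nsr) * 1e-3
  }

  if (!is.null(dyad_flux)) {
    dy <- geom$dyads
    if (any(is.na(dy$sr_node)) || is.null(geom$sr))
      stop("dyads require an SR node for jSR coupling; geometry is inconsistent")
    hv <- fx$dyad_fvox
    add_rb <- dyad_flux$j_ds * dy$v_ds / v_rbss
    for (m in seq_len(nrow(dy))) {   # dyads can share a voxel after merging
      phi_rbss[hv[m]] <- phi_rbss[hv[m]] + add_rb[m]
      qn <- dy$sr_node[m]
      phi_nsr[qn] <- phi_nsr[qn] +
        dyad_flux$j_jsr[m] * dy$v_jsr[m] / geom$sr$v_vox_nsr
    }
  }

  list(phi_cyto = phi_cyto, phi_rbss = phi_rbss, phi_nsr = phi_nsr,
       docc = tr$docc,
       j_naca = j_naca, j_pca = j_pca, j_cab = j_cab)
}

#' Whole-cell normalised force from local troponin occupancy
#'
#' Per-voxel active force follows a saturating Hill function of troponin
#' occupancy through first-order activation/relaxation kinetics; the
#' whole-cell force is the voxel mean, normalised to its maximum over the
#' trace (zero traces stay zero).
#'
#' @param occ matrix of troponin occupancy (time x voxels) or a vector for a
#'   single voxel trace, values in [0, 1].
#' @param dt sample interval of the rows (ms).
#' @param params full parameter list.
#' @return list with `force` (normalised whole-cell trace) and `force_raw`.
#' @export
compute_force <- function(occ, dt = 0.1, params = default_params()) {
  if (is.vector(occ)) occ <- matrix(occ, ncol = 1)
  stopifnot(all(occ >= 0), all(occ <= 1))
  fp <- params$force
  fss <- occ^fp$hill / (occ^fp$hill + fp$k_half^fp$hill)
  f <- matrix(0, nrow(occ), ncol(occ))
  state <- fss[1, ]
  f[1, ] <- state
  if (nrow(occ) > 1) {
    a <- dt / fp$tau_f
    for (t in 2:nrow(occ)) {
      state <- state + a * (fss[t, ] - state)
      f[t, ] <- state
    }
  }
  raw <- rowMeans(f)
  mx <- max(raw)
  list(force = if (mx > 0) raw / mx else raw, force_raw = raw)
}
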