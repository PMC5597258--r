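# Orchestration of the coupled time step: packing geometry and parameters
# for the compiled core, state initialisation, and the generic run driver.

# Pack a cell_geometry + parameter list for the compiled core.
prepare_sim <- function(geom, params = default_params(),
                        scales = list()) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (is.null(geom$sr)) stop("simulation requires an SR strand network")
  if (nrow(geom$dyads) < 1) stop("simulation requires at least one dyad")
  if (any(is.na(geom$dyads$sr_node)))
    stop("dyads require an SR node for jSR coupling; geometry is inconsistent")
  fx <- geom_cache(geom)
  nbr <- build_grid_neighbors(geom$mask)

  adj <- geom$sr$nbr
  deg <- lengths(adj)
  sr_off <- c(0L, cumsum(deg))
  sr_adj <- if (sum(deg)) unlist(adj, use.names = FALSE) else integer(0)

  tp <- params$transport
  geo <- list(
    nbr = nbr, is_mem = fx$is_mem, sr_node_of_vox = fx$sr_node_of_vox,
    sr_off = as.integer(sr_off), sr_adj = as.integer(sr_adj),
    v_vox_nsr = geom$sr$v_vox_nsr,
    dy_vox = as.integer(fx$dyad_fvox), dy_node = as.integer(geom$dyads$sr_node),
    dy_vds = geom$dyads$v_ds, dy_vjsr = geom$dyads$v_jsr,
    dy_nryr = as.integer(geom$dyads$n_ryr), dy_nltcc = as.integer(geom$dyads$n_ltcc),
    buf_b = tp$buffers$b, buf_k = tp$buffers$k
  )
  pv <- flatten_params(params, fx, scales)
  list(geo = geo, pv = pv, geom = geom, params = params, fx = fx,
       scales = scales)
}

flatten_params <- function(params, fx, scales = list()) {
  tp <- params$transport; ch <- params$channels; ry <- ch$ryr; lt <- ch$ltcc
  mb <- params$membrane; k <- params$const; fo <- params$force
  sc <- function(nm, default = 1) if (!is.null(scales[[nm]])) scales[[nm]] else default
  c(dt = params$dt, pitch = params$pitch_um,
    d_cyto = tp$d_cyto,
    d_rbss = sc("d_rbss_override", tp$d_rbss),
    d_nsr = tp$d_nsr * sc("d_nsr_scale"),
    tau_ss = tp$tau_ss, v_cyto_vox = tp$v_cyto_vox,
    v_rbss_vox = tp$v_rbss_frac * tp$v_cyto_vox,
    vup = tp$vup, kup = tp$kup, hup = tp$hup, gleak = tp$gleak,
    kncx = tp$kncx, ncx_gamma = tp$ncx$gamma, ncx_km_nai = tp$ncx$km_nai,
    ncx_km_ca = tp$ncx$km_ca, ncx_ksat = tp$ncx$ksat, ncx_alpha = tp$ncx$alpha,
    ncx_k_allo = tp$ncx$k_allo,
    gpca = tp$gpca, kpca = tp$kpca, gcab = tp$gcab,
    trpn_btot = tp$trpn$btot, trpn_kon = tp$trpn$kon, trpn_koff = tp$trpn$koff,
    rtof = k$rtof, cao = k$cao, nao = k$nao, nai = k$nai, ko = k$ko,
    ki = k$ki, cm = k$cm,
    tau_ds = ch$tau_ds, tau_jsr = ch$tau_jsr, g_ryr = ch$g_ryr,
    csqn_b = ch$csqn_b, csqn_k = ch$csqn_k,
    ry_komax = ry$komax, ry_kca = ry$kca, ry_h = ry$h, ry_kclose = ry$kclose,
    ry_kimax = ry$kimax, ry_kica = ry$kica, ry_hi = ry$hi, ry_kir = ry$k_ir,
    ry_krc = ry$k_rc, ry_lumk = ry$lum_k, ry_lumh = ry$lum_h,
    ry_lummin = ry$lum_min, ry_kbasal = ry$k_basal, ry_basalh = ry$basal_h,
    lt_aopen = lt$a_open, lt_bopen = lt$b_open, lt_taud = lt$tau_d,
    lt_vhd = lt$v_half_d, lt_kd = lt$k_d, lt_vhf = lt$v_half_f, lt_kf = lt$k_f,
    lt_taufin = lt$tau_f_in, lt_taufrec = lt$tau_f_rec, lt_kfca = lt$k_fca,
    lt_kcai = lt$kca_i, lt_kcarec = lt$k_ca_rec, lt_pcal = lt$p_cal,
    lt_open_scale = lt$open_rate_scale * sc("ltcc_open_scale"),
    g_na = mb$g_na, g_nal = mb$g_nal, g_to = mb$g_to, g_kr = mb$g_kr,
    g_ks = mb$g_ks, g_k1 = mb$g_k1, p_nak = mb$p_nak, g_bna = mb$g_bna,
    force_k_half = fo$k_half, force_hill = fo$hill, force_tau_f = fo$tau_f,
    f_mem = fx$f_mem, f_sr = fx$f_sr,
    scale_current = sc("scale_current"),
    jup_scale = sc("jup_scale"), ncx_scale = sc("ncx_scale"))
}

#' Initial simulation state
#'
#' Builds the full coupled state: uniform cytosolic/subspace Ca2+, uniform
#' network-SR and jSR load, troponin at binding equilibrium, all RyRs closed,
#' all LTCCs in the deepest closed state, ionic gates at steady state.
#'
#' @param geom a `cell_geometry`.
#' @param params full parameter list.
#' @param ca_cyto initial cytosolic and subspace Ca2+ (uM).
#' @param ca_nsr initial network-SR and jSR Ca2+ (mM).
#' @param vm initial membrane potential (mV).
#' @return A `sim_state` list.
#' @export
sim_initial_state <- function(geom, params = default_params(),
                              ca_cyto = 0.1, ca_nsr = 1.0, vm = -86.2) {
  n_vox <- sum(geom$mask)
  n_nodes <- nrow(geom$sr$coords)
  n_dy <- nrow(geom$dyads)
  tr <- params$transport$trpn
  occ <- tr$kon * ca_cyto / (tr$kon * ca_cyto + tr$koff)
  fo <- params$force
  fss <- occ^fo$hill / (occ^fo$hill + fo$k_half^fo$hill)
  ryr <- matrix(0L, n_dy, 4)
  ryr[, 1] <- geom$dyads$n_ryr
  ltcc <- matrix(0L, n_dy, 5)
  ltcc[, 1] <- geom$dyads$n_ltcc
  ion <- ionic_initial_state(params, vm)
  structure(list(
    ca_cyto = rep(ca_cyto, n_vox), ca_rbss = rep(ca_cyto, n_vox),
    ca_nsr = rep(ca_nsr, n_nodes), trpn = rep(occ, n_vox),
    force = rep(fss, n_vox), ryr = ryr, ltcc = ltcc,
    ca_ds = rep(ca_cyto, n_dy), ca_jsr = rep(ca_nsr, n_dy),
    vm = ion$vm, gates = ion$gates
  ), class = "sim_state")
}

# low-level engine invocation; returns traces, snapshots and the final state
engine_run <- function(sim, state, n_steps, seed, stream_offset = 0,
                       record_stride = 10L, snapshot_stride = 0L,
                       stim = list(period = 0L, offset = 0L, dur = 100L,
                                   amp = -52),
                       clamp = NULL, t0 = 0) {
  ctrl <- list(
    n_steps = as.integer(n_steps),
    stim_period_steps = as.integer(stim$period),
    stim_offset_steps = as.integer(stim$offset),
    stim_dur_steps = as.integer(stim$dur),
    stim_amp = as.numeric(stim$amp),
    record_stride = as.integer(record_stride),
    snapshot_stride = as.integer(snapshot_stride),
    t0 = as.numeric(t0),
    seed = as.numeric(seed),
    stream_offset = as.numeric(stream_offset),
    clamp = clamp
  )
  run_core(sim$geo, state, sim$pv, ctrl)
}

#' Advance the coupled system one fixed time step
#'
#' Single forward-Euler step of the full model (stochastic dyads, map-gated
#' reactions, three-domain diffusion, ionic model), using the compiled core.
#' The CFL condition `dt < h^2 / (6 D)` is enforced per domain and negative
#' concentrations raise an error rather than being clipped.
#'
#' @param state a `sim_state`.
#' @param geom a `cell_geometry`.
#' @param params full parameter list.
#' @param seed,stream_offset RNG stream seeding for the dyad draws.
#' @param scales optional protocol scalings (see [run_paced()]).
#' @return The advanced `sim_state`.
#' @export
step_fields <- function(state, geom, params = default_params(), seed = 1,
                        stream_offset = 0, scales = list()) {
  sim <- prepare_sim(geom, params, scales)
  out <- engine_run(sim, state, n_steps = 1L, seed = seed,
                    stream_offset = stream_offset, record_stride = 0L)
  structure(out$state, class = "sim_state")
}

#' Run the coupled model for a fixed duration
#'
#' Generic driver used by all protocols: paces (optionally), records
#' whole-cell traces at `record_every` ms and 3-D snapshots at
#' `snapshot_every` ms, and returns a `ca_recording`.
#'
#' @param geom a `cell_geometry`.
#' @param params full parameter list.
#' @param duration_ms simulated duration.
#' @param state optional starting `sim_state` (default: quiet initial state).
#' @param bcl basic cycle length in ms; `NULL` or 0 disables pacing.
#' @param seed integer seed (expands to one RNG stream per dyad).
#' @param stream_offset run-segment counter so that consecutive segments of
#'   one protocol use fresh, reproducible streams.
#' @param record_every trace sampling interval (ms).
#' @param snapshot_every snapshot interval (ms); 0 disables snapshots.
#' @param scales list of protocol scalings: `jup_scale`, `ltcc_open_scale`,
#'   `ncx_scale`, `d_nsr_scale`, `d_rbss_override`, `scale_current`.
#' @param clamp optional AP-clamp waveform: numeric vector of commanded Vm
#'   sampled at `params$dt`, or a function of time (ms).
#' @param t0 time origin for the recording (ms).
#' @return A `ca_recording` (traces, snapshots, stimulus times, final state).
#' @export
run_simulation <- function(geom, params = default_params(), duration_ms,
                           state = NULL, bcl = NULL, seed = 1,
                           stream_offset = 0, record_every = 0.1,
                           snapshot_every = 0, scales = list(),
                           clamp = NULL, t0 = 0) {
  sim <- prepare_sim(geom, params, scales)
  if (is.null(state)) state <- sim_initial_state(geom, params)
  dt <- params$dt
  n_steps <- as.integer(round(duration_ms / dt))
  stim <- if (!is.null(bcl) && bcl > 0)
    list(period = round(bcl / dt), offset = 0L,
         dur = round(params$membrane$stim_dur / dt),
         amp = params$membrane$stim_amp)
  else list(period = 0L, offset = 0L, dur = 0L, amp = 0)
  if (is.function(clamp)) clamp <- clamp(seq(0, duration_ms, by = dt))
  out <- engine_run(sim, state, n_steps, seed, stream_offset,
                    record_stride = max(1L, as.integer(round(record_every / dt))),
                    snapshot_stride = if (snapshot_every > 0)
                      as.integer(round(snapshot_every / dt)) else 0L,
                    stim = stim, clamp = clamp, t0 = t0)
  stim_times <- if (stim$period > 0)
    t0 + seq(0, duration_ms - dt, by = stim$period * dt) else numeric(0)
  new_recording(out, geom, params, stim_times = stim_times,
                meta = list(seed = seed, scales = scales, bcl = bcl,
                            duration_ms = duration_ms))
}

new_recording <- function(out, geom, params, stim_times, meta) {
  tr <- as.data.frame(out$traces)
  structure(list(
    traces = tr,
    snapshots = if (nrow(out$snap_ca) > 0)
      list(ca_cyto = out$snap_ca, ca_nsr = out$snap_nsr, t = out$snap_t)
    else NULL,
    stim_times = stim_times,
    state = structure(out$state, class = "sim_state"),
    geometry = list(dims = geom$dims, pitch_um = geom$pitch_um,
                    vox = which(geom$mask),
                    node_voxel = geom$sr$node_voxel,
                    dyad_voxel = geom$dyads$voxel),
    meta = meta
  ), class = "ca_recording")
}

#' @export
print.ca_recording <- function(x, ...) {
  cat("ca_recording:", nrow(x$traces), "trace samples over",
      round(diff(range(x$traces$t)), 1), "ms;",
      if (is.null(x$snapshots)) 0 else nrow(x$snapshots$ca_cyto),
      "snapshots\n")
  invisible(x)
}

# Total Ca2+ content of the coupled state in uM*um^3 (free + instantaneous
# buffers + troponin-bound in the cytoplasm, subspace, network SR, jSR free +
# calsequestrin-bound, and cleft), for conservation checks.
total_calcium <- function(state, geom, params = default_params()) {
  tp <- params$transport
  ch <- params$channels
  b <- tp$buffers
  bound <- function(ca) {
    s <- 0
    for (i in seq_along(b$b)) s <- s + b$b[i] * ca / (b$k[i] + ca)
    s
  }
  v_rbss <- tp$v_rbss_frac * tp$v_cyto_vox
  csqn <- ch$csqn_b * state$ca_jsr / (ch$csqn_k + state$ca_jsr)
  sum(tp$v_cyto_vox * (state$ca_cyto + bound(state$ca_cyto) +
                         tp$trpn$btot * state$trpn)) +
    sum(v_rbss * state$ca_rbss) +
    sum(geom$sr$v_vox_nsr * state$ca_nsr * 1000) +
    sum(geom$dyads$v_jsr * 1000 * (state$ca_jsr + csqn)) +
    sum(geom$dyads$v_ds * state$ca_ds)
}
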