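# Protocol drivers: control pacing, alternans, spark hierarchy, two-dyad
# spark propagation, and rapid-pacing overload with spontaneous release.

#' Protocol configuration with validated defaults
#'
#' @param ... named overrides of the defaults listed below. Unknown names are
#'   rejected; durations must be positive and scalings non-negative.
#' @return A validated `protocol_config` list.
#' @export
protocol_config <- function(...) {
  cfg <- list(
    bcl = 1250,            # ms basic cycle length
    n_beats = 1L,          # measured beats
    n_prebeats = 2L,       # pre-pacing beats
    quiescent_ms = 2000,   # quiescent window (hierarchy / overload)
    jup_scale = 1, ltcc_open_scale = 1, ncx_scale = 1,
    d_nsr_scale = 1, d_rbss_override = NULL,
    ca_nsr0 = 1.0,         # initial SR load (mM)
    ca_cyto0 = 0.1,        # initial cytosolic Ca2+ (uM)
    n_tot_dyads = 13094,   # whole-cell dyad count for the portion rule
    seed = 1L,
    record_every = 0.1,    # ms
    snapshot_every = 0,    # ms; 0 disables snapshots
    sr_loads = c(0.8, 0.9, 1.0, 1.05, 1.1, 1.2),  # mM, hierarchy protocol
    add_dyad_factor = 1    # extra RyR clusters along the SR (hierarchy)
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown protocol option(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$bcl <= 0) stop("bcl must be > 0")
  if (cfg$quiescent_ms <= 0) stop("quiescent_ms must be > 0")
  if (cfg$n_beats < 0 || cfg$n_prebeats < 0) stop("beat counts must be >= 0")
  for (s in c("jup_scale", "ltcc_open_scale", "ncx_scale", "d_nsr_scale"))
    if (cfg[[s]] < 0) stop(s, " must be >= 0")
  structure(cfg, class = c("protocol_config", "list"))
}

cfg_scales <- function(geom, cfg) {
  sc <- list(jup_scale = cfg$jup_scale, ltcc_open_scale = cfg$ltcc_open_scale,
             ncx_scale = cfg$ncx_scale, d_nsr_scale = cfg$d_nsr_scale,
             scale_current = if (is.null(cfg$n_tot_dyads)) 1 else
               cfg$n_tot_dyads / nrow(geom$dyads))
  if (!is.null(cfg$d_rbss_override)) sc$d_rbss_override <- cfg$d_rbss_override
  sc
}

#' Control pacing protocol
#'
#' Paces the cell at the configured basic cycle length: `n_prebeats` beats of
#' pre-pacing with coarse recording, then `n_beats` measured beats recorded
#' every `record_every` ms (default 0.1 ms) with optional 3-D snapshots.
#' With `n_beats = 0` the returned Recording contains only the initial state.
#'
#' @param geom a `cell_geometry`.
#' @param config a [protocol_config()] (or a list of overrides).
#' @param params full parameter list.
#' @return A `ca_recording`; `$prepace` holds the pre-pacing traces.
#' @export
run_paced <- function(geom, config = protocol_config(),
                      params = default_params()) {
  cfg <- protocol_config(config)
  sc <- cfg_scales(geom, cfg)
  state <- sim_initial_state(geom, params, ca_cyto = cfg$ca_cyto0,
                             ca_nsr = cfg$ca_nsr0)
  pre <- NULL
  t0 <- 0
  if (cfg$n_prebeats > 0) {
    pre <- run_simulation(geom, params, duration_ms = cfg$n_prebeats * cfg$bcl,
                          state = state, bcl = cfg$bcl, seed = cfg$seed,
                          stream_offset = 0, record_every = 1,
                          scales = sc)
    state <- pre$state
    t0 <- cfg$n_prebeats * cfg$bcl
  }
  rec <- run_simulation(geom, params, duration_ms = max(cfg$n_beats, 0) * cfg$bcl,
                        state = state, bcl = if (cfg$n_beats > 0) cfg$bcl else NULL,
                        seed = cfg$seed, stream_offset = 1,
                        record_every = cfg$record_every,
                        snapshot_every = cfg$snapshot_every,
                        scales = sc, t0 = t0)
  rec$prepace <- if (is.null(pre)) NULL else pre$traces
  rec$meta$protocol <- "paced"
  rec$meta$config <- cfg
  rec
}

#' Calcium-transient alternans protocol
#'
#' Applies the alternans-promoting scalings (reduced SERCA maximum and
#' reduced LTCC open probability; defaults `jup_scale = 0.5`,
#' `ltcc_open_scale = 0.2`) and paces at a short cycle length
#' (default BCL 450 ms), recording beat-wise transients and snapshots for
#' phase-map analysis.
#'
#' @inheritParams run_paced
#' @return A `ca_recording`.
#' @export
run_alternans <- function(geom, config = protocol_config(
                            bcl = 450, jup_scale = 0.5, ltcc_open_scale = 0.2,
                            n_beats = 12L, n_prebeats = 4L),
                          params = default_params()) {
  cfg <- protocol_config(config)
  rec <- run_paced(geom, cfg, params)
  rec$meta$protocol <- "alternans"
  rec
}

#' Spontaneous release hierarchy protocol
#'
#' For each configured initial SR load the model is left quiescent (no
#' stimulus) for `quiescent_ms` (default 2000 ms) from a uniform load, and
#' the full Recording is returned tagged with the load. Optionally the dyad
#' distribution is densified first (`add_dyad_factor > 1` introduces
#' additional RyR clusters at SR/t-tubule junctions) to promote propagation.
#'
#' @inheritParams run_paced
#' @return Named list of `ca_recording`s, one per SR load.
#' @export
run_spark_hierarchy <- function(geom, config = protocol_config(
                                  snapshot_every = 10),
                                params = default_params()) {
  cfg <- protocol_config(config)
  if (cfg$add_dyad_factor > 1)
    geom <- perturb_structure(geom, list(dyad_density_factor = cfg$add_dyad_factor),
                              seed = cfg$seed)
  sc <- cfg_scales(geom, cfg)
  out <- list()
  for (load in cfg$sr_loads) {
    state <- sim_initial_state(geom, params, ca_cyto = cfg$ca_cyto0,
                               ca_nsr = load)
    rec <- run_simulation(geom, params, duration_ms = cfg$quiescent_ms,
                          state = state, bcl = NULL, seed = cfg$seed,
                          stream_offset = which(cfg$sr_loads == load)[1],
                          record_every = cfg$record_every,
                          snapshot_every = cfg$snapshot_every, scales = sc)
    rec$meta$protocol <- "spark_hierarchy"
    rec$meta$sr_load <- load
    out[[sprintf("load_%.2f", load)]] <- rec
  }
  out
}

#' Synthetic action-potential clamp waveform
#'
#' A ventricular AP-shaped command waveform for clamp protocols: resting
#' potential, fast upstroke at `t_stim`, decaying plateau and repolarisation
#' with approximately the control APD.
#'
#' @param t time points (ms).
#' @param t_stim upstroke time (ms).
#' @param v_rest,v_peak resting and peak potentials (mV).
#' @param apd approximate AP duration (ms).
#' @return Vm at `t` (mV).
#' @export
synthetic_ap_waveform <- function(t, t_stim = 10, v_rest = -86, v_peak = 32,
                                  apd = 345) {
  vapply(t, function(tt) {
    if (tt < t_stim) return(v_rest)
    te <- tt - t_stim
    if (te <= 1) return(v_rest + (v_peak - v_rest) * te)
    if (te >= apd) return(v_rest)
    x <- (te - 1) / (apd - 1)
    v_peak - 12 * x - (v_peak - 12 - v_rest) * x^6
  }, numeric(1))
}

# minimal two-dyad box geometry: a straight SR strand along z with two dyads
# separated by `dist_vox` voxels; dyad 2 carries no LTCCs so it can only be
# activated by its neighbour's spark.
two_dyad_geometry <- function(dist_vox, params = default_params(),
                              box_xy = 11L, pad_z = 8L) {
  dims <- c(box_xy, box_xy, 2L * pad_z + dist_vox + 1L)
  mask <- array(TRUE, dims)
  cx <- box_xy %/% 2L
  kz <- seq_len(dims[3]) - 1L
  co <- cbind(i = cx, j = cx, k = kz)
  node_voxel <- lin_index(co[, 1], co[, 2], co[, 3], dims)
  links <- cbind(seq_len(dims[3] - 1L), seq_len(dims[3] - 1L) + 1L)
  sr <- structure(list(
    coords = co, nbr = links_to_adj(links, dims[3]),
    node_voxel = node_voxel,
    v_vox_nsr = 0.00305, coarse_dims = dims, pitch_um = params$pitch_um,
    total_sr_volume_um3 = 0.00305 * dims[3],
    n_components = 1L, component = rep(1L, dims[3])
  ), class = "strand_network")
  k1 <- pad_z; k2 <- pad_z + dist_vox
  dyads <- make_dyad_table(node_voxel[c(k1, k2) + 1L], dims, sr,
                           v_ds = params$channels$v_ds,
                           v_jsr = params$channels$v_jsr,
                           n_ryr = params$channels$n_ryr,
                           n_ltcc = params$channels$n_ltcc)
  dyads$n_ltcc[2] <- 0L
  structure(list(
    dims = dims, pitch_um = params$pitch_um, mask = mask,
    v_cyto_vox = params$transport$v_cyto_vox,
    ss_m = shell_voxels(mask), tt_m = node_voxel[c(k1, k2) + 1L],
    sr = sr, dyads = dyads, mode = "detailed",
    meta = list(two_dyad = TRUE, dist_vox = dist_vox)
  ), class = "cell_geometry")
}

#' Two-dyad spark propagation probability
#'
#' Builds a small-box geometry with two dyads on a straight SR strand at each
#' requested separation; dyad 1 is triggered by LTCC openings under AP-clamp
#' while dyad 2 (no LTCCs) can only be recruited by the propagating spark.
#' Propagation succeeds when at least `frac_open` of dyad 2's RyRs are
#' simultaneously open within `window_ms` of dyad 1's activation.
#'
#' @param distances dyad separations in um (multiples of the 0.35 um pitch).
#' @param sr_loads SR loads to test (mM).
#' @param n_trials trials per condition (>= 1).
#' @param seed integer seed.
#' @param params full parameter list.
#' @param frac_open activation threshold as a fraction of dyad 2's RyRs.
#' @param window_ms recruitment window after dyad-1 activation (ms).
#' @param duration_ms clamp duration per trial.
#' @return data.frame with distance, load, probability and trial counts.
#' @export
run_two_dyad <- function(distances, sr_loads = c(0.8, 1.0, 1.2), n_trials = 20,
                         seed = 1, params = default_params(), frac_open = 0.1,
                         window_ms = 100, duration_ms = 150) {
  stopifnot(n_trials >= 1)
  pitch <- params$pitch_um
  dist_vox <- as.integer(round(distances / pitch))
  if (any(dist_vox < 1)) stop("distance below one voxel pitch (", pitch, " um)")
  dt <- params$dt
  chunk_ms <- 1
  n_chunks <- as.integer(duration_ms / chunk_ms)
  res <- list()
  for (dv in dist_vox) {
    geom <- two_dyad_geometry(dv, params)
    sim <- prepare_sim(geom, params, scales = list())
    clamp_full <- synthetic_ap_waveform(seq(0, duration_ms, by = dt))
    for (load in sr_loads) {
      succ <- 0L
      for (trial in seq_len(n_trials)) {
        state <- sim_initial_state(geom, params, ca_cyto = 0.1, ca_nsr = load)
        t1_act <- NA_real_; ok <- FALSE
        for (chk in seq_len(n_chunks)) {
          i0 <- as.integer((chk - 1) * chunk_ms / dt)
          out <- engine_run(sim, state, n_steps = as.integer(chunk_ms / dt),
                            seed = seed + 7919 * trial,
                            stream_offset = chk +
                              1e4 * match(load, sr_loads) + 1e6 * dv,
                            record_stride = 0L,
                            clamp = clamp_full[(i0 + 1):(i0 + chunk_ms / dt + 1)])
          state <- out$state
          o1 <- state$ryr[1, 2] / geom$dyads$n_ryr[1]
          o2 <- state$ryr[2, 2] / geom$dyads$n_ryr[2]
          tnow <- chk * chunk_ms
          if (is.na(t1_act) && o1 >= frac_open) t1_act <- tnow
          if (!is.na(t1_act) && o2 >= frac_open &&
              tnow - t1_act <= window_ms) { ok <- TRUE; break }
          if (!is.na(t1_act) && tnow - t1_act > window_ms) break
        }
        if (ok) succ <- succ + 1L
      }
      res[[length(res) + 1L]] <- data.frame(
        distance_um = dv * pitch, sr_load = load,
        probability = succ / n_trials, n_trials = n_trials, successes = succ)
    }
  }
  do.call(rbind, res)
}

#' Rapid-pacing overload and spontaneous release protocol
#'
#' Applies SR-loading scalings (increased SERCA maximum and LTCC open
#' probability, defaults 2.0/2.0), paces to steady state at a rapid cycle
#' length (default 100 beats at BCL 400 ms), then leaves the cell quiescent
#' with free-running membrane potential. Delayed afterdepolarisations and
#' triggered action potentials in the quiescent window are detected with
#' [detect_dads()].
#'
#' @inheritParams run_paced
#' @return A `ca_recording` of the quiescent window with `$events` from
#'   [detect_dads()]; `$prepace` holds the pacing traces.
#' @export
run_overload_release <- function(geom, config = protocol_config(
                                   bcl = 400, n_prebeats = 100L,
                                   jup_scale = 2, ltcc_open_scale = 2,
                                   ncx_scale = 1),
                                 params = default_params()) {
  cfg <- protocol_config(config)
  sc <- cfg_scales(geom, cfg)
  state <- sim_initial_state(geom, params, ca_cyto = cfg$ca_cyto0,
                             ca_nsr = cfg$ca_nsr0)
  pre <- run_simulation(geom, params, duration_ms = cfg$n_prebeats * cfg$bcl,
                        state = state, bcl = cfg$bcl, seed = cfg$seed,
                        stream_offset = 0, record_every = 1, scales = sc)
  rec <- run_simulation(geom, params, duration_ms = cfg$quiescent_ms,
                        state = pre$state, bcl = NULL, seed = cfg$seed,
                        stream_offset = 1, record_every = cfg$record_every,
                        snapshot_every = cfg$snapshot_every, scales = sc,
                        t0 = cfg$n_prebeats * cfg$bcl)
  rec$prepace <- pre$traces
  rec$meta$protocol <- "overload_release"
  rec$meta$config <- cfg
  rec$events <- detect_dads(rec)
  rec
}
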