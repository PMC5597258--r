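# Measurement layer: transient metrics, alternans phase analysis, release
# event detection, linescans, DAD/TA discrimination.

#' Whole-cell transient metrics for one paced beat
#'
#' Definitions (logged with the results): APD90 is the time from the maximal
#' upstroke rate of Vm to 90% repolarisation toward the pre-stimulus
#' diastolic Vm; the CaT amplitude is the peak minus the pre-stimulus
#' diastolic mean cytosolic Ca2+; the upstroke time runs from the 10%-of-
#' amplitude crossing to the peak; the duration-to-90% runs from the 10%
#' crossing on the rise until decay back below 10% of amplitude above
#' diastole.
#'
#' @param rec a `ca_recording` with stimulus markers.
#' @param beat beat index (1-based among the recording's stimuli).
#' @return list with `apd90`, `cat_amplitude`, `upstroke_ms`,
#'   `duration90_ms`, `diastolic`, `systolic` (and the definitions used).
#' @export
transient_metrics <- function(rec, beat = 1) {
  stopifnot(inherits(rec, "ca_recording"))
  st <- rec$stim_times
  if (length(st) < beat) stop("no stimulus marker for beat ", beat)
  tr <- rec$traces
  t_stim <- st[beat]
  t_end <- if (length(st) > beat) st[beat + 1] else max(tr$t)
  pre <- tr$t >= t_stim - 20 & tr$t < t_stim
  if (!any(pre)) pre <- tr$t <= t_stim  # beat starts the recording
  win <- tr$t >= t_stim & tr$t < t_end
  tw <- tr$t[win]

  # --- membrane potential -------------------------------------------
  vm <- tr$vm[win]
  v_dia <- mean(tr$vm[pre])
  ip <- which.max(vm)
  dv <- diff(vm) / diff(tw)
  i_up <- which.max(dv)
  v90 <- vm[ip] - 0.9 * (vm[ip] - v_dia)
  after <- seq(ip, length(vm))
  i_rep <- after[which(vm[after] <= v90)[1]]
  if (is.na(i_rep)) stop("no repolarisation to 90% found in the beat window")
  apd90 <- tw[i_rep] - tw[i_up]

  # --- calcium transient --------------------------------------------
  ca <- tr$ca_cyto[win]
  ca_dia <- mean(tr$ca_cyto[pre])
  ipc <- which.max(ca)
  if (ca[ipc] <= ca_dia) stop("no Ca2+ transient peak found")
  amp <- ca[ipc] - ca_dia
  thr10 <- ca_dia + 0.1 * amp
  i10 <- which(ca >= thr10)[1]
  upstroke <- tw[ipc] - tw[i10]
  dec <- seq(ipc, length(ca))
  i_dec <- dec[which(ca[dec] <= thr10)[1]]
  duration90 <- if (is.na(i_dec)) NA_real_ else tw[i_dec] - tw[i10]

  list(apd90 = apd90, cat_amplitude = amp, upstroke_ms = upstroke,
       duration90_ms = duration90, diastolic = ca_dia, systolic = ca[ipc],
       definitions = c(
         apd90 = "max dVm/dt to 90% repolarisation toward diastolic Vm",
         amplitude = "peak minus pre-stimulus diastolic mean [Ca]_cyto",
         upstroke = "10% of amplitude to peak",
         duration90 = "10% crossing on rise to decay below 10% of amplitude"))
}

# beat-wise CaT amplitudes from the traces
beat_amplitudes <- function(rec) {
  tr <- rec$traces
  st <- rec$stim_times
  vapply(seq_along(st), function(b) {
    t0 <- st[b]
    t1 <- if (b < length(st)) st[b + 1] else max(tr$t) + 0.1
    pre <- tr$t >= t0 - 20 & tr$t < t0
    if (!any(pre)) pre <- tr$t <= t0
    win <- tr$t >= t0 & tr$t < t1
    max(tr$ca_cyto[win]) - mean(tr$ca_cyto[pre])
  }, numeric(1))
}

#' Alternans magnitude, beat-wise amplitudes and activation phase maps
#'
#' The alternans magnitude is the mean of `|A_i - A_(i+1)| / max(A_i,
#' A_(i+1))` over the last (up to) `n_pairs` beat pairs. Per-voxel activation
#' phase is the first crossing of `threshold` (default 0.3 uM) after the
#' stimulus, normalised to the latest measured activation (`window_ms`,
#' default 180 ms, after the stimulus); voxels that never cross are assigned
#' phase 1. The phase variance is the summed absolute difference of the
#' activation phase maps over successive small-amplitude cycles, normalised
#' by the same quantity over the large-amplitude cycles.
#'
#' @param rec a `ca_recording` with >= 4 recorded beats and snapshots.
#' @param threshold activation threshold (uM).
#' @param window_ms phase normalisation window (ms).
#' @param n_pairs beat pairs used for the magnitude.
#' @return list with `magnitude`, `amplitudes`, `phase_maps` (beats x
#'   voxels), `phase_variance`, `small_beats`, `large_beats`.
#' @export
alternans_metrics <- function(rec, threshold = 0.3, window_ms = 180,
                              n_pairs = 10) {
  stopifnot(inherits(rec, "ca_recording"))
  amps <- beat_amplitudes(rec)
  if (length(amps) < 4) stop("alternans metrics require at least 4 beats")
  np <- min(n_pairs, length(amps) - 1)
  pr <- (length(amps) - np):(length(amps) - 1)
  mag <- mean(abs(amps[pr] - amps[pr + 1]) / pmax(amps[pr], amps[pr + 1]))

  if (is.null(rec$snapshots)) stop("phase maps require snapshots")
  sn <- rec$snapshots
  st <- rec$stim_times
  phase <- matrix(NA_real_, length(st), ncol(sn$ca_cyto))
  for (b in seq_along(st)) {
    sel <- which(sn$t >= st[b] & sn$t <= st[b] + window_ms)
    if (!length(sel)) next
    above <- sn$ca_cyto[sel, , drop = FALSE] >= threshold
    first <- apply(above, 2, function(z) {
      w <- which(z)[1]
      if (is.na(w)) NA_integer_ else w
    })
    ph <- rep(1, ncol(above))
    hit <- !is.na(first)
    ph[hit] <- pmin((sn$t[sel][first[hit]] - st[b]) / window_ms, 1)
    phase[b, ] <- ph
  }
  med <- stats::median(amps)
  small <- which(amps < med)
  large <- which(amps >= med)
  pair_sum <- function(idx) {
    idx <- idx[!is.na(rowSums(phase[idx, , drop = FALSE]))]
    if (length(idx) < 2) return(NA_real_)
    s <- 0
    for (i in seq_len(length(idx) - 1))
      s <- s + sum(abs(phase[idx[i], ] - phase[idx[i + 1], ]))
    s
  }
  pv <- pair_sum(small) / pair_sum(large)
  list(magnitude = mag, amplitudes = amps, phase_maps = phase,
       phase_variance = pv, small_beats = small, large_beats = large)
}

#' Detect spontaneous release events in a snapshot series
#'
#' Connected-component detection on supra-threshold voxels (default 2x the
#' diastolic level) over space (6-neighbourhood) and time (consecutive
#' frames): an event is classified as a wave when its maximal spatial extent
#' in any frame exceeds `wave_fraction` of the cytoplasm voxels, otherwise as
#' a spark. The origin is the highest-amplitude voxel of the event's first
#' frame.
#'
#' @param rec a `ca_recording` with snapshots (quiescent protocol).
#' @param threshold_factor threshold as a multiple of the diastolic level.
#' @param wave_fraction spatial extent fraction separating waves from sparks.
#' @param diastolic optional explicit diastolic level (uM).
#' @return data.frame of events: type, origin voxel (linear grid index),
#'   onset time, peak amplitude, maximal extent (voxels). Empty when nothing
#'   crosses threshold.
#' @export
detect_release_events <- function(rec, threshold_factor = 2,
                                  wave_fraction = 0.5, diastolic = NULL) {
  stopifnot(inherits(rec, "ca_recording"))
  if (is.null(rec$snapshots)) stop("release detection requires snapshots")
  sn <- rec$snapshots$ca_cyto
  if (is.null(diastolic)) diastolic <- mean(sn[1, ])
  thr <- threshold_factor * diastolic
  above <- sn > thr
  if (!any(above)) {
    return(data.frame(type = character(0), origin = integer(0),
                      t_onset = numeric(0), peak = numeric(0),
                      extent = integer(0)))
  }
  dims <- rec$geometry$dims
  vox <- rec$geometry$vox
  nb <- build_grid_neighbors(array(seq_len(prod(dims)) %in% vox, dims))
  nt <- nrow(sn); nv <- ncol(sn)
  lab <- matrix(0L, nt, nv)
  cur <- 0L
  for (tt in seq_len(nt)) for (v in seq_len(nv)) {
    if (!above[tt, v] || lab[tt, v] != 0L) next
    cur <- cur + 1L
    stack <- list(c(tt, v))
    lab[tt, v] <- cur
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      t1 <- nd[1]; v1 <- nd[2]
      cand <- cbind(t1, nb[v1, nb[v1, ] > 0])      # spatial neighbours
      cand <- rbind(cand, c(t1 - 1L, v1), c(t1 + 1L, v1))  # temporal
      for (r in seq_len(nrow(cand))) {
        t2 <- cand[r, 1]; v2 <- cand[r, 2]
        if (t2 < 1 || t2 > nt) next
        if (above[t2, v2] && lab[t2, v2] == 0L) {
          lab[t2, v2] <- cur
          stack[[length(stack) + 1L]] <- c(t2, v2)
        }
      }
    }
  }
  ev <- lapply(seq_len(cur), function(e) {
    w <- which(lab == e, arr.ind = TRUE)
    t_first <- min(w[, 1])
    vv <- w[w[, 1] == t_first, 2]
    origin_f <- vv[which.max(sn[t_first, vv])]
    extent <- max(table(w[, 1]))
    data.frame(
      type = if (extent > wave_fraction * nv) "wave" else "spark",
      origin = vox[origin_f],
      t_onset = rec$snapshots$t[t_first],
      peak = max(sn[w]),
      extent = as.integer(extent))
  })
  do.call(rbind, ev)
}

#' Extract a linescan through a voxel along one axis
#'
#' @param rec a `ca_recording` with snapshots.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param anchor 0-based voxel coordinates `c(i, j, k)` inside the grid.
#' @param field which snapshot field (`"ca_cyto"`).
#' @return A `linescan`: list with `t` (ms), `position_um`, and `values`
#'   (time x position).
#' @export
linescan_extract <- function(rec, axis, anchor, field = "ca_cyto") {
  stopifnot(inherits(rec, "ca_recording"), axis %in% 1:3)
  if (is.null(rec$snapshots)) stop("linescan requires snapshots")
  dims <- rec$geometry$dims
  anchor <- as.integer(anchor)
  if (any(anchor < 0) || any(anchor >= dims))
    stop("anchor voxel lies outside the grid")
  co <- matrix(rep(anchor, each = dims[axis]), ncol = 3)
  co[, axis] <- seq_len(dims[axis]) - 1L
  lin <- lin_index(co[, 1], co[, 2], co[, 3], dims)
  fidx <- match(lin, rec$geometry$vox)
  ok <- !is.na(fidx)
  vals <- rec$snapshots[[field]][, fidx[ok], drop = FALSE]
  structure(list(
    t = rec$snapshots$t,
    position_um = (co[ok, axis] + 0.5) * rec$geometry$pitch_um,
    values = vals, axis = axis, anchor = anchor
  ), class = "linescan")
}

#' Detect delayed afterdepolarisations and triggered activity
#'
#' In a stimulus-free window, a triggered action potential (TA) is a Vm
#' excursion crossing `ta_threshold` (default -20 mV) without stimulus; a
#' delayed afterdepolarisation (DAD) is any sub-threshold deflection larger
#' than `dad_delta` (default 2 mV) above the diastolic baseline. The window
#' starts once Vm has settled to within `dad_delta` of its running minimum.
#'
#' @param rec a `ca_recording` of a quiescent window.
#' @param ta_threshold TA voltage threshold (mV).
#' @param dad_delta DAD amplitude threshold (mV).
#' @return list with `ta` (logical), `dad` (logical), `n_dads`, `v_dia`,
#'   `t_ta` (first TA time or NA).
#' @export
detect_dads <- function(rec, ta_threshold = -20, dad_delta = 2) {
  tr <- rec$traces
  vm <- tr$vm
  t <- tr$t
  v_dia <- stats::quantile(vm, 0.05, names = FALSE)
  settled <- which(vm <= v_dia + dad_delta)[1]
  if (is.na(settled)) settled <- 1L
  vm2 <- vm[settled:length(vm)]
  t2 <- t[settled:length(vm)]
  ta_idx <- which(vm2 >= ta_threshold)[1]
  ta <- !is.na(ta_idx)
  above <- vm2 > v_dia + dad_delta
  runs <- rle(above)
  n_dads <- sum(runs$values)
  list(ta = ta, dad = n_dads > 0, n_dads = n_dads, v_dia = v_dia,
       t_ta = if (ta) t2[ta_idx] else NA_real_)
}
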