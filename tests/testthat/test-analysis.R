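# synthetic Recording builders ------------------------------------------------
fake_recording <- function(t, vm, ca, stim_times, snapshots = NULL,
                           geometry = NULL) {
  structure(list(
    traces = data.frame(t = t, vm = vm, ca_cyto = ca, ca_nsr = 1,
                        ca_rbss = ca, ca_jsr = 1, force = 0),
    snapshots = snapshots, stim_times = stim_times,
    geometry = geometry, meta = list()), class = "ca_recording")
}

test_that("transient metrics recover a synthetic triangular transient", {
  t <- seq(0, 1250, 0.1)
  t_stim <- 100
  base <- 0.12; amp <- 0.68
  ca <- rep(base, length(t))
  rise <- t >= t_stim & t < t_stim + 20
  ca[rise] <- base + amp * (t[rise] - t_stim) / 20
  dec <- t >= t_stim + 20 & t < t_stim + 400
  ca[dec] <- base + amp * (1 - (t[dec] - t_stim - 20) / 380)
  # square Vm pulse of width w
  w <- 345
  vm <- ifelse(t >= t_stim & t < t_stim + w, 10, -86)
  rec <- fake_recording(t, vm, ca, stim_times = t_stim)

  m <- transient_metrics(rec, 1)
  expect_equal(m$cat_amplitude, 0.68, tolerance = 1e-3)
  expect_equal(m$upstroke_ms, 18, tolerance = 0.02)     # 10% -> peak of 20 ms rise
  expect_equal(m$duration90_ms, 0.9 * 400, tolerance = 0.02)
  expect_equal(m$apd90, w, tolerance = 0.01)
  expect_equal(m$diastolic, base, tolerance = 1e-6)

  expect_error(transient_metrics(rec, 2), "stimulus")
})

test_that("alternans phase maps honour the threshold and cap rules", {
  # 3-voxel geometry, 6 beats: alternating large/small amplitudes with
  # identical activation patterns on the small beats
  stims <- seq(0, by = 500, length.out = 6)
  snap_t <- seq(0, 2999, by = 10)
  nvox <- 3
  ca <- matrix(0.1, length(snap_t), nvox)
  amps <- rep(c(0.8, 0.3), 3)
  act_delay <- c(20, 50, 1e9)   # voxel 3 never crosses threshold
  for (b in seq_along(stims)) {
    for (v in 1:2) {
      # large-amplitude beats activate with beat-to-beat jitter, the small
      # ones always with the same pattern
      jit <- if (amps[b] > 0.5) 10 * b else 0
      on <- snap_t >= stims[b] + act_delay[v] + jit & snap_t <= stims[b] + 300
      ca[on, v] <- 0.1 + amps[b]
    }
  }
  tr_t <- seq(0, 2999, 0.5)
  tr_ca <- approx(snap_t, rowMeans(ca), xout = tr_t, rule = 2)$y
  rec <- fake_recording(tr_t, rep(-80, length(tr_t)), tr_ca, stims,
                        snapshots = list(ca_cyto = ca,
                                         ca_nsr = matrix(1, length(snap_t), 1),
                                         t = snap_t))
  am <- alternans_metrics(rec, threshold = 0.3, window_ms = 180, n_pairs = 5)
  expect_gt(am$magnitude, 0.3)
  # voxel 3 capped at phase 1 on every beat
  expect_true(all(am$phase_maps[, 3] == 1))
  # identical small-beat phase maps: numerator of the variance ratio is 0
  expect_equal(am$phase_variance, 0)
  # activation phases normalised by the 180 ms window (small beat 2 has the
  # un-jittered 20 ms activation delay)
  expect_equal(am$phase_maps[2, 1], 20 / 180, tolerance = 0.06)
})

test_that("release-event detection classifies sparks and stays silent below threshold", {
  g <- box_geometry(c(7, 7, 7))
  nvox <- sum(g$mask)
  snap_t <- seq(0, 90, 10)
  flat <- matrix(0.1, length(snap_t), nvox)
  rec0 <- fake_recording(seq(0, 90, 1), rep(-86, 91), rep(0.1, 91), numeric(0),
                         snapshots = list(ca_cyto = flat,
                                          ca_nsr = matrix(1, length(snap_t), 1),
                                          t = snap_t),
                         geometry = list(dims = g$dims, pitch_um = 0.35,
                                         vox = which(g$mask)))
  expect_equal(nrow(detect_release_events(rec0)), 0)

  # a localised spark at the centre voxel, frames 4-6
  spark <- flat
  centre <- which(which(g$mask) == caspatial:::lin_index(3, 3, 3, g$dims))
  nb <- caspatial:::build_grid_neighbors(g$mask)[centre, ]
  for (fr in 4:6) {
    spark[fr, centre] <- 2.0
    spark[fr, nb] <- 0.7
  }
  rec1 <- rec0
  rec1$snapshots$ca_cyto <- spark
  ev <- detect_release_events(rec1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "spark")
  expect_equal(ev$origin, caspatial:::lin_index(3, 3, 3, g$dims))
  expect_equal(ev$t_onset, snap_t[4])
  expect_lt(ev$extent, 0.5 * nvox)
})

test_that("linescans extract the voxel line losslessly", {
  g <- box_geometry(c(9, 5, 5))
  nvox <- sum(g$mask)
  snap_t <- c(0, 10)
  vals <- matrix(runif(2 * nvox), 2, nvox)
  rec <- fake_recording(snap_t, c(-86, -86), c(0.1, 0.1), numeric(0),
                        snapshots = list(ca_cyto = vals,
                                         ca_nsr = matrix(1, 2, 1), t = snap_t),
                        geometry = list(dims = g$dims, pitch_um = 0.35,
                                        vox = which(g$mask)))
  ls <- linescan_extract(rec, axis = 1, anchor = c(0, 2, 2))
  expect_equal(length(ls$position_um), 9)
  lin <- caspatial:::lin_index(0:8, rep(2, 9), rep(2, 9), g$dims)
  expect_identical(ls$values, rec$snapshots$ca_cyto[, match(lin, which(g$mask))])

  # uniform field -> constant linescan
  rec2 <- rec
  rec2$snapshots$ca_cyto[] <- 0.42
  ls2 <- linescan_extract(rec2, 3, c(4, 2, 0))
  expect_true(all(ls2$values == 0.42))

  # symmetric synthetic spark is symmetric about its centre
  prof <- exp(-((0:8) - 4)^2 / 2)
  rec3 <- rec
  lin3 <- caspatial:::lin_index(0:8, rep(2, 9), rep(2, 9), g$dims)
  rec3$snapshots$ca_cyto[1, match(lin3, which(g$mask))] <- prof
  ls3 <- linescan_extract(rec3, 1, c(0, 2, 2))
  expect_equal(ls3$values[1, ], rev(ls3$values[1, ]))

  expect_error(linescan_extract(rec, 1, c(0, 9, 2)), "outside")
})

test_that("analysis is a pure function of the stored Recording", {
  g <- box_geometry(c(5, 5, 6), dyad_ijk = cbind(2, 2, 3))
  rec <- run_paced(g, protocol_config(bcl = 150, n_beats = 1L, n_prebeats = 0L,
                                      seed = 5, snapshot_every = 10))
  d <- tempfile()
  write_recording(rec, d)
  rec2 <- read_recording(d)
  expect_identical(caspatial:::beat_amplitudes(rec),
                   caspatial:::beat_amplitudes(rec2))
  unlink(d, recursive = TRUE)
})
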