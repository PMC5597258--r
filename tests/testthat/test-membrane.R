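p_def <- default_params()

test_that("flux-to-current conversion is linear and respects the portion rule", {
  g <- box_geometry(c(4, 4, 4), dyad_ijk = cbind(c(1, 2), c(1, 2), c(1, 2)))
  zeroes <- list(j_naca = rep(0, 64), j_pca = rep(0, 64), j_cab = rep(0, 64),
                 j_cal = c(0, 0))
  cur0 <- fluxes_to_currents(zeroes, g, p_def)
  expect_equal(unlist(cur0), c(i_naca = 0, i_pca = 0, i_cab = 0, i_cal = 0))

  set.seed(2)
  fl <- list(j_naca = rnorm(64), j_pca = -runif(64), j_cab = runif(64),
             j_cal = c(300, 500))
  c1 <- fluxes_to_currents(fl, g, p_def)
  fl2 <- fl
  fl2$j_naca <- 2 * fl$j_naca
  expect_equal(fluxes_to_currents(fl2, g, p_def)$i_naca, 2 * c1$i_naca)

  # a portion with half the dyads and identical per-dyad fluxes gives the
  # same whole-cell I_CaL after N_tot/N scaling
  g_half <- box_geometry(c(4, 4, 4), dyad_ijk = cbind(1, 1, 1))
  fl_half <- fl
  fl_half$j_cal <- 300
  i_full <- fluxes_to_currents(list(j_naca = rep(0, 64), j_pca = rep(0, 64),
                                    j_cab = rep(0, 64), j_cal = c(300, 300)),
                               g, p_def, scale_factor = 1)$i_cal
  i_half <- fluxes_to_currents(list(j_naca = rep(0, 64), j_pca = rep(0, 64),
                                    j_cab = rep(0, 64), j_cal = 300),
                               g_half, p_def, scale_factor = 2)$i_cal
  expect_equal(i_half, i_full)
})

test_that("AP clamp overrides the membrane equation exactly", {
  st <- ionic_initial_state(p_def, -86)
  out <- step_ionic(st, dt = 0.01, clamp = -23.456, params = p_def)
  expect_identical(out$vm, -23.456)
})

test_that("with every current zero the membrane potential is exactly constant", {
  p0 <- p_def
  p0$membrane[c("g_na", "g_nal", "g_to", "g_kr", "g_ks", "g_k1", "p_nak",
                "g_bna")] <- 0
  st <- ionic_initial_state(p0, -55)
  out <- step_ionic(st, dt = 0.01, params = p0)
  expect_identical(out$vm, -55)
})

test_that("the resting membrane potential is stable without stimulus", {
  st <- ionic_initial_state(p_def, -86.2)
  vm_trace <- numeric(0)
  for (s in seq_len(60000)) {    # 0.6 s at dt = 0.01 ms
    st <- step_ionic(st, dt = 0.01, params = p_def)
    if (s %% 10000 == 0) vm_trace <- c(vm_trace, st$vm)
  }
  # settled value drifts < 1 mV over the second half of the window
  expect_lt(abs(vm_trace[length(vm_trace)] - vm_trace[3]), 1)
  expect_lt(abs(st$vm + 86), 4)  # near the physiological resting potential
})

test_that("all HH gates stay in [0, 1] under random voltage excursions", {
  set.seed(6)
  st <- ionic_initial_state(p_def, -86)
  ok <- TRUE
  for (s in seq_len(20000)) {
    st$vm <- runif(1, -120, 60)
    st <- step_ionic(st, dt = runif(1, 1e-4, 0.01), clamp = st$vm,
                     params = p_def)
    if (any(st$gates < 0 | st$gates > 1)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("non-finite membrane potential raises rather than propagating", {
  st <- ionic_initial_state(p_def, -86)
  bad <- list(i_cal = NaN, i_naca = 0, i_pca = 0, i_cab = 0)
  expect_error(step_ionic(st, ca_currents = bad, dt = 0.01, params = p_def),
               "non-finite")
})
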