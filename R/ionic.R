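# Reduced action-potential model: human-ventricle derived current set
# (INa, INaL, Ito, IKr, IKs, IK1, INaK, background Na+) with fixed
# intracellular Na+/K+, coupled to the spatial model through the Ca-derived
# currents (ICaL, INaCa, IpCa, ICab) converted from the spatial fluxes.

ionic_gate_names <- c("m", "h", "j", "ml", "hl", "r", "s", "xr1", "xr2", "xs")

# steady states and time constants for all HH gates at potential v (mV)
gate_tables <- function(v) {
  mss <- 1 / (1 + exp((-56.86 - v) / 9.03))^2
  am <- 1 / (1 + exp((-60 - v) / 5))
  bm <- 0.1 / (1 + exp((v + 35) / 5)) + 0.1 / (1 + exp((v - 50) / 200))
  hss <- 1 / (1 + exp((v + 71.55) / 7.43))^2
  if (v < -40) {
    ah <- 0.057 * exp(-(v + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v)
    aj <- (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
      (v + 37.78) / (1 + exp(0.311 * (v + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14)))
  } else {
    ah <- 0
    bh <- 0.77 / (0.13 * (1 + exp(-(v + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.6 * exp(0.057 * v) / (1 + exp(-0.1 * (v + 32)))
  }
  xr1a <- 450 / (1 + exp((-45 - v) / 10))
  xr1b <- 6 / (1 + exp((v + 30) / 11.5))
  xr2a <- 3 / (1 + exp((-60 - v) / 20))
  xr2b <- 1.12 / (1 + exp((v - 60) / 20))
  xsa <- 1400 / sqrt(1 + exp((5 - v) / 6))
  xsb <- 1 / (1 + exp((v - 35) / 15))
  list(
    ss = c(m = mss, h = hss, j = hss,
           ml = 1 / (1 + exp((-42.85 - v) / 5.264)),
           hl = 1 / (1 + exp((v + 87.61) / 7.488)),
           r = 1 / (1 + exp((20 - v) / 6)),
           s = 1 / (1 + exp((v + 20) / 5)),
           xr1 = 1 / (1 + exp((-26 - v) / 7)),
           xr2 = 1 / (1 + exp((v + 88) / 24)),
           xs = 1 / (1 + exp((-5 - v) / 14))),
    tau = c(m = am * bm, h = 1 / (ah + bh), j = 1 / (aj + bj),
            ml = am * bm, hl = 200,
            r = 9.5 * exp(-(v + 40)^2 / 1800) + 0.8,
            s = 85 * exp(-(v + 45)^2 / 320) + 5 / (1 + exp((v - 20) / 5)) + 3,
            xr1 = xr1a * xr1b, xr2 = xr2a * xr2b, xs = xsa * xsb + 80)
  )
}

#' Create the ionic model state
#'
#' @param params full parameter list.
#' @param vm initial membrane potential (mV); gates start at their steady
#'   state for this potential.
#' @return An `ionic_state` list (`vm` plus HH gate values).
#' @export
ionic_initial_state <- function(params = default_params(), vm = -86.2) {
  g <- gate_tables(vm)
  structure(list(vm = vm, gates = g$ss), class = "ionic_state")
}

# membrane currents (pA/pF) from the voltage-gated set at fixed Na/K
ionic_currents <- function(vm, gates, params) {
  mb <- params$membrane
  k <- params$const
  ena <- k$rtof * log(k$nao / k$nai)
  ek <- k$rtof * log(k$ko / k$ki)
  eks <- k$rtof * log((k$ko + 0.03 * k$nao) / (k$ki + 0.03 * k$nai))
  ak1 <- 0.1 / (1 + exp(0.06 * (vm - ek - 200)))
  bk1 <- (3 * exp(0.0002 * (vm - ek + 100)) + exp(0.1 * (vm - ek - 10))) /
    (1 + exp(-0.5 * (vm - ek)))
  xk1 <- ak1 / (ak1 + bk1)
  list(
    i_na = mb$g_na * gates[["m"]]^3 * gates[["h"]] * gates[["j"]] * (vm - ena),
    i_nal = mb$g_nal * gates[["ml"]] * gates[["hl"]] * (vm - ena),
    i_to = mb$g_to * gates[["r"]] * gates[["s"]] * (vm - ek),
    i_kr = mb$g_kr * sqrt(k$ko / 5.4) * gates[["xr1"]] * gates[["xr2"]] * (vm - ek),
    i_ks = mb$g_ks * gates[["xs"]]^2 * (vm - eks),
    i_k1 = mb$g_k1 * sqrt(k$ko / 5.4) * xk1 * (vm - ek),
    i_nak = mb$p_nak * (k$ko / (k$ko + 1)) * (k$nai / (k$nai + 40)) /
      (1 + 0.1245 * exp(-0.1 * vm / k$rtof) + 0.0353 * exp(-vm / k$rtof)),
    i_bna = mb$g_bna * (vm - ena)
  )
}

#' Advance the reduced action-potential model one step
#'
#' HH gates advance by the Rush-Larsen scheme; the membrane potential by the
#' explicit sum of the voltage-gated currents, the Ca-derived currents from
#' the spatial model and the stimulus. Under AP clamp the commanded waveform
#' replaces the Vm ODE (gates still follow the clamped potential).
#'
#' @param state an `ionic_state`.
#' @param ca_currents list with `i_cal`, `i_naca`, `i_pca`, `i_cab` (pA/pF),
#'   from [fluxes_to_currents()].
#' @param dt time step (ms).
#' @param stimulus applied stimulus current (pA/pF, negative depolarises).
#' @param clamp optional commanded Vm (mV) for this step; when supplied the
#'   output Vm equals it exactly.
#' @param params full parameter list.
#' @return Updated `ionic_state` with attribute `currents`.
#' @export
step_ionic <- function(state, ca_currents = list(i_cal = 0, i_naca = 0,
                                                 i_pca = 0, i_cab = 0),
                       dt = 0.01, stimulus = 0, clamp = NULL,
                       params = default_params()) {
  stopifnot(dt <= 0.01 + 1e-12)
  vm <- state$vm
  g <- gate_tables(vm)
  gates <- g$ss + (state$gates - g$ss) * exp(-dt / g$tau)
  cur <- ionic_currents(vm, gates, params)
  i_sum <- cur$i_na + cur$i_nal + cur$i_to + cur$i_kr + cur$i_ks + cur$i_k1 +
    cur$i_nak + cur$i_bna + ca_currents$i_cal + ca_currents$i_naca +
    ca_currents$i_pca + ca_currents$i_cab
  vm_new <- if (is.null(clamp)) vm - dt * (i_sum + stimulus) else clamp
  if (!is.finite(vm_new)) stop("membrane potential became non-finite")
  out <- state
  out$vm <- vm_new
  out$gates <- gates
  attr(out, "currents") <- cur
  out
}

#' Convert spatial Ca2+ fluxes to whole-cell membrane currents
#'
#' Sums the local fluxes over the membrane map (NCX, sarcolemmal pump,
#' background) and over the dyads (LTCC), multiplies by the Faraday constant
#' and the respective compartment volumes, applies the net charge moved per
#' Ca2+ ion (NCX +1 with the flux sign, pumps and channels -2) and divides by
#' the reference membrane capacitance. For cell-portion geometries the
#' currents are multiplied by `scale_factor = N_tot_dyads / N_dyads`.
#'
#' @param fluxes list with vectors `j_naca`, `j_pca`, `j_cab` (uM/ms per
#'   cytoplasm voxel) and `j_cal` (uM/ms per dyad, cleft volume).
#' @param geom a `cell_geometry` (supplies `v_ds` per dyad).
#' @param params full parameter list (supplies `v_cyto_vox` and `cm`).
#' @param scale_factor whole-cell scaling for portion models.
#' @return list `i_naca`, `i_pca`, `i_cab`, `i_cal` in pA/pF.
#' @export
fluxes_to_currents <- function(fluxes, geom, params = default_params(),
                               scale_factor = 1) {
  f_pa <- 0.096485   # pA per (uM um^3 / ms)
  v_vox <- params$transport$v_cyto_vox
  cm <- params$const$cm
  conv <- function(total, z_eff) z_eff * f_pa * total * scale_factor / cm
  list(
    i_naca = conv(sum(fluxes$j_naca) * v_vox, +1),
    i_pca = conv(sum(fluxes$j_pca) * v_vox, -2),
    i_cab = conv(sum(fluxes$j_cab) * v_vox, -2),
    i_cal = conv(sum(fluxes$j_cal * geom$dyads$v_ds), -2)
  )
}
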