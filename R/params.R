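#' Default model parameters
#'
#' Returns the full default parameter set as a nested list with blocks
#' `channels` (dyad volumes, RyR/LTCC Markov rates, jSR buffering),
#' `transport` (diffusion coefficients, subspace coupling, SERCA/NCX/PMCA/
#' background fluxes, cytosolic buffers, troponin), `membrane` (reduced
#' action-potential model conductances and stimulus) and `force`.
#'
#' Units: time ms, space um, cytosolic/subspace/cleft Ca2+ uM, SR Ca2+ mM,
#' diffusion um^2/ms, fluxes uM/ms referred to the volume of the compartment
#' they act on, currents pA/pF. Channel-scheme rate constants and membrane
#' conductances are calibration parameters of the model (the free parameters
#' are fitted to the whole-cell control-pacing targets and frozen here).
#'
#' @return Nested parameter list.
#' @export
default_params <- function() {
  list(
    dt = 0.01,            # ms; fixed-step forward Euler
    pitch_um = 0.35,

    # physical constants and fixed ionic conditions
    const = list(
      faraday = 96485,    # C/mol
      rtof = 26.712,      # RT/F in mV at 310 K
      cao = 1.8,          # mM
      nao = 140, nai = 7.8,
      ko = 5.4, ki = 140,
      cm = 185            # pF, reference whole cell
    ),

    channels = list(
      n_ryr = 100L, n_ltcc = 15L,
      v_ds = 1.0e-3,      # um^3 dyadic cleft
      v_jsr = 3.0e-2,     # um^3 junctional SR
      tau_ds = 0.002,     # ms, cleft <-> subspace exchange
      tau_jsr = 8,        # ms, jSR <-> network SR refilling
      g_ryr = 2.0e-3,     # um^3/ms per open RyR (maximal release rate)
      csqn_b = 36, csqn_k = 0.63,   # mM; instantaneous calsequestrin buffer
      ryr = list(
        komax = 0.42,     # /ms saturating opening rate
        kca = 28, h = 3,  # uM half-activation of opening, Hill coefficient
        kclose = 1.0,     # /ms open -> closed
        kimax = 0.35, kica = 25, hi = 2,  # Ca-dependent inactivation
        k_ir = 0.08,      # /ms inactivated -> refractory
        k_rc = 0.0015,    # /ms refractory -> closed (recovery)
        lum_k = 1.0, lum_h = 6,   # mM; jSR-luminal modulation of opening
        lum_min = 0.01,
        k_basal = 5e-8, basal_h = 14  # store-overload basal opening pathway
      ),
      ltcc = list(
        a_open = 0.04,    # /ms d2 -> d3 (the scalable opening transition)
        b_open = 2.0,     # /ms d3 -> d2
        tau_d = 10,       # ms activation time constant scale
        v_half_d = 5, k_d = 6.24,     # mV activation midpoint/slope
        v_half_f = 25, k_f = 8.6,     # mV inactivation midpoint/slope
        tau_f_in = 25, tau_f_rec = 60,    # ms voltage inactivation/recovery
        k_fca = 0.35, kca_i = 15,     # /ms, uM Ca-dependent inactivation
        k_ca_rec = 0.006,             # /ms recovery from Ca inactivation
        p_cal = 3.5e3,    # uM/ms cleft flux scale per open channel
        open_rate_scale = 1
      )
    ),

    transport = list(
      d_cyto = 0.3, d_rbss = 0.3, d_nsr = 0.3,   # um^2/ms
      tau_ss = 2.5,          # ms, subspace <-> cytoplasm exchange
      v_cyto_vox = 0.0314,   # um^3 (75% of (0.35 um)^3, rounded as reported)
      v_rbss_frac = 0.1,     # v_rbss_vox = frac * v_cyto_vox
      vup = 0.9, kup = 0.35, hup = 2,   # SERCA: uM/ms, uM, Hill
      gleak = 1.1e-5,        # /ms leak per uM of nSR Ca
      kncx = 1.2e2,          # NCX flux scale (uM/ms at the driving term)
      ncx = list(gamma = 0.35, km_nai = 87.5, km_ca = 1.38, ksat = 0.1,
                 alpha = 2.5, k_allo = 0.25),  # uM allosteric activation
      gpca = 0.02, kpca = 0.5,    # PMCA uM/ms, uM
      gcab = 4.0e-5,              # background Ca influx scale
      buffers = list(b = c(24, 47), k = c(7, 0.87)),   # uM instantaneous
      trpn = list(btot = 70, kon = 0.0327, koff = 0.0196)  # uM, /uM/ms, /ms
    ),

    membrane = list(
      g_na = 14.838, g_nal = 0.025, g_to = 0.18,
      g_kr = 0.085, g_ks = 0.18, g_k1 = 5.405,
      p_nak = 1.6, g_bna = 2.2e-4,
      stim_amp = -52, stim_dur = 1    # pA/pF, ms
    ),

    force = list(
      k_half = 0.35,   # troponin occupancy at half-maximal activation
      hill = 3,
      tau_f = 40       # ms activation/relaxation kinetics
    )
  )
}
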