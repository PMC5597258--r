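#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Coupled fixed-step (forward Euler / Rush-Larsen) core for the
// three-domain reaction-diffusion model with stochastic dyads and the
// reduced action-potential model. Semantics mirror the R-level module
// functions (update_dyad, reaction_terms, laplacian_grid/_network,
// step_ionic) exactly; the R functions are the readable reference, this is
// the fast path used by the protocol drivers.

namespace {

struct Pars {
  double dt, pitch, d_cyto, d_rbss, d_nsr, tau_ss, v_cyto, v_rbss;
  double vup, kup, hup, gleak;
  double kncx, g_gamma, km_nai, km_ca, ksat, alpha, k_allo;
  double gpca, kpca, gcab;
  double trpn_btot, trpn_kon, trpn_koff;
  double rtof, cao, nao, nai, ko, ki, cm;
  double tau_ds, tau_jsr, g_ryr, csqn_b, csqn_k;
  double ry_komax, ry_kca, ry_h, ry_kclose, ry_kimax, ry_kica, ry_hi,
         ry_kir, ry_krc, ry_lumk, ry_lumh, ry_lummin, ry_kbasal, ry_basalh;
  double lt_aopen, lt_bopen, lt_taud, lt_vhd, lt_kd, lt_vhf, lt_kf,
         lt_taufin, lt_taufrec, lt_kfca, lt_kcai, lt_kcarec, lt_pcal,
         lt_openscale;
  double g_na, g_nal, g_to, g_kr, g_ks, g_k1, p_nak, g_bna;
  double f_khalf, f_hill, f_tauf;
  double f_mem, f_sr, scale_current, jup_scale, ncx_scale;
};

double pget(const NumericVector &pv, const char *nm) {
  if (!pv.containsElementNamed(nm)) stop("missing engine parameter: %s", nm);
  return pv[nm];
}

Pars load_pars(const NumericVector &pv) {
  Pars p;
  p.dt = pget(pv, "dt"); p.pitch = pget(pv, "pitch");
  p.d_cyto = pget(pv, "d_cyto"); p.d_rbss = pget(pv, "d_rbss");
  p.d_nsr = pget(pv, "d_nsr");
  p.tau_ss = pget(pv, "tau_ss");
  p.v_cyto = pget(pv, "v_cyto_vox"); p.v_rbss = pget(pv, "v_rbss_vox");
  p.vup = pget(pv, "vup"); p.kup = pget(pv, "kup"); p.hup = pget(pv, "hup");
  p.gleak = pget(pv, "gleak");
  p.kncx = pget(pv, "kncx"); p.g_gamma = pget(pv, "ncx_gamma");
  p.km_nai = pget(pv, "ncx_km_nai"); p.km_ca = pget(pv, "ncx_km_ca");
  p.ksat = pget(pv, "ncx_ksat"); p.alpha = pget(pv, "ncx_alpha");
  p.k_allo = pget(pv, "ncx_k_allo");
  p.gpca = pget(pv, "gpca"); p.kpca = pget(pv, "kpca");
  p.gcab = pget(pv, "gcab");
  p.trpn_btot = pget(pv, "trpn_btot"); p.trpn_kon = pget(pv, "trpn_kon");
  p.trpn_koff = pget(pv, "trpn_koff");
  p.rtof = pget(pv, "rtof"); p.cao = pget(pv, "cao");
  p.nao = pget(pv, "nao"); p.nai = pget(pv, "nai");
  p.ko = pget(pv, "ko"); p.ki = pget(pv, "ki"); p.cm = pget(pv, "cm");
  p.tau_ds = pget(pv, "tau_ds"); p.tau_jsr = pget(pv, "tau_jsr");
  p.g_ryr = pget(pv, "g_ryr");
  p.csqn_b = pget(pv, "csqn_b"); p.csqn_k = pget(pv, "csqn_k");
  p.ry_komax = pget(pv, "ry_komax"); p.ry_kca = pget(pv, "ry_kca");
  p.ry_h = pget(pv, "ry_h"); p.ry_kclose = pget(pv, "ry_kclose");
  p.ry_kimax = pget(pv, "ry_kimax"); p.ry_kica = pget(pv, "ry_kica");
  p.ry_hi = pget(pv, "ry_hi"); p.ry_kir = pget(pv, "ry_kir");
  p.ry_krc = pget(pv, "ry_krc"); p.ry_lumk = pget(pv, "ry_lumk");
  p.ry_lumh = pget(pv, "ry_lumh"); p.ry_lummin = pget(pv, "ry_lummin");
  p.ry_kbasal = pget(pv, "ry_kbasal"); p.ry_basalh = pget(pv, "ry_basalh");
  p.lt_aopen = pget(pv, "lt_aopen"); p.lt_bopen = pget(pv, "lt_bopen");
  p.lt_taud = pget(pv, "lt_taud"); p.lt_vhd = pget(pv, "lt_vhd");
  p.lt_kd = pget(pv, "lt_kd"); p.lt_vhf = pget(pv, "lt_vhf");
  p.lt_kf = pget(pv, "lt_kf"); p.lt_taufin = pget(pv, "lt_taufin");
  p.lt_taufrec = pget(pv, "lt_taufrec"); p.lt_kfca = pget(pv, "lt_kfca");
  p.lt_kcai = pget(pv, "lt_kcai"); p.lt_kcarec = pget(pv, "lt_kcarec");
  p.lt_pcal = pget(pv, "lt_pcal"); p.lt_openscale = pget(pv, "lt_open_scale");
  p.g_na = pget(pv, "g_na"); p.g_nal = pget(pv, "g_nal");
  p.g_to = pget(pv, "g_to"); p.g_kr = pget(pv, "g_kr");
  p.g_ks = pget(pv, "g_ks"); p.g_k1 = pget(pv, "g_k1");
  p.p_nak = pget(pv, "p_nak"); p.g_bna = pget(pv, "g_bna");
  p.f_khalf = pget(pv, "force_k_half"); p.f_hill = pget(pv, "force_hill");
  p.f_tauf = pget(pv, "force_tau_f");
  p.f_mem = pget(pv, "f_mem"); p.f_sr = pget(pv, "f_sr");
  p.scale_current = pget(pv, "scale_current");
  p.jup_scale = pget(pv, "jup_scale"); p.ncx_scale = pget(pv, "ncx_scale");
  return p;
}

// conditional sequential binomial == multinomial movement sampling
inline void move_multinomial(Xoshiro &rng, int n, const double *prob,
                             int nt, int *out) {
  double cum = 0.0;
  int remaining = n;
  for (int j = 0; j < nt; ++j) {
    out[j] = 0;
    if (remaining <= 0 || prob[j] <= 0.0) { cum += prob[j]; continue; }
    double pc = prob[j] / (1.0 - cum);
    if (pc > 1.0) pc = 1.0;
    int k = rbinom_stream(rng, remaining, pc);
    out[j] = k;
    remaining -= k;
    cum += prob[j];
  }
}

struct GateTab { double ss[10]; double tau[10]; };
// gate order: m h j ml hl r s xr1 xr2 xs (matches the R module)
GateTab gate_tables(double v) {
  GateTab g;
  double mss = 1.0 / (1.0 + std::exp((-56.86 - v) / 9.03));
  g.ss[0] = mss * mss;
  double am = 1.0 / (1.0 + std::exp((-60 - v) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((v + 35) / 5.0)) +
              0.1 / (1.0 + std::exp((v - 50) / 200.0));
  g.tau[0] = am * bm;
  double hss = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
  g.ss[1] = hss * hss; g.ss[2] = g.ss[1];
  double ah, bh, aj, bj;
  if (v < -40) {
    ah = 0.057 * std::exp(-(v + 80) / 6.8);
    bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
    aj = (-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * v) /
         (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32)));
  }
  g.tau[1] = 1.0 / (ah + bh);
  g.tau[2] = 1.0 / (aj + bj);
  g.ss[3] = 1.0 / (1.0 + std::exp((-42.85 - v) / 5.264));
  g.tau[3] = g.tau[0];
  g.ss[4] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  g.tau[4] = 200.0;
  g.ss[5] = 1.0 / (1.0 + std::exp((20 - v) / 6.0));
  g.tau[5] = 9.5 * std::exp(-(v + 40) * (v + 40) / 1800.0) + 0.8;
  g.ss[6] = 1.0 / (1.0 + std::exp((v + 20) / 5.0));
  g.tau[6] = 85.0 * std::exp(-(v + 45) * (v + 45) / 320.0) +
             5.0 / (1.0 + std::exp((v - 20) / 5.0)) + 3.0;
  g.ss[7] = 1.0 / (1.0 + std::exp((-26 - v) / 7.0));
  g.tau[7] = (450.0 / (1.0 + std::exp((-45 - v) / 10.0))) *
             (6.0 / (1.0 + std::exp((v + 30) / 11.5)));
  g.ss[8] = 1.0 / (1.0 + std::exp((v + 88) / 24.0));
  g.tau[8] = (3.0 / (1.0 + std::exp((-60 - v) / 20.0))) *
             (1.12 / (1.0 + std::exp((v - 60) / 20.0)));
  g.ss[9] = 1.0 / (1.0 + std::exp((-5 - v) / 14.0));
  g.tau[9] = (1400.0 / std::sqrt(1.0 + std::exp((5 - v) / 6.0))) *
             (1.0 / (1.0 + std::exp((v - 35) / 15.0))) + 80.0;
  return g;
}

inline double ltcc_flux_one(double vm, double ca_ds_um, const Pars &p) {
  double x = 2.0 * vm / p.rtof;
  double ca_mm = ca_ds_um * 1e-3;
  double phi;
  if (std::fabs(x) < 1e-6)
    phi = 2.0 * (ca_mm - 0.341 * p.cao) * (1.0 + 0.5 * x);
  else
    phi = x * (ca_mm * std::exp(x) - 0.341 * p.cao) / (std::exp(x) - 1.0);
  return -p.lt_pcal * phi;
}

} // namespace

// [[Rcpp::export]]
List run_core(List geo, List st, NumericVector pv, List ctrl) {
  Pars p = load_pars(pv);

  // --- geometry ------------------------------------------------------
  const IntegerMatrix nbr = geo["nbr"];                 // n_vox x 6, 0 = none
  const int n_vox = nbr.nrow();
  const LogicalVector is_mem = geo["is_mem"];
  const IntegerVector sr_node_of_vox = geo["sr_node_of_vox"];  // 1-based, 0 none
  const IntegerVector sr_off = geo["sr_off"];           // CSR offsets, 0-based
  const IntegerVector sr_adj = geo["sr_adj"];           // 1-based node ids
  const int n_nodes = sr_off.size() - 1;
  const double v_nsr = geo["v_vox_nsr"];
  const IntegerVector dy_vox = geo["dy_vox"];           // 1-based field index
  const IntegerVector dy_node = geo["dy_node"];         // 1-based node id
  const NumericVector dy_vds = geo["dy_vds"], dy_vjsr = geo["dy_vjsr"];
  const IntegerVector dy_nryr = geo["dy_nryr"], dy_nltcc = geo["dy_nltcc"];
  const int n_dy = dy_vox.size();
  const NumericVector buf_b = geo["buf_b"], buf_k = geo["buf_k"];
  const int n_buf = buf_b.size();

  // --- control -------------------------------------------------------
  const int n_steps = as<int>(ctrl["n_steps"]);
  const double dt = p.dt;
  const int stim_period = as<int>(ctrl["stim_period_steps"]);
  const int stim_offset = as<int>(ctrl["stim_offset_steps"]);
  const int stim_dur = as<int>(ctrl["stim_dur_steps"]);
  const double stim_amp = as<double>(ctrl["stim_amp"]);
  const int rec_stride = as<int>(ctrl["record_stride"]);
  const int snap_stride = as<int>(ctrl["snapshot_stride"]);
  const double t0 = as<double>(ctrl["t0"]);
  const double seed = as<double>(ctrl["seed"]);
  const double stream_offset = as<double>(ctrl["stream_offset"]);
  NumericVector clamp;
  bool has_clamp = false;
  if (ctrl.containsElementNamed("clamp") && !Rf_isNull(ctrl["clamp"])) {
    clamp = as<NumericVector>(ctrl["clamp"]);
    has_clamp = true;
    if (clamp.size() < n_steps) stop("clamp waveform shorter than the run");
  }

  // CFL check, naming the offending domain
  double h2 = p.pitch * p.pitch;
  if (dt >= h2 / (6.0 * p.d_cyto)) stop("CFL violation in the cytoplasm domain");
  if (dt >= h2 / (6.0 * p.d_rbss)) stop("CFL violation in the subspace (rbSS) domain");
  if (dt >= h2 / (6.0 * p.d_nsr)) stop("CFL violation in the network-SR domain");

  // --- state (copied; final state returned) --------------------------
  NumericVector ca_cyto = clone(as<NumericVector>(st["ca_cyto"]));
  NumericVector ca_rbss = clone(as<NumericVector>(st["ca_rbss"]));
  NumericVector ca_nsr = clone(as<NumericVector>(st["ca_nsr"]));
  NumericVector trpn = clone(as<NumericVector>(st["trpn"]));
  NumericVector force_f = clone(as<NumericVector>(st["force"]));
  IntegerMatrix ryr = clone(as<IntegerMatrix>(st["ryr"]));    // n_dy x 4
  IntegerMatrix ltcc = clone(as<IntegerMatrix>(st["ltcc"]));  // n_dy x 5
  NumericVector ca_ds = clone(as<NumericVector>(st["ca_ds"]));
  NumericVector ca_jsr = clone(as<NumericVector>(st["ca_jsr"]));
  double vm = as<double>(st["vm"]);
  NumericVector gates = clone(as<NumericVector>(st["gates"]));

  if (ca_cyto.size() != n_vox || ca_rbss.size() != n_vox ||
      ca_nsr.size() != n_nodes)
    stop("field lengths do not match the geometry");

  // per-dyad RNG streams (counter-based seeding keyed by dyad index)
  std::vector<Xoshiro> rng(n_dy);
  for (int m = 0; m < n_dy; ++m)
    rng[m].seed((uint64_t)seed + (uint64_t)stream_offset * 0x51ED2701ULL,
                (uint64_t)(m + 1));

  // --- recording -----------------------------------------------------
  const int n_rec = (rec_stride > 0) ? (n_steps / rec_stride + 1) : 0;
  const int ncol_tr = 14;
  NumericMatrix traces(std::max(n_rec, 0), ncol_tr);
  CharacterVector trnames = CharacterVector::create(
    "t", "vm", "ca_cyto", "ca_rbss", "ca_nsr", "ca_jsr", "force",
    "i_cal", "i_naca", "frac_o_ryr", "frac_o_ltcc", "sd_nsr", "stim", "i_stim");
  const int n_snap = (snap_stride > 0) ? (n_steps / snap_stride + 1) : 0;
  NumericMatrix snap_ca(std::max(n_snap, 0), (n_snap > 0) ? n_vox : 0);
  NumericMatrix snap_nsr(std::max(n_snap, 0), (n_snap > 0) ? n_nodes : 0);
  NumericVector snap_t(std::max(n_snap, 0));
  int rec_i = 0, snap_i = 0;

  std::vector<double> phi_cyto(n_vox), phi_rbss(n_vox), lap(n_vox);
  std::vector<double> phi_nsr(n_nodes);
  std::vector<double> jds(n_dy), jjsr(n_dy), jcal(n_dy);
  const double f_pa = 0.096485;
  const double v_rbss = p.v_rbss;
  const double ena = p.rtof * std::log(p.nao / p.nai);
  const double ek = p.rtof * std::log(p.ko / p.ki);
  const double eks = p.rtof * std::log((p.ko + 0.03 * p.nao) / (p.ki + 0.03 * p.nai));

  double i_cal_rec = 0, i_naca_rec = 0, stim_rec = 0;

  auto record = [&](double t) {
    double mc = 0, mr = 0, mn = 0, mj = 0, mf = 0, oR = 0, oL = 0, nR = 0, nL = 0;
    for (int i = 0; i < n_vox; ++i) { mc += ca_cyto[i]; mr += ca_rbss[i]; mf += force_f[i]; }
    for (int q = 0; q < n_nodes; ++q) mn += ca_nsr[q];
    double mn_mean = mn / n_nodes, sdn = 0;
    for (int q = 0; q < n_nodes; ++q) {
      double d = ca_nsr[q] - mn_mean; sdn += d * d;
    }
    for (int m = 0; m < n_dy; ++m) {
      mj += ca_jsr[m];
      oR += ryr(m, 1); nR += dy_nryr[m];
      oL += ltcc(m, 2); nL += dy_nltcc[m];
    }
    traces(rec_i, 0) = t; traces(rec_i, 1) = vm;
    traces(rec_i, 2) = mc / n_vox; traces(rec_i, 3) = mr / n_vox;
    traces(rec_i, 4) = mn_mean; traces(rec_i, 5) = (n_dy > 0) ? mj / n_dy : 0;
    traces(rec_i, 6) = mf / n_vox;
    traces(rec_i, 7) = i_cal_rec; traces(rec_i, 8) = i_naca_rec;
    traces(rec_i, 9) = (nR > 0) ? oR / nR : 0;
    traces(rec_i, 10) = (nL > 0) ? oL / nL : 0;
    traces(rec_i, 11) = std::sqrt(sdn / n_nodes);
    traces(rec_i, 12) = stim_rec; traces(rec_i, 13) = stim_rec;
    ++rec_i;
  };
  auto snapshot = [&](double t) {
    for (int i = 0; i < n_vox; ++i) snap_ca(snap_i, i) = ca_cyto[i];
    for (int q = 0; q < n_nodes; ++q) snap_nsr(snap_i, q) = ca_nsr[q];
    snap_t[snap_i] = t;
    ++snap_i;
  };
  if (n_rec > 0) record(t0);
  if (n_snap > 0) snapshot(t0);

  // NCX per-step voltage factors cache
  for (int step = 0; step < n_steps; ++step) {
    if ((step & 4095) == 0) Rcpp::checkUserInterrupt();
    double vnow = has_clamp ? clamp[step] : vm;

    // stimulus
    double istim = 0;
    if (stim_period > 0) {
      int ph = (step - stim_offset) % stim_period;
      if (ph >= 0 && ph < stim_dur) istim = stim_amp;
    }
    stim_rec = istim;

    // --- dyads -------------------------------------------------------
    double sum_jcal_v = 0;
    for (int m = 0; m < n_dy; ++m) {
      double cds = ca_ds[m], cjsr = ca_jsr[m];
      // RyR rates (C O I R)
      double hill = std::pow(cds, p.ry_h) /
        (std::pow(cds, p.ry_h) + std::pow(p.ry_kca, p.ry_h));
      double xh = std::pow(cjsr, p.ry_lumh);
      double kh = std::pow(p.ry_lumk, p.ry_lumh);
      double lum0 = xh / (xh + kh);
      double lumn = 1.0 / (1.0 + kh);
      double lum = lum0 / lumn;
      if (lum < p.ry_lummin) lum = p.ry_lummin;
      double basal = p.ry_kbasal * std::pow(cjsr / p.ry_lumk, p.ry_basalh);
      double r_co = p.ry_komax * hill * lum + basal;
      double r_oc = p.ry_kclose;
      double r_oi = p.ry_kimax * std::pow(cds, p.ry_hi) /
        (std::pow(cds, p.ry_hi) + std::pow(p.ry_kica, p.ry_hi));
      double r_ir = p.ry_kir, r_rc = p.ry_krc;
      double maxp = std::max(std::max(r_co, r_oc + r_oi),
                             std::max(r_ir, r_rc)) * dt;
      // LTCC rates (d1 d2 d3 IV ICa)
      double dss = 1.0 / (1.0 + std::exp(-(vnow + p.lt_vhd) / p.lt_kd));
      double fss = 1.0 / (1.0 + std::exp((vnow + p.lt_vhf) / p.lt_kf));
      double l_12 = dss / p.lt_taud, l_21 = (1.0 - dss) / p.lt_taud;
      double l_23 = p.lt_aopen * p.lt_openscale, l_32 = p.lt_bopen;
      double l_2iv = (1.0 - fss) / p.lt_taufin;
      double l_3iv = (1.0 - fss) / p.lt_taufin;
      double l_iv1 = fss / p.lt_taufrec;
      double l_3ica = p.lt_kfca * cds / (cds + p.lt_kcai);
      double l_ica2 = p.lt_kcarec * fss;   // recovery only near rest
      maxp = std::max(maxp, std::max(std::max(l_12, l_21 + l_23 + l_2iv),
             std::max(l_23, l_32 + l_3iv + l_3ica)) * dt);
      maxp = std::max(maxp, std::max(l_iv1, l_ica2) * dt);
      if (maxp > 0.2)
        stop("transition probability rate*dt exceeds 0.2 at dyad %d; use a smaller dt", m + 1);

      int mv[3];
      // RyR: from C, from O (two destinations), from I, from R
      Xoshiro &g = rng[m];
      int c = ryr(m, 0), o = ryr(m, 1), ii = ryr(m, 2), rr = ryr(m, 3);
      double prC[1] = { r_co * dt };
      move_multinomial(g, c, prC, 1, mv);
      int c_to_o = mv[0];
      double prO[2] = { r_oc * dt, r_oi * dt };
      move_multinomial(g, o, prO, 2, mv);
      int o_to_c = mv[0], o_to_i = mv[1];
      double prI[1] = { r_ir * dt };
      move_multinomial(g, ii, prI, 1, mv);
      int i_to_r = mv[0];
      double prR[1] = { r_rc * dt };
      move_multinomial(g, rr, prR, 1, mv);
      int r_to_c = mv[0];
      ryr(m, 0) = c - c_to_o + o_to_c + r_to_c;
      ryr(m, 1) = o - o_to_c - o_to_i + c_to_o;
      ryr(m, 2) = ii - i_to_r + o_to_i;
      ryr(m, 3) = rr - r_to_c + i_to_r;

      // LTCC
      int d1 = ltcc(m, 0), d2 = ltcc(m, 1), d3 = ltcc(m, 2),
          iv = ltcc(m, 3), ica = ltcc(m, 4);
      double pr1[1] = { l_12 * dt };
      move_multinomial(g, d1, pr1, 1, mv);
      int m12 = mv[0];
      double pr2[3] = { l_21 * dt, l_23 * dt, l_2iv * dt };
      move_multinomial(g, d2, pr2, 3, mv);
      int m21 = mv[0], m23 = mv[1], m2iv = mv[2];
      double pr3[3] = { l_32 * dt, l_3iv * dt, l_3ica * dt };
      move_multinomial(g, d3, pr3, 3, mv);
      int m32 = mv[0], m3iv = mv[1], m3ica = mv[2];
      double priv[1] = { l_iv1 * dt };
      move_multinomial(g, iv, priv, 1, mv);
      int miv1 = mv[0];
      double prica[1] = { l_ica2 * dt };
      move_multinomial(g, ica, prica, 1, mv);
      int mica2 = mv[0];
      ltcc(m, 0) = d1 - m12 + m21 + miv1 + mica2;
      ltcc(m, 1) = d2 - m21 - m23 - m2iv + m12 + m32;
      ltcc(m, 2) = d3 - m32 - m3iv - m3ica + m23;
      ltcc(m, 3) = iv - miv1 + m3iv + m2iv;
      ltcc(m, 4) = ica - mica2 + m3ica;

      // fluxes: quasi-steady cleft with the NEW open counts, cds as previous
      int n_o_ryr = ryr(m, 1), n_o_ltcc = ltcc(m, 2);
      double jc = n_o_ltcc * ltcc_flux_one(vnow, cds, p);
      double k_rel = n_o_ryr * p.g_ryr / dy_vds[m];
      double rb = ca_rbss[dy_vox[m] - 1];
      double cds_new = (rb + p.tau_ds * (k_rel * cjsr * 1000.0 + jc)) /
        (1.0 + p.tau_ds * k_rel);
      double j_rel = k_rel * (cjsr * 1000.0 - cds_new);
      double j_ds = j_rel + jc - (cds_new - cds) / dt;
      double ca_nsr_here = ca_nsr[dy_node[m] - 1];
      double j_jsr = (cjsr - ca_nsr_here) / p.tau_jsr;
      double beta_jsr = 1.0 /
        (1.0 + p.csqn_b * p.csqn_k / ((p.csqn_k + cjsr) * (p.csqn_k + cjsr)));
      double cjsr_new = cjsr + dt * beta_jsr *
        (-j_rel * 1e-3 * dy_vds[m] / dy_vjsr[m] - j_jsr);
      if (cjsr_new < 0 || cds_new < 0)
        stop("negative dyad concentration at dyad %d; dt too large or pathological parameters", m + 1);
      ca_ds[m] = cds_new; ca_jsr[m] = cjsr_new;
      jds[m] = j_ds; jjsr[m] = j_jsr; jcal[m] = jc;
      sum_jcal_v += jc * dy_vds[m];
    }

    // --- reaction terms ---------------------------------------------
    // NCX voltage factors (vm is global: compute once per step)
    double x = vnow / p.rtof;
    double e1 = std::exp(p.g_gamma * x), e2 = std::exp((p.g_gamma - 1.0) * x);
    double ncx_den = (p.km_nai * p.km_nai * p.km_nai + p.nao * p.nao * p.nao) *
      (p.km_ca + p.cao) * (1.0 + p.ksat * e2);
    double ncx_a = e1 * p.nai * p.nai * p.nai * p.cao;
    double ncx_b = e2 * p.nao * p.nao * p.nao * p.alpha * 1e-3;
    double sum_naca = 0, sum_pca = 0, sum_cab = 0;

    for (int q = 0; q < n_nodes; ++q) phi_nsr[q] = 0.0;
    for (int i = 0; i < n_vox; ++i) {
      double ca = ca_cyto[i], rb = ca_rbss[i], occ = trpn[i];
      double j_ss = (rb - ca) / p.tau_ss;
      double on = p.trpn_kon * ca * (1.0 - occ);
      double off = p.trpn_koff * occ;
      double j_trpn = p.trpn_btot * (on - off);
      double phi = (v_rbss / p.v_cyto) * j_ss - j_trpn;
      if (is_mem[i]) {
        double allo = ca * ca / (ca * ca + p.k_allo * p.k_allo);
        double j_naca = p.ncx_scale * p.f_mem * p.kncx * allo *
          (ncx_a - ncx_b * ca) / ncx_den;
        double j_pca = -p.f_mem * p.gpca * ca / (ca + p.kpca);
        double e_ca = 0.5 * p.rtof * std::log(p.cao / (ca * 1e-3));
        double j_cab = p.f_mem * p.gcab * (e_ca - vnow);
        phi += j_naca + j_pca + j_cab;
        sum_naca += j_naca; sum_pca += j_pca; sum_cab += j_cab;
      }
      int nd = sr_node_of_vox[i];
      if (nd > 0) {
        double cah = (p.hup == 2.0) ? ca * ca : std::pow(ca, p.hup);
        double kuh = (p.hup == 2.0) ? p.kup * p.kup : std::pow(p.kup, p.hup);
        double j_up = p.jup_scale * p.vup * cah / (cah + kuh);
        double j_leak = p.gleak * ca_nsr[nd - 1] * 1000.0;
        double net = p.f_sr * (j_up - j_leak);
        phi -= net;
        phi_nsr[nd - 1] += net * (p.v_cyto / v_nsr) * 1e-3;
      }
      phi_cyto[i] = phi;
      phi_rbss[i] = -j_ss;
      trpn[i] = occ + dt * (on - off);
      // force kinetics
      double och = (p.f_hill == 3.0) ? occ * occ * occ : std::pow(occ, p.f_hill);
      double fkh = (p.f_hill == 3.0) ? p.f_khalf * p.f_khalf * p.f_khalf
                                     : std::pow(p.f_khalf, p.f_hill);
      double fss_v = och / (och + fkh);
      force_f[i] += dt * (fss_v - force_f[i]) / p.f_tauf;
    }
    for (int m = 0; m < n_dy; ++m) {
      phi_rbss[dy_vox[m] - 1] += jds[m] * dy_vds[m] / v_rbss;
      phi_nsr[dy_node[m] - 1] += jjsr[m] * dy_vjsr[m] / v_nsr;
    }

    // --- currents and ionic step ------------------------------------
    double i_naca = f_pa * sum_naca * p.v_cyto * p.scale_current / p.cm;
    double i_pca = -2.0 * f_pa * sum_pca * p.v_cyto * p.scale_current / p.cm;
    double i_cab = -2.0 * f_pa * sum_cab * p.v_cyto * p.scale_current / p.cm;
    double i_cal = -2.0 * f_pa * sum_jcal_v * p.scale_current / p.cm;
    i_cal_rec = i_cal; i_naca_rec = i_naca;

    GateTab gt = gate_tables(vnow);
    for (int gi = 0; gi < 10; ++gi)
      gates[gi] = gt.ss[gi] + (gates[gi] - gt.ss[gi]) * std::exp(-dt / gt.tau[gi]);
    double ak1 = 0.1 / (1.0 + std::exp(0.06 * (vnow - ek - 200.0)));
    double bk1 = (3.0 * std::exp(0.0002 * (vnow - ek + 100.0)) +
                  std::exp(0.1 * (vnow - ek - 10.0))) /
                 (1.0 + std::exp(-0.5 * (vnow - ek)));
    double xk1 = ak1 / (ak1 + bk1);
    double i_na = p.g_na * gates[0] * gates[0] * gates[0] * gates[1] * gates[2] * (vnow - ena);
    double i_nal = p.g_nal * gates[3] * gates[4] * (vnow - ena);
    double i_to = p.g_to * gates[5] * gates[6] * (vnow - ek);
    double i_kr = p.g_kr * std::sqrt(p.ko / 5.4) * gates[7] * gates[8] * (vnow - ek);
    double i_ks = p.g_ks * gates[9] * gates[9] * (vnow - eks);
    double i_k1 = p.g_k1 * std::sqrt(p.ko / 5.4) * xk1 * (vnow - ek);
    double i_nak = p.p_nak * (p.ko / (p.ko + 1.0)) * (p.nai / (p.nai + 40.0)) /
      (1.0 + 0.1245 * std::exp(-0.1 * vnow / p.rtof) + 0.0353 * std::exp(-vnow / p.rtof));
    double i_bna = p.g_bna * (vnow - ena);
    double i_sum = i_na + i_nal + i_to + i_kr + i_ks + i_k1 + i_nak + i_bna +
      i_cal + i_naca + i_pca + i_cab;
    if (has_clamp) {
      vm = (step + 1 < clamp.size()) ? clamp[step + 1] : clamp[n_steps - 1];
    } else {
      vm = vnow - dt * (i_sum + istim);
    }
    if (!std::isfinite(vm)) stop("membrane potential became non-finite");

    // --- diffusion + field update -----------------------------------
    for (int i = 0; i < n_vox; ++i) {
      double l = 0;
      double f0 = ca_cyto[i];
      for (int c2 = 0; c2 < 6; ++c2) {
        int nbi = nbr(i, c2);
        if (nbi > 0) l += ca_cyto[nbi - 1] - f0;
      }
      lap[i] = l / h2;
    }
    for (int i = 0; i < n_vox; ++i) {
      double ca = ca_cyto[i];
      double denom = 1.0;
      for (int b = 0; b < n_buf; ++b) {
        double kk = buf_k[b] + ca;
        denom += buf_b[b] * buf_k[b] / (kk * kk);
      }
      double beta = 1.0 / denom;
      ca_cyto[i] = ca + dt * beta * (p.d_cyto * lap[i] + phi_cyto[i]);
      if (ca_cyto[i] < 0)
        stop("negative concentration in the cytoplasm domain at voxel %d", i + 1);
    }
    for (int i = 0; i < n_vox; ++i) {
      double l = 0, f0 = ca_rbss[i];
      for (int c2 = 0; c2 < 6; ++c2) {
        int nbi = nbr(i, c2);
        if (nbi > 0) l += ca_rbss[nbi - 1] - f0;
      }
      lap[i] = l / h2;
    }
    for (int i = 0; i < n_vox; ++i) {
      ca_rbss[i] += dt * (p.d_rbss * lap[i] + phi_rbss[i]);
      if (ca_rbss[i] < 0)
        stop("negative concentration in the subspace (rbSS) domain at voxel %d", i + 1);
    }
    {
      std::vector<double> lapn(n_nodes);
      for (int q = 0; q < n_nodes; ++q) {
        double l = 0, f0 = ca_nsr[q];
        for (int a = sr_off[q]; a < sr_off[q + 1]; ++a)
          l += ca_nsr[sr_adj[a] - 1] - f0;
        lapn[q] = l / h2;
      }
      for (int q = 0; q < n_nodes; ++q) {
        ca_nsr[q] += dt * (p.d_nsr * lapn[q] + phi_nsr[q]);
        if (ca_nsr[q] < 0)
          stop("negative concentration in the network-SR domain at node %d", q + 1);
      }
    }

    // --- recording ---------------------------------------------------
    double tnow = t0 + (step + 1) * dt;
    if (rec_stride > 0 && ((step + 1) % rec_stride == 0) && rec_i < n_rec)
      record(tnow);
    if (snap_stride > 0 && ((step + 1) % snap_stride == 0) && snap_i < n_snap)
      snapshot(tnow);
  }

  colnames(traces) = trnames;
  List final_state = List::create(
    _["ca_cyto"] = ca_cyto, _["ca_rbss"] = ca_rbss, _["ca_nsr"] = ca_nsr,
    _["trpn"] = trpn, _["force"] = force_f, _["ryr"] = ryr, _["ltcc"] = ltcc,
    _["ca_ds"] = ca_ds, _["ca_jsr"] = ca_jsr, _["vm"] = vm, _["gates"] = gates);
  return List::create(
    _["traces"] = traces,
    _["snap_ca"] = snap_ca, _["snap_nsr"] = snap_nsr, _["snap_t"] = snap_t,
    _["state"] = final_state);
}
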