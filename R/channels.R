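# Stochastic dyad channel clusters: RyR and LTCC Markov chains, the analytic
# quasi-steady cleft Ca2+, and the dyad-local fluxes and jSR update.

ryr_states <- c("C", "O", "I", "R")
ltcc_states <- c("d1", "d2", "d3", "IV", "ICa")

# RyR cluster transition-rate matrix (/ms). 4-state cycle
# C -> O (Ca-activated, saturating Hill, scaled by jSR-luminal load),
# O -> C, O -> I (Ca-dependent inactivation), I -> R -> C (recovery).
ryr_rates <- function(ca_ds, ca_jsr, p) {
  r <- p$ryr
  hill <- ca_ds^r$h / (ca_ds^r$h + r$kca^r$h)
  lum0 <- function(x) x^r$lum_h / (x^r$lum_h + r$lum_k^r$lum_h)
  lum <- max(r$lum_min, lum0(ca_jsr) / lum0(1.0))  # normalised to 1 at 1 mM
  basal <- r$k_basal * (ca_jsr / r$lum_k)^r$basal_h
  q <- matrix(0, 4, 4, dimnames = list(ryr_states, ryr_states))
  q["C", "O"] <- r$komax * hill * lum + basal
  q["O", "C"] <- r$kclose
  q["O", "I"] <- r$kimax * ca_ds^r$hi / (ca_ds^r$hi + r$kica^r$hi)
  q["I", "R"] <- r$k_ir
  q["R", "C"] <- r$k_rc
  q
}

# LTCC cluster transition-rate matrix (/ms). Closed chain d1 <-> d2 with
# voltage-dependent activation, scalable opening d2 -> d3, voltage-dependent
# inactivation from the open state and Ca-dependent inactivation driven by
# cleft Ca2+.
ltcc_rates <- function(vm, ca_ds, p, open_rate_scale = 1) {
  l <- p$ltcc
  dss <- 1 / (1 + exp(-(vm + l$v_half_d) / l$k_d))
  fss <- 1 / (1 + exp((vm + l$v_half_f) / l$k_f))
  q <- matrix(0, 5, 5, dimnames = list(ltcc_states, ltcc_states))
  q["d1", "d2"] <- dss / l$tau_d
  q["d2", "d1"] <- (1 - dss) / l$tau_d
  q["d2", "d3"] <- l$a_open * open_rate_scale
  q["d3", "d2"] <- l$b_open
  q["d2", "IV"] <- (1 - fss) / l$tau_f_in
  q["d3", "IV"] <- (1 - fss) / l$tau_f_in
  q["IV", "d1"] <- fss / l$tau_f_rec
  q["d3", "ICa"] <- l$k_fca * ca_ds / (ca_ds + l$kca_i)
  q["ICa", "d1"] <- l$k_ca_rec * fss   # recovery only near rest
  q
}

#' Advance a Markov channel cluster one fixed time step
#'
#' Each channel transitions independently with probability `rate * dt`
#' (standard per-channel Monte-Carlo at fixed step): for every occupied state
#' the numbers moving along each outgoing transition are drawn from the
#' corresponding multinomial, so occupancy is conserved exactly.
#'
#' @param counts named integer vector of per-state channel counts.
#' @param q square transition-rate matrix (/ms), zero diagonal.
#' @param dt time step (ms). An error is raised if any single transition has
#'   `rate * dt > 0.2` (the fixed-step scheme is then unreliable).
#' @return Integer vector of updated counts (same names, same sum).
#' @export
step_markov_cluster <- function(counts, q, dt) {
  stopifnot(dt > 0, nrow(q) == length(counts))
  p <- q * dt
  if (max(p) > 0.2)
    stop("transition probability rate*dt = ", signif(max(p), 3),
         " exceeds 0.2; use a smaller dt")
  new <- counts
  for (i in seq_along(counts)) {
    n_i <- counts[i]
    if (n_i == 0L) next
    pi <- p[i, ]
    s <- sum(pi)
    if (s <= 0) next
    mov <- stats::rmultinom(1, n_i, c(1 - s, pi))[, 1]
    leave <- n_i - mov[1]
    if (leave > 0L) {
      new[i] <- new[i] - leave
      new <- new + mov[-1]
    }
  }
  new
}

#' RyR cluster Monte-Carlo step
#'
#' @param state named integer vector over states `C, O, I, R` summing to the
#'   cluster size.
#' @param ca_ds dyadic cleft Ca2+ (uM).
#' @param ca_jsr junctional SR Ca2+ (mM).
#' @param dt time step (ms).
#' @param params full parameter list (see [default_params()]); rates come
#'   from `params$channels$ryr`.
#' @return Updated state vector.
#' @export
step_ryr_cluster <- function(state, ca_ds, ca_jsr, dt, params = default_params()) {
  stopifnot(ca_ds >= 0, ca_jsr >= 0)
  step_markov_cluster(state, ryr_rates(ca_ds, ca_jsr, params$channels), dt)
}

#' LTCC cluster Monte-Carlo step
#'
#' @param state named integer vector over states `d1, d2, d3, IV, ICa`
#'   (`d3` is the open state).
#' @param vm membrane potential (mV).
#' @param ca_ds dyadic cleft Ca2+ (uM).
#' @param dt time step (ms).
#' @param params full parameter list.
#' @param open_rate_scale multiplies the `d2 -> d3` opening rate (the
#'   open-probability scaling used by the alternans and overload protocols).
#' @return Updated state vector.
#' @export
step_ltcc_cluster <- function(state, vm, ca_ds, dt, params = default_params(),
                              open_rate_scale = 1) {
  stopifnot(ca_ds >= 0, open_rate_scale >= 0)
  step_markov_cluster(state, ltcc_rates(vm, ca_ds, params$channels, open_rate_scale), dt)
}

#' Quasi-steady dyadic cleft Ca2+ concentration
#'
#' The cleft volume is small enough that within one fixed step it reaches the
#' steady state of its flux balance; setting the cleft ODE to zero gives
#' `ca_ds = (ca_rbss + tau_ds * (k_rel * ca_jsr + j_cal)) / (1 + tau_ds * k_rel)`
#' with `k_rel = n_o_ryr * g_ryr / v_ds` (jSR Ca2+ converted from mM to uM).
#'
#' @param ca_rbss subspace Ca2+ at the host voxel (uM).
#' @param ca_jsr junctional SR Ca2+ (mM).
#' @param n_o_ryr number of open RyRs.
#' @param j_cal total LTCC flux into the cleft (uM/ms, cleft volume).
#' @param tau_ds cleft-subspace exchange time constant (ms).
#' @param g_ryr maximal per-channel RyR flux rate (um^3/ms).
#' @param v_ds cleft volume (um^3).
#' @return Cleft Ca2+ (uM).
#' @export
cleft_quasi_steady <- function(ca_rbss, ca_jsr, n_o_ryr, j_cal, tau_ds, g_ryr, v_ds) {
  stopifnot(tau_ds > 0, v_ds > 0)
  k_rel <- n_o_ryr * g_ryr / v_ds
  (ca_rbss + tau_ds * (k_rel * ca_jsr * 1000 + j_cal)) / (1 + tau_ds * k_rel)
}

# GHK-type flux into the cleft per open LTCC (uM/ms referred to v_ds);
# positive into the cell at physiological potentials.
ltcc_flux_per_channel <- function(vm, ca_ds, const, p_cal) {
  x <- 2 * vm / const$rtof
  ca_i <- ca_ds * 1e-3          # mM
  if (abs(x) < 1e-6) {
    phi <- 2 * (ca_i - 0.341 * const$cao) * (1 + x / 2)
  } else {
    phi <- x * (ca_i * exp(x) - 0.341 * const$cao) / (exp(x) - 1)
  }
  -p_cal * phi
}

#' Create a dyad state
#'
#' @param params full parameter list.
#' @param ca_jsr initial junctional SR Ca2+ (mM).
#' @param ca_ds initial cleft Ca2+ (uM).
#' @param n_ryr,n_ltcc cluster sizes (defaults from `params`).
#' @return A `dyad_state` list: RyR and LTCC state-count vectors, cleft and
#'   jSR Ca2+, volumes.
#' @export
new_dyad_state <- function(params = default_params(), ca_jsr = 1.0, ca_ds = 0.1,
                           n_ryr = NULL, n_ltcc = NULL) {
  ch <- params$channels
  n_ryr <- if (is.null(n_ryr)) ch$n_ryr else as.integer(n_ryr)
  n_ltcc <- if (is.null(n_ltcc)) ch$n_ltcc else as.integer(n_ltcc)
  stopifnot(n_ryr >= 1, n_ltcc >= 0)
  ryr <- setNames(c(n_ryr, 0L, 0L, 0L), ryr_states)
  ltcc <- setNames(c(n_ltcc, 0L, 0L, 0L, 0L), ltcc_states)
  structure(list(ryr = ryr, ltcc = ltcc, ca_ds = ca_ds, ca_jsr = ca_jsr,
                 v_ds = ch$v_ds, v_jsr = ch$v_jsr), class = "dyad_state")
}

#' Advance one dyad by one time step
#'
#' Steps both channel clusters, recomputes the quasi-steady cleft Ca2+,
#' evaluates the cleft-to-subspace flux `j_ds` (the release plus trigger flux
#' corrected for the change in cleft content, equal to
#' `(ca_ds - ca_rbss) / tau_ds` for a stationary cleft) and the jSR refill
#' flux `j_jsr = (ca_jsr - ca_nsr) / tau_jsr`, and
#' advances the jSR store with instantaneous calsequestrin buffering.
#' Returned fluxes are volume-unscaled (the caller applies the volume ratios
#' when adding them to the subspace and network-SR reaction terms).
#'
#' @param dy a `dyad_state`.
#' @param ca_rbss subspace Ca2+ at the host voxel (uM).
#' @param ca_nsr network SR Ca2+ at the coupled strand node (mM).
#' @param vm membrane potential (mV).
#' @param dt time step (ms).
#' @param params full parameter list.
#' @param open_rate_scale LTCC opening-rate scale.
#' @return list with the updated `dyad_state` and the fluxes `j_ds`
#'   (uM/ms, cleft volume), `j_jsr` (mM/ms, jSR volume), `j_cal`, `j_rel`.
#' @export
update_dyad <- function(dy, ca_rbss, ca_nsr, vm, dt, params = default_params(),
                        open_rate_scale = 1) {
  stopifnot(inherits(dy, "dyad_state"), is.finite(ca_rbss), is.finite(ca_nsr),
            is.finite(vm), dt > 0)
  ch <- params$channels
  dy$ryr <- step_ryr_cluster(dy$ryr, dy$ca_ds, dy$ca_jsr, dt, params)
  dy$ltcc <- step_ltcc_cluster(dy$ltcc, vm, dy$ca_ds, dt, params, open_rate_scale)

  n_o_ryr <- dy$ryr[["O"]]
  n_o_ltcc <- dy$ltcc[["d3"]]
  j_cal <- n_o_ltcc * ltcc_flux_per_channel(vm, dy$ca_ds, params$const, ch$ltcc$p_cal)
  ca_ds <- cleft_quasi_steady(ca_rbss, dy$ca_jsr, n_o_ryr, j_cal,
                              ch$tau_ds, ch$g_ryr, dy$v_ds)

  k_rel <- n_o_ryr * ch$g_ryr / dy$v_ds
  j_rel <- k_rel * (dy$ca_jsr * 1000 - ca_ds)       # uM/ms, cleft volume
  # cleft-to-subspace flux: the quasi-steady cleft stores no mass of its own,
  # so the subspace receives the release and trigger fluxes minus the change
  # in cleft content; this equals (ca_ds - ca_rbss)/tau_ds whenever the cleft
  # is stationary and keeps the discrete scheme exactly conservative.
  j_ds <- j_rel + j_cal - (ca_ds - dy$ca_ds) / dt   # uM/ms, cleft volume
  j_jsr <- (dy$ca_jsr - ca_nsr) / ch$tau_jsr        # mM/ms, jSR volume

  beta_jsr <- 1 / (1 + ch$csqn_b * ch$csqn_k / (ch$csqn_k + dy$ca_jsr)^2)
  ca_jsr <- dy$ca_jsr + dt * beta_jsr *
    (-j_rel * 1e-3 * dy$v_ds / dy$v_jsr - j_jsr)
  if (ca_jsr < 0 || ca_ds < 0)
    stop("negative dyad concentration after step; dt too large or ",
         "pathological parameters")
  dy$ca_ds <- ca_ds
  dy$ca_jsr <- ca_jsr
  list(state = dy, j_ds = j_ds, j_jsr = j_jsr, j_cal = j_cal, j_rel = j_rel)
}
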