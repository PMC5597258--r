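p_def <- default_params()

test_that("Markov cluster steps conserve occupancy and respect zero rates", {
  st <- setNames(c(60L, 25L, 10L, 5L), caspatial:::ryr_states)
  expect_identical(step_markov_cluster(st, matrix(0, 4, 4), 0.01), st)

  set.seed(42)
  for (rep in 1:200) {
    q <- matrix(runif(16, 0, 15), 4, 4)
    diag(q) <- 0
    st <- step_markov_cluster(st, q, 0.01)
    expect_identical(sum(st), 100L)
    expect_true(all(st >= 0L))
  }

  qbad <- matrix(0, 4, 4); qbad[1, 2] <- 25   # rate*dt = 0.25 > 0.2
  expect_error(step_markov_cluster(st, qbad, 0.01), "0.2")
})

test_that("newly opened channels follow the per-channel binomial law", {
  alpha <- 2; dt <- 0.01; n <- 100L
  q <- matrix(0, 2, 2, dimnames = list(c("C", "O"), c("C", "O")))
  q["C", "O"] <- alpha
  set.seed(7)
  tot <- 0L
  trials <- 1000
  for (i in seq_len(trials)) {
    st <- step_markov_cluster(setNames(c(n, 0L), c("C", "O")), q, dt)
    tot <- tot + st[["O"]]
  }
  pexp <- alpha * dt
  expect_lt(abs(tot - trials * n * pexp),
            4 * sqrt(trials * n * pexp * (1 - pexp)))
})

test_that("two-state cluster relaxes to the alpha/(alpha+beta) occupancy", {
  alpha <- 0.05; beta <- 0.05; dt <- 0.01; n <- 100L
  q <- matrix(c(0, beta, alpha, 0), 2, 2)  # states (C, O); q[1,2]=alpha
  set.seed(11)
  nstep <- 3e5
  n_open <- 0L; st <- c(n, 0L)
  trace <- integer(nstep)
  for (t in seq_len(nstep)) {
    # direct binomial update of the two-state cluster (same law as
    # step_markov_cluster, but cheap enough for a long run)
    open_new <- rbinom(1, st[1], alpha * dt)
    close_new <- rbinom(1, st[2], beta * dt)
    st <- c(st[1] - open_new + close_new, st[2] + open_new - close_new)
    trace[t] <- st[2]
  }
  frac <- mean(trace / n)
  # batch-means standard error (the trajectory is autocorrelated)
  nb <- 50
  bm <- colMeans(matrix(trace[seq_len(nb * (nstep %/% nb))] / n, ncol = nb))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(frac - alpha / (alpha + beta)), 3 * se)

  # step_markov_cluster agrees with the direct law over a shorter run
  st2 <- setNames(c(n, 0L), c("C", "O"))
  acc <- 0
  for (t in seq_len(2e4)) {
    st2 <- step_markov_cluster(st2, q, dt)
    acc <- acc + st2[["O"]]
  }
  expect_lt(abs(acc / (2e4 * n) - 0.5), 0.05)
})

test_that("LTCC gating honours the opening-rate scale and voltage dependence", {
  st <- setNames(c(0L, 15L, 0L, 0L, 0L), caspatial:::ltcc_states)
  set.seed(1)
  s <- st
  for (t in 1:5000) {
    s <- step_ltcc_cluster(s, vm = 0, ca_ds = 1, dt = 0.01, p_def,
                           open_rate_scale = 0)
    expect_identical(s[["d3"]], 0L)
    if (t == 5L) break  # no need to iterate long; opening is impossible
  }

  # dt -> 0: state unchanged
  s0 <- setNames(c(10L, 3L, 1L, 1L, 0L), caspatial:::ltcc_states)
  expect_identical(step_ltcc_cluster(s0, 0, 1, 1e-12, p_def), s0)

  # resting potential: essentially no openings compared with 0 mV
  open_frac <- function(vm, seed) {
    set.seed(seed)
    s <- setNames(c(15L, 0L, 0L, 0L, 0L), caspatial:::ltcc_states)
    tot <- 0
    for (t in 1:20000) {
      s <- step_ltcc_cluster(s, vm, 0.2, 0.01, p_def)
      tot <- tot + s[["d3"]]
    }
    tot / (20000 * 15)
  }
  f_rest <- open_frac(-80, 2)
  f_act <- open_frac(0, 3)
  expect_gt(f_act, 0.001)   # depolarisation does open channels
  expect_lt(f_rest, 0.01 * f_act)
})

test_that("LTCC mean open count scales monotonically with the opening rate", {
  mean_open <- function(scale, seed) {
    set.seed(seed)
    s <- setNames(c(15L, 0L, 0L, 0L, 0L), caspatial:::ltcc_states)
    tot <- 0
    for (t in 1:8000) {   # 80 ms depolarising pulse
      s <- step_ltcc_cluster(s, 0, 0.5, 0.01, p_def, open_rate_scale = scale)
      tot <- tot + s[["d3"]]
    }
    tot / 8000
  }
  m1 <- mean_open(1, 4); m05 <- mean_open(0.5, 5); m025 <- mean_open(0.25, 6)
  expect_gt(m1, m05)
  expect_gt(m05, m025)
})

test_that("quasi-steady cleft concentration matches its defining limits", {
  # no release, no trigger flux: cleft equals subspace exactly
  expect_identical(cleft_quasi_steady(0.1, 1.0, 0, 0, 0.002, 2e-3, 1e-3), 0.1)

  # tau_ds * k_rel -> infinity: cleft approaches the jSR concentration
  ca <- cleft_quasi_steady(0.1, 1.0, 1e9, 0, 0.002, 2e-3, 1e-3)
  expect_equal(ca, 1000, tolerance = 1e-6)

  # against stiff-ODE integration of the cleft balance over one fixed step
  skip_if_not_installed("deSolve")
  ch <- p_def$channels
  for (n_o in c(1, 5, 25)) {
    k_rel <- n_o * ch$g_ryr / ch$v_ds
    j_cal <- 300
    rbss <- 0.5; jsr_um <- 1000
    rhs <- function(t, y, parms)
      list(k_rel * (jsr_um - y) + j_cal - (y - rbss) / ch$tau_ds)
    sol <- deSolve::lsoda(c(ca = rbss), seq(0, 0.01, length.out = 11), rhs,
                          NULL, rtol = 1e-10, atol = 1e-12)
    qss <- cleft_quasi_steady(rbss, 1.0, n_o, j_cal, ch$tau_ds, ch$g_ryr, ch$v_ds)
    expect_lt(abs(sol[11, "ca"] - qss) / qss, 0.01)
  }
})

test_that("dyad update returns zero fluxes at equilibrium and drains the jSR on release", {
  # equilibrium: equal concentrations, channels shut and rates frozen
  pfrozen <- p_def
  pfrozen$channels$ryr$komax <- 0
  dy <- new_dyad_state(pfrozen, ca_jsr = 1.0, ca_ds = 0.1)
  set.seed(3)
  out <- update_dyad(dy, ca_rbss = 0.1, ca_nsr = 1.0, vm = -80, dt = 0.01, pfrozen)
  expect_identical(out$j_ds, 0)
  expect_identical(out$j_jsr, 0)
  expect_identical(out$state$ca_jsr, 1.0)

  # one permanently open RyR: release flux positive, jSR strictly decreasing
  popen <- p_def
  popen$channels$ryr$komax <- 0
  popen$channels$ryr$kclose <- 0
  popen$channels$ryr$kimax <- 0
  dy2 <- new_dyad_state(popen, ca_jsr = 1.0, ca_ds = 0.1)
  dy2$ryr <- setNames(c(99L, 1L, 0L, 0L), caspatial:::ryr_states)
  out2 <- update_dyad(dy2, 0.1, 1.0, -80, 0.01, popen)
  expect_gt(out2$j_rel, 0)
  expect_lt(out2$state$ca_jsr, 1.0)
})

test_that("a closed jSR-cleft-subspace system conserves total calcium", {
  p <- p_def
  p$channels$ryr$komax <- 0; p$channels$ryr$kclose <- 0; p$channels$ryr$kimax <- 0
  ch <- p$channels
  v_rbss <- 0.00314
  dy <- new_dyad_state(p, ca_jsr = 1.0, ca_ds = 4)
  dy$ryr <- setNames(c(99L, 1L, 0L, 0L), caspatial:::ryr_states)
  rbss <- 0.2
  total <- function(dy, rbss) {
    csqn <- ch$csqn_b * dy$ca_jsr / (ch$csqn_k + dy$ca_jsr)
    dy$v_jsr * 1000 * (dy$ca_jsr + csqn) + dy$v_ds * dy$ca_ds + v_rbss * rbss
  }
  set.seed(5)
  for (s in 1:50) {
    t0 <- total(dy, rbss)
    out <- update_dyad(dy, rbss, dy$ca_jsr, -80, 0.01, p)  # ca_nsr==ca_jsr: closed
    rbss <- rbss + 0.01 * out$j_ds * ch$v_ds / v_rbss
    dy <- out$state
    expect_lt(abs(total(dy, rbss) - t0) / t0, 1e-6)
  }
})

test_that("per-dyad RNG streams are reproducible and independent", {
  a <- caspatial:::rng_stream_create(123, 7)
  b <- caspatial:::rng_stream_create(123, 7)
  expect_identical(caspatial:::rng_stream_unif(a, 100),
                   caspatial:::rng_stream_unif(b, 100))
  c2 <- caspatial:::rng_stream_create(123, 8)
  expect_false(identical(caspatial:::rng_stream_unif(a, 100),
                         caspatial:::rng_stream_unif(c2, 100)))

  # binomial draws from a stream match the binomial law
  s <- caspatial:::rng_stream_create(1, 0)
  x <- caspatial:::rng_stream_binom(s, rep(100L, 20000), rep(0.05, 20000))
  expect_lt(abs(mean(x) - 5), 4 * sqrt(100 * 0.05 * 0.95 / 20000))
  expect_true(all(x >= 0 & x <= 100))
})
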