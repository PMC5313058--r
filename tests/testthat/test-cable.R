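test_that("resting state is stationary: no-stimulus run stays put", {
  ch <- small_chain(n_nodes = 7L)
  rs <- resting_state(ch)
  expect_lt(rs$delta, 1e-6)
  expect_gt(rs$V_node_rest, -85)
  expect_lt(rs$V_node_rest, -80)
  cfg <- sim_config(dt = 1e-3, duration = 10, stim_amp = 0)
  sim <- simulate_axon(ch, config = cfg, init = rs)
  drift <- max(abs(sim$Vm[nrow(sim$Vm), ] - sim$Vm[1, ]))
  expect_lt(drift, 0.5)
  # initial dV/dt below 0.1 mV/ms everywhere
  dv0 <- abs(sim$Vm[2, ] - sim$Vm[1, ]) / (sim$t[2] - sim$t[1])
  expect_lt(max(dv0), 0.1)
})

test_that("passive model rests exactly at the leak potential and relaxes with tau = c/g", {
  p <- optic(g_Na = 1e-12, g_Ks = 1e-12, g_Nap = 1e-12)
  ch <- small_chain(p, n_nodes = 5L)
  rs <- resting_state(ch)
  expect_equal(max(abs(rs$V - p$E_Lk)), 0, tolerance = 1e-6)
  expect_equal(max(abs(rs$U)), 0, tolerance = 1e-6)
  # with axial coupling suppressed (enormous axoplasmic resistivity) a
  # perturbed node relaxes exponentially with tau = c_mem/g_L exactly
  p_iso <- optic(g_Na = 1e-12, g_Ks = 1e-12, g_Nap = 1e-12,
                 rho_ax = 1e12, rho_p = 1e12)
  ch_iso <- small_chain(p_iso, n_nodes = 5L)
  rs_iso <- resting_state(ch_iso)
  init <- rs_iso; init$V <- rs_iso$V + 10
  cfg <- sim_config(dt = 2.5e-4, duration = 0.06, stim_amp = 0,
                    record_every = 1L)
  sim <- simulate_axon(ch_iso, config = cfg, init = init)
  j <- which(sim$node_of_rec == 3)
  tau <- 0.9 / 80  # ms, c_ax/g_L_node in matched units
  expected <- p$E_Lk + 10 * exp(-sim$t / tau)
  expect_equal(sim$Vm[, j], expected, tolerance = 0.02)
})

test_that("simulation is bitwise reproducible", {
  ch <- small_chain(n_nodes = 5L)
  cfg <- sim_config(dt = 1e-3, duration = 1)
  s1 <- simulate_axon(ch, config = cfg)
  s2 <- simulate_axon(ch, config = cfg)
  expect_identical(s1$Vm, s2$Vm)
  expect_identical(s1$U, s2$U)
})

test_that("propagation is symmetric under reversal of the stimulated end", {
  ch <- small_chain(n_nodes = 9L)
  init <- resting_state(ch)
  cfg_f <- sim_config(dt = 5e-4, duration = 2.5)
  cfg_b <- sim_config(dt = 5e-4, duration = 2.5, stim_node = 9L)
  sf <- simulate_axon(ch, config = cfg_f, init = init)
  sb <- simulate_axon(ch, config = cfg_b, init = init)
  d_f <- as.numeric(spike_time(sf, 6)) - as.numeric(spike_time(sf, 3))
  d_b <- as.numeric(spike_time(sb, 4)) - as.numeric(spike_time(sb, 7))
  expect_equal(d_f, d_b, tolerance = 1e-8)
})

test_that("conduction delay converges under dt refinement", {
  ch <- small_chain(n_nodes = 9L)
  init <- resting_state(ch)
  delay <- function(dt) {
    cfg <- sim_config(dt = dt, duration = 2.5, record_every = 1L)
    sim <- simulate_axon(ch, config = cfg, init = init)
    as.numeric(spike_time(sim, 7)) - as.numeric(spike_time(sim, 3))
  }
  d1 <- delay(1e-3); d2 <- delay(5e-4); d3 <- delay(2.5e-4)
  # refinement differences shrink and the halved-dt change is < 1%
  expect_lt(abs(d3 - d2), abs(d2 - d1) + 1e-9)
  expect_lt(abs(d2 - d3) / d3, 0.01)
})

test_that("subthreshold stimuli decay without spiking", {
  ch <- small_chain(n_nodes = 7L)
  cfg <- sim_config(dt = 1e-3, duration = 2, stim_amp = 0.005)
  sim <- simulate_axon(ch, config = cfg)
  expect_false(sim$propagated)
  expect_lt(max(sim$Vm[, 5]), -60)
  expect_error(spike_time(sim, 5), "propagation failure")
})

test_that("suprathreshold stimulation yields a ~100 mV propagating spike", {
  ch <- small_chain(n_nodes = 9L)
  sim <- simulate_axon(ch, config = sim_config(dt = 5e-4, duration = 2.5))
  expect_true(sim$propagated)
  amp <- max(sim$Vm[, 7]) - sim$Vm[1, 7]
  expect_gt(amp, 90); expect_lt(amp, 130)
  expect_gt(max(sim$Vm[, 7]), 0)
})

test_that("myelin wrapping speeds conduction and halves myelin capacitance", {
  ch7 <- small_chain(n_nodes = 9L)
  ch14 <- build_axon(optic(), n_nodes = 9L,
                     internodal_compartments = 34L, N_wraps = 14L)
  i <- which(ch7$kind == "internode")[1]
  expect_equal(ch14$c_my[i] / ch7$c_my[i], 0.5, tolerance = 0.15)
  s7 <- small_speed(n_nodes = 9L, last_node = 7L, dt = 5e-4)
  s14 <- as.numeric(axon_speed(optic(), n_nodes = 9L, N_wraps = 14L,
                               first_node = 3L, last_node = 7L,
                               dt = 5e-4))
  expect_gt(s14, s7)
})

test_that("internodal axolemma sees only a small fraction of the spike", {
  ch <- small_chain(n_nodes = 7L)
  mid <- which(ch$kind == "internode")
  mid <- mid[round(length(mid) / 2)]
  cfg <- sim_config(dt = 5e-4, duration = 2.5,
                    record = c(which(ch$node_index == 4), mid))
  sim <- simulate_axon(ch, config = cfg)
  node_amp <- max(sim$Vm[, 1]) - sim$Vm[1, 1]
  inter_amp <- max(sim$Vm[, 2]) - sim$Vm[1, 2]
  # most of the internodal voltage change sits across the myelin
  expect_lt(inter_amp, 0.25 * node_amp)
  peri_amp <- max(sim$U[, 2]) - sim$U[1, 2]
  expect_gt(peri_amp, inter_amp)
})

test_that("the implicit integrator matches an independent stiff ODE solve", {
  skip_if_not_installed("deSolve")
  p <- optic()
  ch <- small_chain(p, n_nodes = 5L)
  a <- ranvier:::chain_arrays(ch)
  n <- nrow(ch)
  kin <- channel_kinetics()
  rs <- resting_state(ch)
  is_node <- a$is_node == 1
  node_rows <- which(is_node)
  gax <- a$g_ax; gp <- a$g_p
  rhs <- function(t, y, parms) {
    V <- y[1:n]; U <- y[(n + 1):(2 * n)]
    G <- matrix(y[(2 * n + 1):(2 * n + 4 * length(node_rows))],
                ncol = 4)
    U[is_node] <- 0
    Vm <- V - U
    Iax <- numeric(n); Ip <- numeric(n)
    dV <- V[-1] - V[-n]; dU <- U[-1] - U[-n]
    Iax[-n] <- Iax[-n] + gax * dV; Iax[-1] <- Iax[-1] - gax * dV
    Ip[-n] <- Ip[-n] + gp * dU; Ip[-1] <- Ip[-1] - gp * dU
    gion <- a$g_L; gE <- a$g_L * p$E_Lk
    gna <- a$g_Na[node_rows] * G[, 1]^3 * G[, 2]
    gnap <- a$g_Nap[node_rows] * G[, 3]^3
    gks <- a$g_Ks[node_rows] * G[, 4]
    gion[node_rows] <- gion[node_rows] + gna + gnap + gks
    gE[node_rows] <- gE[node_rows] + (gna + gnap) * p$E_Na +
      gks * p$E_K
    Iion <- gion * Vm - gE
    stim <- numeric(n)
    if (t > 0 && t <= 0.1) stim[node_rows[1]] <- 1000
    dUdt <- ifelse(is_node, 0,
                   (-a$g_my * U + Ip + Iax + stim) /
                     pmax(a$c_my, 1e-12))
    dVdt <- (-Iion + Iax + stim) / a$c_mem + dUdt
    Vn <- Vm[node_rows]
    dG <- matrix(0, length(node_rows), 4)
    for (gi in 1:4) {
      r <- gate_rates(kin, kin$gates[gi], Vn)
      dG[, gi] <- r$alpha * (1 - G[, gi]) - r$beta * G[, gi]
    }
    list(c(dVdt, dUdt, as.vector(dG)))
  }
  y0 <- c(rs$V, rs$U, as.vector(rs$gates[node_rows, ]))
  out <- deSolve::ode(y0, seq(0, 1.0, by = 0.002), rhs, NULL,
                      method = "lsoda", rtol = 1e-7, atol = 1e-7)
  xt <- function(node) {
    i <- node_rows[node]
    v <- out[, 1 + i] - out[, 1 + n + i]
    k <- which(v[-1] >= -20 & v[-length(v)] < -20)[1]
    out[k, 1] + (-20 - v[k]) / (v[k + 1] - v[k]) * 0.002
  }
  d_oracle <- as.numeric(xt(4) - xt(2))
  sim <- simulate_axon(ch, config = sim_config(dt = 2.5e-4,
                                               duration = 1.0,
                                               record_every = 1L),
                       init = rs)
  d_pkg <- as.numeric(spike_time(sim, 4)) - as.numeric(spike_time(sim, 2))
  expect_equal(d_pkg, d_oracle, tolerance = 0.01)
})

test_that("conduction delay is stable under spatial refinement", {
  delay_at <- function(nc) {
    ch <- build_axon(optic(), n_nodes = 9L,
                     internodal_compartments = nc)
    sim <- simulate_axon(ch, config = sim_config(dt = 5e-4,
                                                 duration = 2.5))
    as.numeric(spike_time(sim, 7)) - as.numeric(spike_time(sim, 3))
  }
  d1 <- delay_at(34L); d2 <- delay_at(66L)
  expect_lt(abs(d2 - d1) / d2, 0.02)
})
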