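test_that("conduction speed is distance over interpolated crossing-time difference", {
  # synthetic traces: node 20 crosses -20 mV at 1.0 ms, node 30
  # exactly 0.5 ms later, centres 1.403 mm apart
  t <- seq(0, 3, by = 0.01)
  ramp <- function(t0) -80 + 120 * pmax(pmin((t - t0) / 0.1, 1), 0)
  sim <- structure(list(
    t = t, Vm = cbind(ramp(0.95), ramp(1.45)),
    node_of_rec = c(20L, 30L),
    node_positions = c(rep(NA, 19), 0, rep(NA, 9), 1403)),
    class = "axon_sim")
  s <- conduction_speed(sim, 20, 30)
  expect_equal(as.numeric(s), 2.806, tolerance = 1e-6)
  expect_equal(attr(s, "delay_ms"), 0.5, tolerance = 1e-9)
})

test_that("channel scaling modes behave as specified", {
  p <- optic()
  # constant number at double the mean length: half the density
  p2 <- scale_nodal_channels(p, 2.04, "constant_number")
  expect_equal(p2$g_Na, 1500)
  expect_equal(p2$g_Ks, 40)
  expect_equal(p2$g_Nap, 2.5)
  expect_equal(p2$g_L_node, 40)
  # identity at the mean length
  p3 <- scale_nodal_channels(p, 1.02, "constant_number")
  expect_equal(p3$g_Na, 3000)
  # constant density never touches densities
  p4 <- scale_nodal_channels(p, 0.33, "constant_density")
  expect_equal(p4$g_Na, 3000)
  expect_equal(p4$L_node, 0.33)
  expect_error(scale_nodal_channels(p, -1), "positive")
})

test_that("propagation delay is length over speed", {
  expect_equal(propagation_delay(0.01, 2.61), 3.83, tolerance = 1e-3)
  expect_equal(propagation_delay(0.01, 2.61 * 0.8),
               propagation_delay(0.01, 2.61) * 1.25, tolerance = 1e-12)
  expect_equal(propagation_delay(0, 3), 0)
  expect_error(propagation_delay(0.01, 0), "speed")
})

test_that("constant-number speed decreases monotonically with node length", {
  sp <- vapply(c(0.6, 1.02, 1.6, 2.2), function(L)
    small_speed(node_lengths = L, mode = "constant_number"), 0)
  expect_true(all(diff(sp) < 0))
})

test_that("constant-density speed has an interior maximum near 1.7 um", {
  lens <- c(0.5, 1.02, 1.7, 2.6, 3.4)
  sp <- vapply(lens, function(L)
    small_speed(node_lengths = L, mode = "constant_density"), 0)
  expect_gt(sp[3], sp[1])   # rises from the shortest nodes
  expect_gt(sp[3], sp[5])   # falls at long nodes
  expect_gt(sp[3], sp[2])   # above the mean-length speed
})

test_that("the two modes coincide at the mean node length", {
  s_cd <- small_speed(node_lengths = 1.02, mode = "constant_density")
  s_cn <- small_speed(node_lengths = 1.02, mode = "constant_number")
  expect_equal(s_cd, s_cn, tolerance = 1e-12)
})

test_that("speed rises then falls with internode length", {
  sp <- vapply(c(12, 40, 81.7, 200, 350), function(L)
    small_speed(cortex(), L_internode = L, dt = 2.5e-4), 0)
  expect_gt(max(sp[2:3]), sp[1])   # rises from short internodes
  expect_gt(max(sp[2:3]), sp[4])   # falls at long internodes
  expect_gt(sp[4], sp[5])
})

test_that("speed is invariant to the stimulus amplitude far from the electrode", {
  s1 <- small_speed(stim_amp = 1)
  s2 <- small_speed(stim_amp = 2.5)
  expect_equal(s1, s2, tolerance = 5e-3)
})

test_that("sweep results carry percent changes anchored at the baseline", {
  sw <- sweep_node_length(optic(), c(0.7, 1.02), "constant_number",
                          n_nodes = 11L, first_node = 3L,
                          last_node = 8L, dt = 1e-3)
  expect_s3_class(sw, "node_sweep")
  expect_equal(sw$pct_change[sw$value == 1.02], 0, tolerance = 1e-9)
  expect_gt(sw$pct_change[1], 0)  # shorter node faster in this mode
  sp <- sweep_spread(sw)
  expect_gt(sp$max_vs_min_pct, 0)
})

test_that("alternating node lengths cancel under constant number but cost speed under constant density", {
  cn <- alternating_node_axon(optic(), mean_length = 1.02,
                              delta = 0.25, mode = "constant_number",
                              n_nodes = 11L, first_node = 3L,
                              last_node = 8L, dt = 1e-3)
  expect_lt(abs(cn$pct_change), 0.5)
  cd <- alternating_node_axon(optic(), mean_length = 1.02,
                              delta = 0.25, mode = "constant_density",
                              n_nodes = 11L, first_node = 3L,
                              last_node = 8L, dt = 1e-3)
  expect_lt(cd$pct_change, 0)
  expect_gt(cd$pct_change, -2)
  # zero alternation reproduces the uniform axon exactly
  z <- alternating_node_axon(optic(), mean_length = 1.02, delta = 0,
                             n_nodes = 11L, first_node = 3L,
                             last_node = 8L, dt = 1e-3)
  expect_equal(z$speed, z$uniform, tolerance = 1e-12)
})

test_that("speed-matched equivalents solve the node-length knob", {
  # a 0% target returns the baseline on all knobs without simulating
  eq0 <- speed_matched_equivalents(optic(), 0, n_nodes = 11L,
                                   first_node = 3L, last_node = 8L,
                                   dt = 1e-3)
  expect_equal(eq0$node_length_um, 1.02)
  expect_equal(eq0$density_change_pct, 0)
  # a modest slow-down is reachable by shortening the node
  eq <- speed_matched_equivalents(optic(), -5, knobs = "node_length",
                                  tol_pp = 0.3, n_nodes = 11L,
                                  first_node = 3L, last_node = 8L,
                                  dt = 1e-3)
  expect_lt(eq$node_length_um, 1.02)
  s <- small_speed(node_lengths = eq$node_length_um)
  expect_equal(100 * (s / eq$baseline_speed - 1), -5, tolerance = 0.1)
})

test_that("threshold bisection brackets a propagating amplitude", {
  thr <- threshold_amplitude(optic(), n_nodes = 9L, dt = 2e-3)
  expect_gt(thr, 0.01)
  expect_lt(thr, 1)  # the default 1 nA stimulus is suprathreshold
})

test_that("wrap sweeps anchor at zero and slow with demyelination", {
  sw <- sweep_wraps(optic(), c(0L, -1L), n_nodes = 11L,
                    first_node = 3L, last_node = 8L, dt = 1e-3)
  expect_equal(sw$pct_change[sw$value == 7], 0, tolerance = 1e-12)
  expect_lt(sw$pct_change[sw$value == 6], 0)
  expect_error(sweep_wraps(optic(), -7L), ">= 1")
})
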