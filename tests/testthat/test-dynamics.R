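# closed-form oracles for the neuron and synapse update operators

test_that("resting neuron with zero current is a fixed point", {
  p <- lif_params()
  st <- list(V = p$V0, ref = 0)
  out <- lif_step(st, p, I = 0, dt = 1e-4)
  expect_equal(out$state$V, p$V0)
  expect_false(out$spiked)
})

test_that("subthreshold constant current converges to V0 + R I", {
  p <- lif_params()
  I <- 0.5 * (p$Vth - p$V0) / p$R   # half rheobase
  st <- list(V = p$V0, ref = 0)
  for (i in 1:5000) {
    out <- lif_step(st, p, I, dt = 1e-4)
    expect_false(out$spiked)
    st <- out$state
  }
  expect_equal(st$V, p$V0 + p$R * I, tolerance = 1e-6)
})

test_that("suprathreshold firing matches the closed-form LIF period", {
  p <- lif_params(t_ref = 2e-3)
  I <- 2.5 * (p$Vth - p$V0) / p$R
  T_oracle <- lif_isi(p, I)
  dt <- 1e-4
  st <- list(V = p$V0, ref = 0)
  spikes <- c()
  for (m in 1:40000) {
    out <- lif_step(st, p, I, dt)
    if (out$spiked) spikes <- c(spikes, m * dt)
    st <- out$state
  }
  isi <- diff(spikes)
  expect_gt(length(isi), 5)
  expect_true(all(abs(isi - T_oracle) <= 2 * dt))
  expect_true(all(isi >= p$t_ref))
})

test_that("non-finite current is rejected", {
  p <- lif_params()
  expect_error(lif_step(list(V = p$V0, ref = 0), p, NaN, 1e-4), "non-finite")
})

test_that("alpha synapse reproduces its closed-form impulse response", {
  for (pars in list(alpha_synapse_params(1e-9, a_r = 5000, a_d = 200),
                    alpha_synapse_params(1e-9, a_r = 300, a_d = 300))) {
    dt <- 1e-5
    st <- c(0, 0)
    out <- alpha_synapse_step(st, pars, n_spikes = 1, dt = dt)
    st <- out$state
    ts <- dt
    for (m in 2:2000) {
      out <- alpha_synapse_step(st, pars, 0, dt)
      st <- out$state
      ts <- c(ts, m * dt)
    }
    # integrator state after the spike follows s(t) exactly
    s_exact <- alpha_impulse_response(pars, ts[length(ts)])
    expect_equal(st[1], s_exact, tolerance = 1e-6)
  }
})

test_that("alpha synapse with no input stays at rest and peaks where predicted", {
  pars <- alpha_synapse_params(1e-9, 5000, 200)
  out <- alpha_synapse_step(c(0, 0), pars, 0, 1e-4)
  expect_equal(out$state, c(0, 0))
  pk <- alpha_impulse_peak(5000, 200)
  t_grid <- seq(1e-5, 5 * pk$t_peak, by = 1e-6)
  resp <- alpha_impulse_response(pars, t_grid)
  expect_equal(t_grid[which.max(resp)], pk$t_peak, tolerance = 1e-3)
  expect_equal(max(resp), pk$s_peak, tolerance = 1e-4)
})

test_that("repeated-root alpha impulse matches a^2 t exp(-a t)", {
  pars <- alpha_synapse_params(1, a_r = 400, a_d = 400)
  t <- c(1e-3, 2.5e-3, 1 / 400)
  expect_equal(alpha_impulse_response(pars, t), 400^2 * t * exp(-400 * t))
  pk <- alpha_impulse_peak(400, 400)
  expect_equal(pk$t_peak, 1 / 400)
  expect_equal(pk$s_peak, 400 / exp(1))
})

test_that("exponential synapse decays exactly and sums deltas", {
  p <- exp_synapse_params(1e-9, tau = 10e-3)
  # decay from s = 1 over one time constant
  s <- 1
  n_sub <- 200
  for (i in 1:n_sub) s <- exp_synapse_step(s, p, 0, p$tau / n_sub)$s
  expect_equal(s, exp(-1), tolerance = 1e-12)
  # two simultaneous spikes from rest
  expect_equal(exp_synapse_step(0, p, 2, 1e-4)$s, 2)
})

test_that("NMDA magnesium block matches the printed voltage dependence", {
  p <- nmda_synapse_params(2e-9, tau = 0.1, alpha = 0.5, mg = 1)
  # no magnesium: pure gating
  p0 <- nmda_synapse_params(2e-9, tau = 0.1, alpha = 0.5, mg = 0)
  out <- nmda_synapse_step(0.5, p0, 0, V_post = -60e-3, dt = 1e-4)
  expect_equal(out$g, p0$g_bar * out$s)
  # V = 0, mg = 1: block factor 1 / (1 + 1/3.56)
  expect_equal(nmda_block(0, 1), 1 / (1 + 1 / 3.56))
  expect_equal(nmda_block(0, 1), 0.7807, tolerance = 1e-4)
  # saturation: many rapid spikes drive s -> 1 without exceeding it
  s <- 0
  for (i in 1:200) s <- nmda_synapse_step(s, p, 5, -60e-3, 1e-5)$s
  expect_lte(s, 1)
  expect_gt(s, 0.99)
})

test_that("per-spike NMDA increment integrates the saturating impulse exactly", {
  p <- nmda_synapse_params(1e-9, alpha = 2)
  out <- nmda_synapse_step(0, p, 1, -70e-3, 1e-9)
  # ds/dt = alpha (1 - s) delta(t) integrates to 1 - exp(-alpha)
  expect_equal(out$s, 1 - exp(-2), tolerance = 1e-6)
})

test_that("synaptic coupling current follows the stated conventions", {
  expect_equal(synaptic_current(0, -60e-3, 0, "conductance"), 0)
  expect_equal(synaptic_current(2e-9, -10e-3, -10e-3, "conductance"), 0)
  expect_equal(synaptic_current(2, NA, NA, "current", sign = "inh"), -2)
  expect_equal(synaptic_current(2, NA, NA, "current", sign = "exc"), 2)
  g <- 1e-9
  expect_equal(synaptic_current(g, -70e-3, 0, "conductance"), g * 70e-3)
})

# ---- engine-level oracles --------------------------------------------------

test_that("engine reproduces the closed-form LIF period under injected current", {
  circ <- single_neuron_circuit(lif_params(t_ref = 2e-3))
  p <- lif_params(t_ref = 2e-3)
  I <- 2.5 * (p$Vth - p$V0) / p$R
  dt <- 1e-4
  drive <- const_current_drive("n0", I, duration = 2, dt = dt)
  rec <- simulate(circ, drive, engine_config(dt = dt))
  isi <- diff(rec$times[["n0"]])
  expect_gt(length(isi), 10)
  expect_true(all(abs(isi - lif_isi(p, I)) <= 2 * dt))
})

test_that("simulation is bit-identical under a repeated seed and config", {
  toy <- make_toy_ring(4, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  dt <- 1e-3
  ids <- toy$circuit$neurons$id[toy$circuit$neurons$cell_class == "EB-LAL-PB"]
  drive <- cxsim:::new_input_drive(
    "poisson", dt, ids, matrix(80, 500, length(ids)),
    cxsim:::input_syn_table(default_config("B"), "input->EB-LAL-PB",
                            length(ids)))
  r1 <- simulate(toy$circuit, drive, engine_config(dt = dt), seed = 7)
  r2 <- simulate(toy$circuit, drive, engine_config(dt = dt), seed = 7)
  expect_identical(r1$times, r2$times)
  r3 <- simulate(toy$circuit, drive, engine_config(dt = dt), seed = 8)
  expect_false(identical(r1$times, r3$times))
})

test_that("no interspike interval violates the refractory period", {
  toy <- make_toy_ring(4, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  dt <- 1e-4
  ids <- toy$circuit$neurons$id[toy$circuit$neurons$cell_class == "EB-LAL-PB"]
  drive <- const_current_drive(ids, 1.2e-9, duration = 1, dt = dt)
  rec <- simulate(toy$circuit, drive, engine_config(dt = dt))
  t_ref <- toy$circuit$neurons$t_ref[1]
  for (id in rec$ids) {
    if (length(rec$times[[id]]) > 1) {
      expect_true(all(diff(rec$times[[id]]) >= t_ref))
    }
  }
})

test_that("all-silenced circuits emit no spikes", {
  toy <- make_toy_ring(4, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  circ <- silence(toy$circuit, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  drive <- const_current_drive(circ$neurons$id, 1e-9, 0.5, 1e-4)
  rec <- simulate(circ, drive, engine_config(dt = 1e-4))
  expect_equal(sum(vapply(rec$times, length, integer(1))), 0L)
})

test_that("silencing a neuron equals removing it, for all other spike trains", {
  toy <- make_toy_ring(4, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  dt <- 1e-4
  eb <- toy$circuit$neurons$id[toy$circuit$neurons$cell_class == "EB-LAL-PB"]
  drive <- const_current_drive(eb, 0.9e-9, duration = 1, dt = dt)
  victim <- toy$circuit$neurons$id[toy$circuit$neurons$cell_class == "PB-EB-LAL"][1]
  sil <- silence(toy$circuit, victim)
  rem <- toy$circuit
  rem$neurons <- rem$neurons[rem$neurons$id != victim, ]
  rem$synapses <- rem$synapses[rem$synapses$pre != victim &
                               rem$synapses$post != victim, ]
  r_sil <- simulate(sil, drive, engine_config(dt = dt))
  r_rem <- simulate(rem, drive, engine_config(dt = dt))
  for (id in rem$neurons$id) {
    expect_identical(r_sil$times[[id]], r_rem$times[[id]])
  }
})

test_that("engine matches the dense reference integrator on a toy ring", {
  fx <- equivalence_fixture()
  rec_fast <- simulate(fx$circuit, fx$drive,
                       engine_config(dt = fx$dt,
                                     record = "spikes+voltages"))
  rec_ref <- simulate_reference(
    fx$circuit, fx$drive,
    list(dt = fx$dt, dt_ref = fx$dt / 100, duration = fx$duration,
         delay_steps = 1L, coupling = "conductance"),
    record_v = TRUE)
  n_fast <- sum(vapply(rec_fast$times, length, integer(1)))
  expect_gt(n_fast, 3)
  for (id in fx$circuit$neurons$id) {
    expect_trains_close(rec_fast$times[[id]], rec_ref$times[[id]],
                        tol = 2 * fx$dt)
  }
  # subthreshold neurons: dense voltage agreement (synapse + coupling path)
  quiet <- fx$circuit$neurons$id[
    vapply(rec_fast$times, length, integer(1))[fx$circuit$neurons$id] == 0]
  expect_gt(length(quiet), 0)
  Vf <- attr(rec_fast, "V"); Vr <- attr(rec_ref, "V")
  expect_lt(max(abs(Vf[, quiet] - Vr[, quiet])), 1.5e-3)
})

test_that("halving dt changes each spike interval by at most dt", {
  circ <- single_neuron_circuit(lif_params(t_ref = 2e-3))
  p <- lif_params(t_ref = 2e-3)
  I <- 3 * (p$Vth - p$V0) / p$R
  t1 <- simulate(circ, const_current_drive("n0", I, 1, 1e-4),
                 engine_config(dt = 1e-4))$times[["n0"]]
  t2 <- simulate(circ, const_current_drive("n0", I, 1, 5e-5),
                 engine_config(dt = 5e-5))$times[["n0"]]
  expect_lte(abs(t1[1] - t2[1]), 1e-4 + 1e-12)
  n <- min(length(t1), length(t2))
  expect_true(all(abs(diff(t1[1:n]) - diff(t2[1:n])) <= 1e-4 + 1e-12))
})
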