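# shared fixtures: miniature circuits and drives, built in code

toy_core <- function(n_wedges = 4L) {
  make_toy_ring(n_wedges, classes = c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
}

# constant-current drive injecting `I` amps into the given neurons
const_current_drive <- function(ids, I, duration, dt) {
  n_steps <- round(duration / dt)
  vals <- matrix(I, n_steps, length(ids))
  cxsim:::new_input_drive("current", dt, ids, vals)
}

# a single-neuron "circuit" for LIF oracle tests
single_neuron_circuit <- function(p = lif_params()) {
  topo <- make_topology(2L, 2L)
  neurons <- data.frame(
    id = "n0", cell_class = "EB-LAL-PB", subtype = NA_character_,
    dend_region = "EB", wedge = 0L, glom = NA_character_,
    rf_center = NA_real_, axon_region = "PB+LAL", enabled = TRUE,
    C = p$C, R = p$R, V0 = p$V0, Vth = p$Vth, Vr = p$Vr, t_ref = p$t_ref,
    stringsAsFactors = FALSE)
  cxsim:::new_circuit(topo, neurons, cxsim:::empty_synapse_table(),
                      "custom", NULL)
}

# Spike-train agreement up to the engine's per-step quantization: equal
# counts, first spike within `tol`, and every interspike interval within
# `tol` (absolute times drift by ~dt/2 per interval in any fixed-step
# engine, so intervals, not absolute times, carry the per-spike error).
expect_trains_close <- function(a, b, tol) {
  expect_equal(length(a), length(b))
  if (length(a) >= 1) expect_lte(abs(a[1] - b[1]), tol)
  if (length(a) >= 2) expect_lte(max(abs(diff(a) - diff(b))), tol)
}

# equivalence fixture: toy ring at 1/10 coupling (second layer subthreshold,
# so the comparison is conditioned: no chaotic recruitment)
equivalence_fixture <- function(dt = 1e-4, duration = 0.1) {
  toy <- make_toy_ring(4, c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO"))
  circ <- toy$circuit
  circ$synapses$g_bar <- circ$synapses$g_bar * 0.1
  eb <- circ$neurons$id[circ$neurons$cell_class == "EB-LAL-PB"]
  drive <- const_current_drive(eb[c(1, 3)], 0.85e-9, duration, dt)
  list(circuit = circ, drive = drive, dt = dt, duration = duration)
}
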