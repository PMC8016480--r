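#' Leaky integrate-and-fire neuron parameters
#'
#' Point-neuron membrane parameters, SI units. Between spikes the membrane
#' obeys `C dV/dt = -(V - V0)/R + I`; on reaching `Vth` the neuron spikes,
#' `V` is reset to `Vr`, and inputs are ignored for `t_ref` seconds (the
#' voltage is clamped at `Vr` during refractoriness).
#'
#' @param C Membrane capacitance (F).
#' @param R Membrane resistance (Ohm).
#' @param V0 Resting potential (V).
#' @param Vth Spike threshold (V); must exceed `Vr`.
#' @param Vr Reset potential (V).
#' @param t_ref Absolute refractory period (s), `>= 0`.
#' @return A `lif_params` list.
#' @export
lif_params <- function(C = 0.35e-9, R = 2e-2 / 0.35e-9, V0 = -70e-3, Vth = -50e-3,
                       Vr = -70e-3, t_ref = 0) {
  stopifnot(C > 0, R > 0, Vth > Vr, t_ref >= 0)
  structure(list(C = C, R = R, V0 = V0, Vth = Vth, Vr = Vr, t_ref = t_ref),
            class = "lif_params")
}

#' Alpha-synapse parameters
#'
#' Second-order linear conductance model. The state pair `(s, h)` follows
#' `ds/dt = h`, `dh/dt = -(a_r + a_d) h - a_r a_d s`, with every presynaptic
#' spike adding `a_r * a_d` to `h`; the conductance is `g = g_bar * s`.
#'
#' @param g_bar Conductance scaling factor (S); `>= 0`.
#' @param a_r Rise rate (1/s).
#' @param a_d Decay rate (1/s).
#' @export
alpha_synapse_params <- function(g_bar, a_r = 5000, a_d = 200) {
  stopifnot(g_bar >= 0, a_r > 0, a_d > 0)
  list(kind = "alpha", g_bar = g_bar, a_r = a_r, a_d = a_d)
}

#' Exponential (AMPA / GABA-A) synapse parameters
#'
#' First-order receptor model `ds/dt = -s/tau + sum_k delta(t - t_k)`,
#' conductance `g = g_bar * s`.
#'
#' @param g_bar Maximum conductance per unit state (S).
#' @param tau Decay time constant (s).
#' @export
exp_synapse_params <- function(g_bar, tau = 5e-3) {
  stopifnot(g_bar >= 0, tau > 0)
  list(kind = "exp", g_bar = g_bar, tau = tau)
}

#' NMDA synapse parameters
#'
#' Saturating receptor model `ds/dt = -s/tau + alpha (1 - s) sum_k delta(t-t_k)`
#' with the voltage-dependent magnesium block
#' `g = g_bar * s / (1 + mg * exp(-0.062 * V_mV) / 3.56)`, where `V_mV` is the
#' postsynaptic membrane voltage in millivolts. The constants 0.062 (per mV)
#' and 3.56 (mM) are fixed properties of the block and are not parameters.
#'
#' @param g_bar Maximum conductance (S), attained as `s -> 1` at full relief
#'   of the block.
#' @param tau Decay time constant (s).
#' @param alpha Saturation rate (dimensionless impulse exponent per spike).
#' @param mg Extracellular Mg2+ concentration (mM).
#' @export
nmda_synapse_params <- function(g_bar, tau = 100e-3, alpha = 0.63, mg = 1.0) {
  stopifnot(g_bar >= 0, tau > 0, alpha > 0, mg >= 0)
  list(kind = "nmda", g_bar = g_bar, tau = tau, alpha = alpha, mg = mg)
}

# Fixed NMDA Mg-block constants (per mV; mM). Immutable by contract.
NMDA_BLOCK_BETA <- 0.062
NMDA_BLOCK_GAMMA <- 3.56

#' Peak of the alpha-synapse single-spike state response
#'
#' For a single spike arriving at rest, `s(t)` peaks at
#' `t* = log(a_d/a_r) / (a_d - a_r)` with the closed-form value returned here;
#' the repeated-root limit `a_r = a_d = a` gives `s_peak = a / e`.
#'
#' @param a_r,a_d Rise and decay rates (1/s).
#' @return List with `t_peak` (s) and `s_peak` (state units).
#' @export
alpha_impulse_peak <- function(a_r, a_d) {
  if (isTRUE(all.equal(a_r, a_d))) {
    list(t_peak = 1 / a_r, s_peak = a_r / exp(1))
  } else {
    t_star <- log(a_d / a_r) / (a_d - a_r)
    s_star <- (a_r * a_d / (a_d - a_r)) *
      (exp(-a_r * t_star) - exp(-a_d * t_star))
    list(t_peak = t_star, s_peak = s_star)
  }
}

#' Solve alpha-synapse parameters for a target time-to-peak and peak
#'
#' Finds `(a_r, a_d, g_bar)` such that the single-spike conductance response
#' peaks at `t_peak` seconds with value `g_peak` siemens. The problem is
#' underdetermined by one degree of freedom; the rise/decay rate ratio
#' `ratio = a_r / a_d` (sharpness of the rise) is held fixed and `a_d` is
#' found by bisection on the time-to-peak.
#'
#' @param t_peak Target time-to-peak (s).
#' @param g_peak Target peak conductance (S).
#' @param ratio Fixed ratio `a_r / a_d` (> 0, != 1 handled too).
#' @return An [alpha_synapse_params()] list.
#' @export
alpha_params_for_peak <- function(t_peak, g_peak, ratio = 25) {
  stopifnot(t_peak > 0, g_peak >= 0, ratio > 0)
  tp_of <- function(a_d) alpha_impulse_peak(ratio * a_d, a_d)$t_peak
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (tp_of(mid) > t_peak) lo <- mid else hi <- mid
  }
  a_d <- sqrt(lo * hi); a_r <- ratio * a_d
  s_peak <- alpha_impulse_peak(a_r, a_d)$s_peak
  alpha_synapse_params(g_bar = g_peak / s_peak, a_r = a_r, a_d = a_d)
}

#' Single-spike peak of a synapse state response
#'
#' Used to convert interpretable per-spike peak conductances in configs into
#' the `g_bar` scaling of each kinetic scheme. For `exp` the peak state is 1;
#' for `nmda` the configured weight is taken as the saturation maximum
#' (state 1), so the factor is also 1.
#' @keywords internal
#' @noRd
synapse_unit_peak <- function(kind, params) {
  switch(kind,
         alpha = alpha_impulse_peak(params$a_r, params$a_d)$s_peak,
         exp = 1,
         nmda = 1,
         stop("unknown synapse kind: ", kind))
}
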