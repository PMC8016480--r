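#' Single-step leaky integrate-and-fire update
#'
#' Advances the membrane state by the exact exponential solution of
#' `C dV/dt = -(V - V0)/R + I` over `dt` with the current held constant:
#' `V(t+dt) = V0 + R I + (V - V0 - R I) exp(-dt / (R C))`. On crossing the
#' threshold the spike flag is set, `V` is reset to `Vr` and the refractory
#' clock is loaded with `t_ref`; while refractory the voltage is clamped at
#' `Vr` and inputs are ignored.
#'
#' @param state List with `V` (volts) and `ref` (remaining refractory time,
#'   s).
#' @param p A [lif_params()] object.
#' @param I Input current (A), held constant over the step.
#' @param dt Step size (s).
#' @return List with updated `state` and logical `spiked`.
#' @export
lif_step <- function(state, p, I, dt) {
  stopifnot(dt > 0)
  if (!is.finite(I)) stop("non-finite input current")
  if (state$ref > 1e-12) {
    return(list(state = list(V = p$Vr, ref = state$ref - dt),
                spiked = FALSE))
  }
  Vinf <- p$V0 + p$R * I
  V <- Vinf + (state$V - Vinf) * exp(-dt / (p$R * p$C))
  if (V >= p$Vth) {
    list(state = list(V = p$Vr, ref = p$t_ref), spiked = TRUE)
  } else {
    list(state = list(V = V, ref = 0), spiked = FALSE)
  }
}

#' Closed-form interspike interval of a LIF neuron under constant current
#'
#' For `R I > Vth - V0` the neuron fires periodically with period
#' `t_ref + R C log((R I - (Vr - V0)) / (R I - (Vth - V0)))`.
#'
#' @param p A [lif_params()] object.
#' @param I Constant current (A).
#' @return Period in seconds (`Inf` below rheobase).
#' @export
lif_isi <- function(p, I) {
  drive <- p$R * I
  if (drive <= p$Vth - p$V0) return(Inf)
  p$t_ref + p$R * p$C * log((drive - (p$Vr - p$V0)) / (drive - (p$Vth - p$V0)))
}

#' Single-step alpha-synapse update
#'
#' Each incoming spike increments `h` by `a_r * a_d`; the linear system
#' `ds/dt = h`, `dh/dt = -(a_r + a_d) h - a_r a_d s` is then advanced by its
#' exact matrix-exponential update over `dt`.
#'
#' @param state Numeric `c(s, h)`.
#' @param p An [alpha_synapse_params()] object.
#' @param n_spikes Number of presynaptic spikes arriving this step.
#' @param dt Step size (s).
#' @return List with `state = c(s, h)` and conductance `g = g_bar * s`
#'   (evaluated after the update).
#' @export
alpha_synapse_step <- function(state, p, n_spikes, dt) {
  s <- state[1]; h <- state[2] + n_spikes * p$a_r * p$a_d
  if (isTRUE(all.equal(p$a_r, p$a_d))) {
    a <- p$a_r
    E <- exp(-a * dt)
    s1 <- (s + (h + a * s) * dt) * E
    h1 <- (h - a * (h + a * s) * dt) * E
  } else {
    E1 <- exp(-p$a_r * dt); E2 <- exp(-p$a_d * dt)
    den <- p$a_d - p$a_r
    s1 <- ((p$a_d * E1 - p$a_r * E2) * s + (E1 - E2) * h) / den
    h1 <- (p$a_r * p$a_d * (E2 - E1) * s + (p$a_d * E2 - p$a_r * E1) * h) / den
  }
  list(state = c(s1, h1), g = p$g_bar * s1)
}

#' Closed-form alpha-synapse impulse response
#'
#' State response `s(t)` to a single spike at `t = 0` from rest:
#' `s(t) = a_r a_d / (a_d - a_r) (exp(-a_r t) - exp(-a_d t))`, with the
#' repeated-root limit `a^2 t exp(-a t)`.
#'
#' @param p An [alpha_synapse_params()] object.
#' @param t Times (s), vectorized.
#' @export
alpha_impulse_response <- function(p, t) {
  if (isTRUE(all.equal(p$a_r, p$a_d))) {
    p$a_r^2 * t * exp(-p$a_r * t)
  } else {
    (p$a_r * p$a_d / (p$a_d - p$a_r)) * (exp(-p$a_r * t) - exp(-p$a_d * t))
  }
}

#' Single-step exponential (AMPA/GABA-A) synapse update
#'
#' `s := s exp(-dt / tau) + n_spikes`; exact for
#' `ds/dt = -s/tau + sum_k delta(t - t_k)` with the spikes arriving at the
#' end of the step.
#'
#' @param s State value (>= 0).
#' @param p An [exp_synapse_params()] object.
#' @param n_spikes Number of presynaptic spikes arriving this step.
#' @param dt Step size (s).
#' @return List with `s` and `g = g_bar * s`.
#' @export
exp_synapse_step <- function(s, p, n_spikes, dt) {
  s1 <- s * exp(-dt / p$tau) + n_spikes
  list(s = s1, g = p$g_bar * s1)
}

#' Single-step NMDA synapse update
#'
#' Per spike the saturating update `s := s + (1 - exp(-alpha)) (1 - s)` is
#' applied (the exact integral of `ds/dt = alpha (1 - s) delta(t)` across the
#' impulse), then the state decays by `exp(-dt / tau)`. The conductance
#' carries the voltage-dependent magnesium block evaluated at the
#' postsynaptic voltage: `g = g_bar s / (1 + mg exp(-0.062 V_mV) / 3.56)`.
#'
#' @param s State value in `[0, 1]`.
#' @param p An [nmda_synapse_params()] object.
#' @param n_spikes Number of presynaptic spikes arriving this step.
#' @param V_post Postsynaptic membrane voltage (V).
#' @param dt Step size (s).
#' @return List with `s` and `g`.
#' @export
nmda_synapse_step <- function(s, p, n_spikes, V_post, dt) {
  if (s < -1e-9 || s > 1 + 1e-9) {
    stop("NMDA saturation contract broken: s = ", s)
  }
  if (n_spikes > 0) {
    s <- 1 - (1 - s) * exp(-p$alpha)^n_spikes
  }
  s1 <- s * exp(-dt / p$tau)
  list(s = s1, g = p$g_bar * s1 * nmda_block(V_post, p$mg))
}

#' Magnesium-block factor of the NMDA conductance
#'
#' `1 / (1 + mg * exp(-0.062 * V_mV) / 3.56)` with the membrane voltage in
#' millivolts.
#'
#' @param V_post Postsynaptic voltage (V).
#' @param mg Extracellular Mg2+ concentration (mM).
#' @export
nmda_block <- function(V_post, mg) {
  1 / (1 + mg * exp(-NMDA_BLOCK_BETA * V_post * 1e3) / NMDA_BLOCK_GAMMA)
}

#' Synaptic coupling current
#'
#' Conductance mode: `I = g (reversal - V_post)` (driving-force coupling);
#' current mode: `I = +g` for excitatory, `-g` for inhibitory synapses.
#'
#' @param g Conductance (S).
#' @param V_post Postsynaptic voltage (V).
#' @param reversal Reversal potential (V), conductance mode.
#' @param mode `"conductance"` or `"current"`.
#' @param sign `"exc"` or `"inh"`, current mode.
#' @export
synaptic_current <- function(g, V_post, reversal,
                             mode = c("conductance", "current"),
                             sign = "exc") {
  mode <- match.arg(mode)
  if (mode == "conductance") g * (reversal - V_post)
  else if (sign == "exc") g else -g
}

# ---- pure-R brute-force reference integrator -------------------------------

#' Dense forward-Euler reference integrator
#'
#' An independent, deliberately naive network integrator used as the oracle
#' for engine-equivalence tests: first-order forward Euler on every state
#' variable at a fine step `dt_ref` (typically 1/100 of the engine step),
#' with the same event semantics as the engine (one-engine-step synaptic
#' delay, per-step input spikes, refractory clamping). Not exported for
#' production use; scales only to toy circuits.
#'
#' @param model A `cx_circuit`.
#' @param drive A `cx_input_drive` (its `dt` defines the engine step whose
#'   event grid is respected), or `NULL`.
#' @param cfg Engine configuration: `dt` (engine step, s), `dt_ref` (fine
#'   step, s), `delay_steps` (engine steps), `coupling`, `duration`.
#' @param input_spikes Optional precomputed input spike record (as produced
#'   by [sample_poisson()]); required when `drive` is in rate mode.
#' @param record_v If `TRUE`, attach the voltage traces sampled at engine
#'   step boundaries as attribute `"V"` (matrix steps x neurons).
#' @return A `cx_spike_record`.
#' @export
simulate_reference <- function(model, drive, cfg, input_spikes = NULL,
                               record_v = FALSE) {
  dt <- cfg$dt
  dt_ref <- if (!is.null(cfg$dt_ref)) cfg$dt_ref else dt / 100
  sub <- round(dt / dt_ref)
  stopifnot(abs(sub * dt_ref - dt) < 1e-12)
  n_steps <- round(cfg$duration / dt)
  delay <- if (!is.null(cfg$delay_steps)) cfg$delay_steps else 1L
  coupling <- if (!is.null(cfg$coupling)) cfg$coupling else "conductance"

  n <- model$neurons
  syn <- model$synapses
  nn <- nrow(n); ns <- nrow(syn)
  pre_i <- match(syn$pre, n$id); post_i <- match(syn$post, n$id)

  V <- n$V0; ref <- rep(0, nn)
  s_state <- rep(0, ns); h_state <- rep(0, ns)

  # input bookkeeping
  ext_steps <- vector("list", nn)  # engine-step indices of input spikes
  drv_idx <- integer(); I_ext_mat <- NULL
  in_syn <- NULL
  if (!is.null(drive)) {
    if (drive$mode == "current") {
      drv_idx <- match(drive$ids, n$id)
      I_ext_mat <- drive$values
    } else {
      stopifnot(!is.null(input_spikes))
      in_syn <- drive$syn
      in_target <- match(drive$ids, n$id)
      in_s <- rep(0, length(drive$ids)); in_h <- rep(0, length(drive$ids))
      for (k in seq_along(drive$ids)) {
        ext_steps[[k]] <- input_spikes$steps[[k]]
      }
    }
  }

  spikes <- vector("list", nn)
  Vrec <- if (record_v) matrix(NA_real_, n_steps, nn) else NULL
  # spikes deposited per engine step, delivered `delay` engine steps later
  pending <- vector("list", n_steps + delay + 1L)

  for (m in seq_len(n_steps)) {
    # spikes entering synapses this engine step
    arriving <- integer()
    if (m > delay && !is.null(pending[[m - delay]])) {
      arriving <- pending[[m - delay]]
    }
    n_spk_syn <- rep(0, ns)
    if (length(arriving) > 0L) {
      for (a in arriving) {
        idx <- which(pre_i == a)
        n_spk_syn[idx] <- n_spk_syn[idx] + 1L
      }
    }
    # impulses applied at the start of the engine step
    if (ns > 0L) {
      imp <- n_spk_syn > 0
      if (any(imp)) {
        al <- imp & syn$kind == "alpha"
        h_state[al] <- h_state[al] +
          n_spk_syn[al] * syn$a_r[al] * syn$a_d[al]
        ex <- imp & syn$kind == "exp"
        s_state[ex] <- s_state[ex] + n_spk_syn[ex]
        nm <- imp & syn$kind == "nmda"
        s_state[nm] <- 1 - (1 - s_state[nm]) *
          exp(-syn$alpha[nm])^n_spk_syn[nm]
      }
    }
    # external spike impulses onto input synapses
    if (!is.null(in_syn)) {
      for (k in seq_along(ext_steps)) {
        cnt <- sum(ext_steps[[k]] == m)
        if (cnt > 0L) {
          if (in_syn$kind[k] == "alpha") {
            in_h[k] <- in_h[k] + cnt * in_syn$a_r[k] * in_syn$a_d[k]
          } else if (in_syn$kind[k] == "exp") {
            in_s[k] <- in_s[k] + cnt
          } else {
            in_s[k] <- 1 - (1 - in_s[k]) * exp(-in_syn$alpha[k])^cnt
          }
        }
      }
    }
    spiked_engine_step <- integer()
    for (q in seq_len(sub)) {
      # currents from synapse states at the current fine step
      I <- rep(0, nn)
      if (ns > 0L) {
        g <- syn$g_bar * s_state
        nm <- syn$kind == "nmda"
        if (any(nm)) {
          g[nm] <- g[nm] * nmda_block(V[post_i[nm]], syn$mg[nm])
        }
        pre_ok <- n$enabled[pre_i]
        g[!pre_ok] <- 0
        if (coupling == "conductance") {
          Ij <- g * (syn$reversal - V[post_i])
        } else {
          Ij <- ifelse(syn$sign == "exc", g, -g)
        }
        for (j in seq_len(ns)) I[post_i[j]] <- I[post_i[j]] + Ij[j]
      }
      if (!is.null(in_syn)) {
        gin <- in_syn$g_bar * in_s
        if (coupling == "conductance") {
          Iin <- gin * (in_syn$reversal - V[in_target])
        } else {
          Iin <- ifelse(in_syn$sign == "exc", gin, -gin)
        }
        for (k in seq_along(in_target)) {
          I[in_target[k]] <- I[in_target[k]] + Iin[k]
        }
      }
      if (!is.null(I_ext_mat)) {
        for (k in seq_along(drv_idx)) {
          I[drv_idx[k]] <- I[drv_idx[k]] + I_ext_mat[m, k]
        }
      }
      # forward-Euler membrane update
      for (i in seq_len(nn)) {
        if (!n$enabled[i]) next
        if (ref[i] > 1e-12) { V[i] <- n$Vr[i]; ref[i] <- ref[i] - dt_ref; next }
        dV <- (-(V[i] - n$V0[i]) / n$R[i] + I[i]) / n$C[i]
        V[i] <- V[i] + dt_ref * dV
        if (V[i] >= n$Vth[i]) {
          V[i] <- n$Vr[i]; ref[i] <- n$t_ref[i]
          t_sp <- (m - 1) * dt + q * dt_ref
          spikes[[i]] <- c(spikes[[i]], t_sp)
          spiked_engine_step <- c(spiked_engine_step, i)
        }
      }
      # forward-Euler synapse decay
      if (ns > 0L) {
        al <- syn$kind == "alpha"
        if (any(al)) {
          s_old <- s_state[al]
          s_state[al] <- s_old + dt_ref * h_state[al]
          h_state[al] <- h_state[al] + dt_ref *
            (-(syn$a_r[al] + syn$a_d[al]) * h_state[al] -
               syn$a_r[al] * syn$a_d[al] * s_old)
        }
        ot <- !al
        s_state[ot] <- s_state[ot] - dt_ref * s_state[ot] / syn$tau[ot]
      }
      if (!is.null(in_syn)) {
        for (k in seq_along(in_target)) {
          if (in_syn$kind[k] == "alpha") {
            so <- in_s[k]
            in_s[k] <- so + dt_ref * in_h[k]
            in_h[k] <- in_h[k] + dt_ref *
              (-(in_syn$a_r[k] + in_syn$a_d[k]) * in_h[k] -
                 in_syn$a_r[k] * in_syn$a_d[k] * so)
          } else {
            in_s[k] <- in_s[k] - dt_ref * in_s[k] / in_syn$tau[k]
          }
        }
      }
    }
    if (length(spiked_engine_step) > 0L) {
      pending[[m]] <- unique(spiked_engine_step)
    }
    if (record_v) Vrec[m, ] <- V
  }
  out <- new_spike_record(n$id, spikes, t_end = cfg$duration,
                          provenance = list(model = model$label,
                                            engine = "reference"))
  if (record_v) {
    colnames(Vrec) <- n$id
    attr(out, "V") <- Vrec
  }
  out
}

new_spike_record <- function(ids, times_list, t_end, provenance = list()) {
  names(times_list) <- ids
  times_list <- lapply(times_list, function(x) if (is.null(x)) numeric() else x)
  structure(list(ids = ids, times = times_list, t_end = t_end,
                 provenance = provenance),
            class = "cx_spike_record")
}

#' @export
print.cx_spike_record <- function(x, ...) {
  n_sp <- sum(vapply(x$times, length, integer(1)))
  cat("cx_spike_record:", length(x$ids), "neurons,", n_sp,
      "spikes over", x$t_end, "s\n")
  invisible(x)
}

#' Spike record as a data frame
#'
#' @param record A `cx_spike_record`.
#' @return `data.frame(neuron_id, spike_time_s)` sorted by neuron then time.
#' @export
spikes_as_df <- function(record) {
  stopifnot(inherits(record, "cx_spike_record"))
  n_per <- vapply(record$times, length, integer(1))
  data.frame(neuron_id = rep(record$ids, n_per),
             spike_time_s = unlist(record$times, use.names = FALSE),
             stringsAsFactors = FALSE)
}
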