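#' Engine configuration
#'
#' @param dt Fixed step (s), default `1e-4`.
#' @param duration Simulation length (s); defaults to the drive's length.
#' @param delay_steps Synaptic delay in engine steps (`>= 1`; one-step
#'   minimum so the update order is well defined).
#' @param coupling `"conductance"` (driving-force coupling
#'   `I = g (E_rev - V)`) or `"current"` (signed `I = +/- g`).
#' @param record `"spikes"` or `"spikes+voltages"`.
#' @param record_ids Neuron ids whose voltages to record (default all, only
#'   used with `record = "spikes+voltages"`).
#' @return An `cx_engine_config` list.
#' @export
engine_config <- function(dt = 1e-4, duration = NULL, delay_steps = 1L,
                          coupling = c("conductance", "current"),
                          record = c("spikes", "spikes+voltages"),
                          record_ids = NULL) {
  stopifnot(dt > 0, delay_steps >= 1)
  structure(list(dt = dt, duration = duration,
                 delay_steps = as.integer(delay_steps),
                 coupling = match.arg(coupling), record = match.arg(record),
                 record_ids = record_ids),
            class = "cx_engine_config")
}

#' Simulate a circuit under an input drive
#'
#' Deterministic fixed-step network simulation. Per step the engine (1)
#' realizes input spikes and injected currents, (2) applies presynaptic
#' spikes from `delay_steps` engine steps earlier to the synapse states,
#' (3) sums synaptic and injected currents, (4) advances the LIF membranes
#' by their exact exponential update, and (5) records spikes. Identical
#' `(model, drive, cfg, seed)` give bit-identical spike records. Disabled
#' (silenced) neurons emit no spikes and their outgoing synapses contribute
#' no current.
#'
#' @param model A `cx_circuit`.
#' @param drive A `cx_input_drive` (current or poisson mode), or `NULL` for
#'   no external input.
#' @param cfg An [engine_config()]; its `dt` must equal the drive's.
#' @param seed Integer seed for the Poisson realization of rate drives.
#' @return A `cx_spike_record`; with `record = "spikes+voltages"`, the
#'   voltage traces are attached as attribute `"V"` (matrix steps x
#'   neurons, colnames = ids).
#' @export
simulate <- function(model, drive = NULL, cfg = engine_config(),
                     seed = 0L) {
  stopifnot(inherits(model, "cx_circuit"))
  dt <- cfg$dt
  if (!is.null(drive)) {
    if (abs(drive$dt - dt) > 1e-15) {
      stop("inconsistent dt between drive (", drive$dt, ") and engine (",
           dt, ")")
    }
    n_steps <- drive$n_steps
  } else {
    if (is.null(cfg$duration)) stop("cfg$duration required without a drive")
    n_steps <- round(cfg$duration / dt)
  }
  if (!is.null(cfg$duration)) n_steps <- round(cfg$duration / dt)

  n <- model$neurons
  syn <- model$synapses
  nn <- nrow(n)
  kind_code <- function(k) match(k, c("alpha", "exp", "nmda")) - 1L

  s_pre <- match(syn$pre, n$id) - 1L
  s_post <- match(syn$post, n$id) - 1L
  s_kind <- kind_code(syn$kind)
  s_gbar <- syn$g_bar
  s_rev <- syn$reversal
  s_sign <- ifelse(syn$sign == "exc", 1L, -1L)
  s_ar <- syn$a_r; s_ad <- syn$a_d; s_tau <- syn$tau
  s_alpha <- syn$alpha; s_mg <- syn$mg

  ev_step <- integer(); ev_syn <- integer()
  I_ext <- matrix(0, 0, 0); driven <- integer()
  input_spikes <- NULL
  if (!is.null(drive)) {
    if (drive$mode == "current") {
      driven <- match(drive$ids, n$id) - 1L
      if (anyNA(driven)) stop("drive references unknown neurons")
      I_ext <- drive$values[seq_len(n_steps), , drop = FALSE]
    } else {
      input_spikes <- sample_poisson(drive, seed)
      k0 <- length(s_pre)
      tgt <- match(drive$ids, n$id) - 1L
      if (anyNA(tgt)) stop("drive references unknown neurons")
      s_pre <- c(s_pre, rep(-1L, length(tgt)))
      s_post <- c(s_post, tgt)
      s_kind <- c(s_kind, kind_code(drive$syn$kind))
      s_gbar <- c(s_gbar, drive$syn$g_bar)
      s_rev <- c(s_rev, drive$syn$reversal)
      s_sign <- c(s_sign, ifelse(drive$syn$sign == "exc", 1L, -1L))
      s_ar <- c(s_ar, drive$syn$a_r); s_ad <- c(s_ad, drive$syn$a_d)
      s_tau <- c(s_tau, drive$syn$tau)
      s_alpha <- c(s_alpha, drive$syn$alpha); s_mg <- c(s_mg, drive$syn$mg)
      for (k in seq_along(tgt)) {
        st <- input_spikes$steps[[k]]
        st <- st[st <= n_steps]
        ev_step <- c(ev_step, st - 1L)       # 0-based for the engine
        ev_syn <- c(ev_syn, rep(k0 + k - 1L, length(st)))
      }
      o <- order(ev_step)
      ev_step <- ev_step[o]; ev_syn <- ev_syn[o]
    }
  }

  rec_idx <- integer()
  if (cfg$record == "spikes+voltages") {
    ids <- if (is.null(cfg$record_ids)) n$id else cfg$record_ids
    rec_idx <- match(ids, n$id) - 1L
    if (anyNA(rec_idx)) stop("record_ids contains unknown neurons")
  }

  res <- cx_engine_run(
    n$C, n$R, n$V0, n$Vth, n$Vr, n$t_ref, n$enabled,
    as.integer(s_pre), as.integer(s_post), as.integer(s_kind),
    as.numeric(s_gbar), as.numeric(s_rev), as.integer(s_sign),
    as.numeric(ifelse(is.na(s_ar), 0, s_ar)),
    as.numeric(ifelse(is.na(s_ad), 0, s_ad)),
    as.numeric(ifelse(is.na(s_tau), 1, s_tau)),
    as.numeric(ifelse(is.na(s_alpha), 0, s_alpha)),
    as.numeric(ifelse(is.na(s_mg), 0, s_mg)),
    as.integer(ev_step), as.integer(ev_syn),
    I_ext, as.integer(driven),
    dt, as.integer(n_steps), cfg$delay_steps,
    if (cfg$coupling == "conductance") 0L else 1L,
    as.integer(rec_idx))

  times_list <- vector("list", nn)
  if (length(res$spike_neuron) > 0L) {
    sp <- split(res$spike_step * dt, res$spike_neuron)
    for (nm in names(sp)) times_list[[as.integer(nm)]] <- sp[[nm]]
  }
  rec <- new_spike_record(
    n$id, times_list, t_end = n_steps * dt,
    provenance = list(model = model$label, seed = seed,
                      config_hash = config_hash(model$config)))
  if (cfg$record == "spikes+voltages") {
    V <- res$V
    colnames(V) <- n$id[rec_idx + 1L]
    attr(rec, "V") <- V
  }
  rec
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical serialization; used in run manifests so that a run
#' is reproducible from (config hash, seed).
#'
#' @param cfg Any R object.
#' @return Character MD5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
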