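#' @title Stimulus encoders
#' @description
#' Encoders turn a rendered stimulus protocol into per-neuron input drives:
#' injected current traces (Model A) or instantaneous Poisson rate traces
#' (Models B and C). Drives are sampled on the engine's time grid
#' (`t_m = (m-1) dt`) and carried in a `cx_input_drive` object together with
#' the input-synapse parameters used to couple spike-train inputs into the
#' circuit.
#' @name encoders
NULL

new_input_drive <- function(mode, dt, ids, values, syn = NULL) {
  stopifnot(mode %in% c("current", "poisson"))
  structure(list(mode = mode, dt = dt, n_steps = nrow(values),
                 ids = ids, values = values, syn = syn),
            class = "cx_input_drive")
}

#' @export
print.cx_input_drive <- function(x, ...) {
  cat("cx_input_drive (", x$mode, "): ", length(x$ids), " neurons x ",
      x$n_steps, " steps (dt = ", x$dt, " s)\n", sep = "")
  invisible(x)
}

input_syn_table <- function(cfg, conn_class, n) {
  spec <- cfg$synapses[[conn_class]]
  if (is.null(spec)) stop("configuration error: missing synapse class '",
                          conn_class, "'")
  params <- switch(spec$kind,
    alpha = list(a_r = spec$a_r, a_d = spec$a_d),
    exp = list(tau = spec$tau),
    nmda = list(tau = spec$tau, alpha = spec$alpha, mg = spec$mg))
  g_bar <- spec$peak / synapse_unit_peak(spec$kind, params)
  data.frame(kind = rep(spec$kind, n), sign = spec$sign, g_bar = g_bar,
             reversal = spec$reversal,
             a_r = if (spec$kind == "alpha") spec$a_r else NA_real_,
             a_d = if (spec$kind == "alpha") spec$a_d else NA_real_,
             tau = if (spec$kind != "alpha") spec$tau else NA_real_,
             alpha = if (spec$kind == "nmda") spec$alpha else NA_real_,
             mg = if (spec$kind == "nmda") spec$mg else NA_real_,
             stringsAsFactors = FALSE)
}

drive_times <- function(protocol, dt) {
  n_steps <- round(protocol$duration / dt)
  (seq_len(n_steps) - 1) * dt
}

#' Encode the protocol as injected currents (Model A)
#'
#' Every enabled PB-dendritic columnar neuron (PB-EB-LAL, PB-EB-NO) receives
#' the stimulus filtered by its glomerulus's rectangular receptive field
#' (20 degrees of azimuth, full elevation) as an injected current
#' `I(t) = gain_pb * drive(t)`; every ring neuron receives the stimulus
#' filtered by its BU microglomerulus's Gaussian receptive field
#' (sigma = 9 degrees) times `gain_ring`. Disabled neurons receive zero
#' (they are excluded from the drive).
#'
#' @param model A Model-A style `cx_circuit`.
#' @param protocol A `cx_protocol`.
#' @param cfg_enc Encoder parameters (see `encoder` in
#'   [default_config()]`("A")`).
#' @param dt Engine step (s).
#' @return A `cx_input_drive` in current mode.
#' @export
encode_model_A <- function(model, protocol, cfg_enc = NULL, dt = 1e-4) {
  if (is.null(cfg_enc)) cfg_enc <- model$config$encoder
  stopifnot(cfg_enc$mode == "current", cfg_enc$gain_pb > 0)
  times <- drive_times(protocol, dt)
  n <- model$neurons
  topo <- model$topology
  drv <- n[n$enabled & ((n$cell_class %in% c("PB-EB-LAL", "PB-EB-NO")) |
                          (n$cell_class == "Ring" & n$dend_region == "BU")), ]
  if (nrow(drv) == 0L) stop("no drivable neurons in model")
  vals <- matrix(0, length(times), nrow(drv))
  glom_cache <- list()
  for (k in seq_len(nrow(drv))) {
    if (drv$cell_class[k] == "Ring") {
      if (is.na(drv$rf_center[k])) {
        stop("ring neuron ", drv$id[k], " lacks a receptive-field assignment")
      }
      rf <- rf_gauss(drv$rf_center[k], cfg_enc$rf_ring_sigma)
      vals[, k] <- cfg_enc$gain_ring * rf_drive(protocol, rf, times)
    } else {
      g <- drv$glom[k]
      if (is.null(glom_cache[[g]])) {
        ctr <- topo$glom_centers[glom_index(topo, g) + 1L]
        rf <- rf_rect(ctr, cfg_enc$rf_pb_width)
        glom_cache[[g]] <- cfg_enc$gain_pb * rf_drive(protocol, rf, times)
      }
      vals[, k] <- glom_cache[[g]]
    }
  }
  new_input_drive("current", dt, drv$id, vals)
}

#' Encode the protocol as Poisson rates onto EB wedges (Model B)
#'
#' Each EB wedge has a rectangular receptive field spanning its own 22.5
#' degree sector; every EB-LAL-PB neuron of wedge `j` receives rate
#' `rate_j(t) = rate_background + kappa * drive_j(t)` with
#' `kappa = rate_max / drive(calibration bar)`, so a maximally bright bar of
#' the calibration width optimally aligned with the wedge yields a
#' stimulus-driven component of exactly `rate_max`. The background rate is
#' present even in darkness. If `background_additive` is `FALSE` the total
#' is instead capped at `rate_max`.
#'
#' @param model A Model-B style `cx_circuit`.
#' @param protocol A `cx_protocol`.
#' @param cfg_enc Encoder parameters (see [default_config()]`("B")`).
#' @param dt Engine step (s).
#' @return A `cx_input_drive` in poisson mode.
#' @export
encode_model_B <- function(model, protocol, cfg_enc = NULL, dt = 1e-4) {
  if (is.null(cfg_enc)) cfg_enc <- model$config$encoder
  stopifnot(cfg_enc$rate_max > 0, cfg_enc$rate_background >= 0)
  times <- drive_times(protocol, dt)
  topo <- model$topology
  wedge_width <- 360 / topo$n_wedges
  cal_drive <- min(cfg_enc$cal_bar_width, wedge_width) / wedge_width
  kappa <- cfg_enc$rate_max / cal_drive
  ctrs <- wedge_centers(topo)
  n <- model$neurons
  drv <- n[n$enabled & n$cell_class == "EB-LAL-PB", ]
  wedge_drive <- matrix(0, length(times), topo$n_wedges)
  for (w in seq_len(topo$n_wedges)) {
    rf <- rf_rect(ctrs[w], wedge_width)
    wedge_drive[, w] <- rf_drive(protocol, rf, times)
  }
  vals <- matrix(0, length(times), nrow(drv))
  for (k in seq_len(nrow(drv))) {
    stim <- kappa * wedge_drive[, drv$wedge[k] + 1L]
    vals[, k] <- if (isTRUE(cfg_enc$background_additive)) {
      cfg_enc$rate_background + stim
    } else {
      pmin(cfg_enc$rate_background + stim, cfg_enc$rate_max)
    }
  }
  syn <- input_syn_table(model$config, "input->EB-LAL-PB", nrow(drv))
  new_input_drive("poisson", dt, drv$id, vals, syn)
}

#' Encode the protocol as Poisson rates onto PB glomerulus pairs (Model C)
#'
#' The wedge receptive fields are as in Model B, but each wedge's drive is
#' routed to all enabled neurons with dendrites in the wedge's glomerulus
#' pair, scaled so that a wedge-covering maximum-brightness bar yields
#' `rate_max` (50 Hz); there is no background term. Neurons reached by
#' several wedges receive the summed rate. Optionally, ring neurons receive
#' a constant-rate external drive (`ring_rate`, default 0 = off).
#'
#' @param model A Model-C style `cx_circuit`.
#' @param protocol A `cx_protocol`.
#' @param cfg_enc Encoder parameters (see [default_config()]`("C")`).
#' @param dt Engine step (s).
#' @return A `cx_input_drive` in poisson mode.
#' @export
encode_model_C <- function(model, protocol, cfg_enc = NULL, dt = 1e-4) {
  if (is.null(cfg_enc)) cfg_enc <- model$config$encoder
  stopifnot(cfg_enc$rate_max > 0)
  times <- drive_times(protocol, dt)
  topo <- model$topology
  ctrs <- wedge_centers(topo)
  wedge_width <- 360 / topo$n_wedges
  n <- model$neurons
  # rate per wedge; calibration bar covers the whole wedge (unit drive)
  wedge_rate <- matrix(0, length(times), topo$n_wedges)
  for (w in seq_len(topo$n_wedges)) {
    rf <- rf_rect(ctrs[w], wedge_width)
    wedge_rate[, w] <- cfg_enc$rate_max * rf_drive(protocol, rf, times)
  }
  drv <- n[n$enabled & n$cell_class %in% c("PB-EB-LAL", "PB-EB-NO"), ]
  vals <- matrix(0, length(times), nrow(drv))
  for (k in seq_len(nrow(drv))) {
    for (w in seq_len(topo$n_wedges)) {
      if (drv$glom[k] %in% topo$wedge_to_glom_pair[w, ]) {
        vals[, k] <- vals[, k] + wedge_rate[, w]
      }
    }
  }
  ids <- drv$id
  syn_lal <- input_syn_table(model$config, "input->PB-EB-LAL", 1L)
  syn_no <- input_syn_table(model$config, "input->PB-EB-NO", 1L)
  syn <- do.call(rbind, lapply(drv$cell_class, function(cls) {
    if (cls == "PB-EB-LAL") syn_lal else syn_no
  }))
  ring_rate <- if (is.null(cfg_enc$ring_rate)) 0 else cfg_enc$ring_rate
  if (ring_rate > 0) {
    rings <- n[n$enabled & n$cell_class == "Ring", ]
    if (nrow(rings) > 0L) {
      vals <- cbind(vals, matrix(ring_rate, length(times), nrow(rings)))
      ids <- c(ids, rings$id)
      syn <- rbind(syn, input_syn_table(model$config, "input->Ring",
                                        nrow(rings)))
    }
  }
  rownames(syn) <- NULL
  new_input_drive("poisson", dt, ids, vals, syn)
}

# stable 31-bit hash of a neuron id mixed with the run seed, so that input
# spike trains are reproducible per (seed, id) independent of the id set
id_seed <- function(id, seed) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 65536) * 32749 + 7919) %% 2147483647)
}

#' Realize Poisson spike trains from a rate drive
#'
#' Per engine step and neuron, a spike is emitted with probability
#' `rate * dt`, independently across neurons and steps (Bernoulli thinning,
#' exact to first order in `dt`). The realization is deterministic given the
#' seed and the neuron id.
#'
#' @param drive A `cx_input_drive` in poisson mode.
#' @param seed Integer seed.
#' @return List with `ids`, `steps` (per-neuron 1-based engine-step indices)
#'   and `times` (spike times, s), of class `cx_input_spikes`.
#' @export
sample_poisson <- function(drive, seed = 0L) {
  stopifnot(inherits(drive, "cx_input_drive"), drive$mode == "poisson")
  pmax_ <- max(drive$values) * drive$dt
  if (pmax_ >= 1) {
    stop("dt * max rate = ", signif(pmax_, 3),
         " >= 1: decrease dt for a valid Bernoulli thinning")
  }
  steps <- vector("list", length(drive$ids))
  times <- vector("list", length(drive$ids))
  for (k in seq_along(drive$ids)) {
    old <- .Random.seed_save()
    set.seed(id_seed(drive$ids[k], seed))
    u <- stats::runif(drive$n_steps)
    .Random.seed_restore(old)
    sp <- which(u < drive$values[, k] * drive$dt)
    steps[[k]] <- sp
    times[[k]] <- (sp - 1) * drive$dt
  }
  structure(list(ids = drive$ids, steps = steps, times = times,
                 dt = drive$dt, seed = seed), class = "cx_input_spikes")
}

# save/restore the global RNG state so sampling is a pure function of the
# seed and does not perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
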