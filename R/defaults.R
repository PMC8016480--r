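# Shipped default configurations for the three circuit architectures.
#
# Per-class neuron counts, synaptic weights and electrical constants are NOT
# printed in the source publications' comparison; the values below are
# reconstructed defaults, calibrated so that each architecture expresses its
# qualitative regime (input-driven bump for A; self-sustaining, input-movable
# bump for B; NMDA-stabilized persistent bump for C). Counts default to one
# neuron per sector per class. All of this is configuration, not data.

#' Default run configuration for a circuit model
#'
#' Returns the complete nested configuration (topology, per-class counts and
#' membrane parameters, per-connection-class synapse table, stimulus encoder,
#' engine and analysis settings) for one of the three shipped architectures.
#' Every value can be overridden via [load_config()] or by editing the list.
#'
#' @param model `"A"`, `"B"` or `"C"`.
#' @return Nested configuration list.
#' @export
default_config <- function(model = c("A", "B", "C")) {
  model <- match.arg(model)
  t_ref <- switch(model, A = 2e-3, B = 2.2e-3, C = 2e-3)
  lif_common <- lif_params(t_ref = t_ref)

  topology <- list(n_wedges = 16L, n_glomeruli = 18L)

  counts <- switch(model,
    A = list("EB-LAL-PB" = 1L, "PB-EB-LAL" = 1L, "PB-EB-NO" = 1L,
             "PB-local" = 1L, "Ring" = 1L),
    B = list("EB-LAL-PB" = 1L, "PB-EB-LAL" = 1L, "PB-EB-NO" = 1L,
             "PB-local" = 1L),
    C = list("EB-LAL-PB" = 1L, "PB-EB-LAL" = 1L, "PB-EB-NO" = 1L,
             "Ring" = 1L))

  classes <- names(counts)
  lif <- stats::setNames(rep(list(lif_common), length(classes)), classes)

  E_EXC <- 0; E_INH <- -80e-3

  syn <- function(kind, sign, peak, ...) {
    c(list(kind = kind, sign = sign, peak = peak,
           reversal = if (sign == "exc") E_EXC else E_INH), list(...))
  }

  synapses <- switch(model,
    A = list(
      "EB-LAL-PB->PB-EB-LAL" = syn("alpha", "exc", 35.0e-9),
      "EB-LAL-PB->PB-EB-NO"  = syn("alpha", "exc", 35.0e-9),
      "PB-EB-LAL->EB-LAL-PB" = syn("alpha", "exc", 52.5e-9),
      "PB-EB-NO->EB-LAL-PB"  = syn("alpha", "exc", 52.5e-9),
      "EB-LAL-PB->PB-local"  = syn("alpha", "exc", 112.0e-9),
      "PB-local->PB-EB-LAL"  = syn("alpha", "inh", 78.75e-9),
      "PB-local->PB-EB-NO"   = syn("alpha", "inh", 78.75e-9),
      "PB-local->PB-local"   = syn("alpha", "inh", 29.75e-9),
      "PB-local->EB-LAL-PB"  = syn("alpha", "inh", 17.5e-9),
      "Ring->EB-LAL-PB"      = syn("alpha", "inh", 35.0e-9)),
    B = list(
      "input->EB-LAL-PB"     = syn("alpha", "exc", 22.0e-9 * 0.954011415440),
      "EB-LAL-PB->PB-EB-LAL" = syn("alpha", "exc", 88.2e-9 * 0.966648820406),
      "EB-LAL-PB->PB-EB-NO"  = syn("alpha", "exc", 88.2e-9 * 0.966648820406),
      "PB-EB-LAL->EB-LAL-PB" = syn("alpha", "exc", 54.88e-9 * 0.966648820406),
      "PB-EB-NO->EB-LAL-PB"  = syn("alpha", "exc", 54.88e-9 * 0.966648820406),
      "EB-LAL-PB->PB-local"  = syn("alpha", "exc", 145.6e-9 * 1.027924543663),
      "PB-local->PB-EB-LAL"  = syn("alpha", "inh",
                                   90e-9 * 1.75 * 1.0014991 * 0.931105961954),
      "PB-local->PB-EB-NO"   = syn("alpha", "inh",
                                   90e-9 * 1.75 * 1.0014991 * 0.931105961954),
      "PB-local->PB-local"   = syn("alpha", "inh", 29.75e-9),
      "PB-local->EB-LAL-PB"  = syn("alpha", "inh", 112.0e-9)),
    C = list(
      "input->PB-EB-LAL"     = syn("exp", "exc", 44.0e-9 * 0.964751459175,
                                   tau = 5e-3),
      "input->PB-EB-NO"      = syn("exp", "exc", 44.0e-9 * 0.964751459175,
                                   tau = 5e-3),
      "input->Ring"          = syn("exp", "exc", 4.0e-9, tau = 5e-3),
      # the memory leg of the loop: saturating NMDA with slow decay
      "EB-LAL-PB->PB-EB-LAL" = syn("nmda", "exc", 290.0e-9,
                                   tau = 100e-3, alpha = 0.1, mg = 1.0),
      # the relay leg: fast AMPA back-projection to the wedges
      "PB-EB-LAL->EB-LAL-PB" = syn("exp", "exc",
                                   131.21722554e-9 * 0.953879325033,
                                   tau = 5e-3),
      "PB-EB-NO->EB-LAL-PB"  = syn("exp", "exc", 131.0e-9, tau = 5e-3),
      "EB-LAL-PB->Ring"      = syn("exp", "exc",
                                   76.23955300e-9 * 1.018430593012,
                                   tau = 5e-3),
      "Ring->EB-LAL-PB"      = syn("exp", "inh", 88.58054069e-9,
                                   tau = 10e-3)))

  # alpha kinetics shared default: ~0.7 ms time-to-peak, ~5 ms decay
  for (nm in names(synapses)) {
    if (synapses[[nm]]$kind == "alpha") {
      if (is.null(synapses[[nm]]$a_r)) synapses[[nm]]$a_r <- 5000
      if (is.null(synapses[[nm]]$a_d)) synapses[[nm]]$a_d <- 200
    }
  }

  encoder <- switch(model,
    A = list(mode = "current",
             gain_pb = 1.5e-9,      # A of injected current per unit drive
             gain_ring = 0.7e-9,
             rf_pb_width = 20,      # deg, rectangular, full elevation
             rf_ring_sigma = 9),    # deg, Gaussian in azimuth and elevation
    B = list(mode = "poisson",
             rate_max = 120,        # Hz at the calibration bar
             rate_background = 5,   # Hz, always present
             cal_bar_width = 20,    # deg; calibration bar at brightness 1
             background_additive = TRUE),
    C = list(mode = "poisson",
             rate_max = 50,         # Hz at a wedge-covering max-brightness bar
             rate_background = 0,
             cal_bar_width = NA,    # wedge-covering calibration (unit drive)
             ring_rate = 0))        # optional constant drive to ring neurons

  list(
    model = model,
    topology = topology,
    counts = counts,
    lif = lif,
    # configured synapse peaks are the TOTAL converging conductance per
    # target neuron and connection class (divided over the in-degree)
    normalize_in_degree = TRUE,
    offsets = list("PB-EB-LAL" = 1L, "PB-EB-NO" = 1L),
    # PB-EB-* axon arborization: relative synaptic weight per wedge
    # displacement from the shifted retinotopic target wedge
    axon_spread = c("-1" = 0.5, "0" = 1, "1" = 0.5),
    synapses = synapses,
    encoder = encoder,
    engine = list(dt = 1e-4, delay_steps = 1L, coupling = "conductance",
                  record = "spikes"),
    protocol = list(duration = 35, bar_width = 20,
                    moving_brightness = 1, static_brightness = 0.5,
                    static_azimuth = 60, initial_azimuth = 0,
                    sweep_period = 29, t_move_start = 1,
                    t_move_end = 30, t_static_end = 33),
    analysis = list(kernel_tau = 0.7215, sample_dt = 0.01,
                    min_prominence = 0.2, normalize = FALSE),
    seed = 0L
  )
}
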