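#' @title Executable circuit models
#' @description
#' A `cx_circuit` is a typed neuron/synapse graph over a [make_topology()]
#' scaffold: a neuron table (one row per point neuron, carrying its cell
#' class, innervated sector, enable flag and membrane parameters) and a
#' synapse table (one row per connection, carrying kinetic kind, sign,
#' neuropil, conductance scaling and kinetic parameters). Only synapses
#' within the protocerebral bridge (PB) and the ellipsoid body (EB) are
#' modelled.
#'
#' @name cx_circuit
NULL

CORE_CLASSES <- c("EB-LAL-PB", "PB-EB-LAL", "PB-EB-NO")
ALL_CLASSES <- c(CORE_CLASSES, "PB-local", "Ring")

new_circuit <- function(topology, neurons, synapses, label, config) {
  structure(list(topology = topology, neurons = neurons,
                 synapses = synapses, label = label, config = config),
            class = "cx_circuit")
}

empty_synapse_table <- function() {
  data.frame(pre = character(), post = character(), conn_class = character(),
             kind = character(), sign = character(), region = character(),
             g_bar = numeric(), reversal = numeric(), a_r = numeric(),
             a_d = numeric(), tau = numeric(), alpha = numeric(),
             mg = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.cx_circuit <- function(x, ...) {
  cat("cx_circuit (model ", x$label, "): ", nrow(x$neurons), " neurons (",
      sum(!x$neurons$enabled), " disabled), ", nrow(x$synapses),
      " synapses\n", sep = "")
  tab <- table(x$neurons$cell_class)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

# ---- neuron table construction ---------------------------------------------

make_neuron_table <- function(topology, counts, lif, model) {
  rows <- list()
  add <- function(id, cell_class, subtype, dend_region, wedge, glom,
                  rf_center, axon_region, p, enabled = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, cell_class = cell_class, subtype = subtype,
      dend_region = dend_region,
      wedge = if (is.null(wedge)) NA_integer_ else as.integer(wedge),
      glom = if (is.null(glom)) NA_character_ else glom,
      rf_center = if (is.null(rf_center)) NA_real_ else rf_center,
      axon_region = axon_region, enabled = enabled,
      C = p$C, R = p$R, V0 = p$V0, Vth = p$Vth, Vr = p$Vr, t_ref = p$t_ref,
      stringsAsFactors = FALSE)
  }
  nw <- topology$n_wedges

  if (!is.null(counts[["EB-LAL-PB"]])) {
    p <- lif[["EB-LAL-PB"]]
    for (w in 0:(nw - 1L)) for (k in seq_len(counts[["EB-LAL-PB"]]) - 1L) {
      add(sprintf("EB-LAL-PB-w%02d-%d", w, k), "EB-LAL-PB", NA_character_,
          "EB", w, NULL, NULL, "PB+LAL", p)
    }
  }
  for (cls in c("PB-EB-LAL", "PB-EB-NO")) {
    if (is.null(counts[[cls]])) next
    p <- lif[[cls]]
    enabled <- !(model == "C" && cls == "PB-EB-NO")
    for (g in topology$glom_ids) for (k in seq_len(counts[[cls]]) - 1L) {
      add(sprintf("%s-%s-%d", cls, g, k), cls, NA_character_,
          "PB", NULL, g, NULL,
          if (cls == "PB-EB-LAL") "EB+LAL" else "EB+NO", p, enabled)
    }
  }
  if (!is.null(counts[["PB-local"]])) {
    p <- lif[["PB-local"]]
    for (g in topology$glom_ids) for (k in seq_len(counts[["PB-local"]]) - 1L) {
      add(sprintf("PB-local-%s-%d", g, k), "PB-local", NA_character_,
          "PB", NULL, g, NULL, "PB", p)
    }
  }
  if (!is.null(counts[["Ring"]])) {
    p <- lif[["Ring"]]
    if (model == "C") {
      # three ring-neuron subtypes, all innervating the EB
      for (st in 1:3) for (w in 0:(nw - 1L)) {
        for (k in seq_len(counts[["Ring"]]) - 1L) {
          add(sprintf("Ring-r%d-w%02d-%d", st, w, k), "Ring",
              paste0("r", st), "EB", NULL, NULL, NULL, "EB", p)
        }
      }
    } else {
      # model A: one BU microglomerulus per ring neuron, centres equally
      # spaced in azimuth at mid-elevation
      n_ring <- counts[["Ring"]] * nw
      ctrs <- (seq_len(n_ring) - 0.5) * 360 / n_ring
      for (i in seq_len(n_ring)) {
        add(sprintf("Ring-%02d", i - 1L), "Ring", NA_character_,
            "BU", NULL, NULL, ctrs[i], "EB", p)
      }
    }
  }
  do.call(rbind, rows)
}

# ---- wiring ----------------------------------------------------------------

# axon target wedge of a PB-EB-* neuron: the wedge retinotopically matching
# its glomerulus, shifted by an integer wedge offset whose sign depends on
# the hemisphere (L -> -offset, R -> +offset)
pb_eb_target_wedge <- function(topology, glom, offset) {
  gi <- glom_index(topology, glom) + 1L
  w0 <- azimuth_to_wedge(topology, topology$glom_centers[gi])
  sgn <- ifelse(topology$glom_hemisphere[gi] == "R", 1L, -1L)
  (w0 + sgn * as.integer(offset)) %% topology$n_wedges
}

wire_circuit <- function(topology, neurons, cfg) {
  normalize <- !isFALSE(cfg$normalize_in_degree)
  syn_rows <- list()
  add_syn <- function(pre, post, conn_class, spec, region, relw = 1) {
    if (length(pre) == 0L || length(post) == 0L) return(invisible())
    pairs <- expand.grid(pre = pre, post = post,
                         stringsAsFactors = FALSE)
    relw <- rep_len(relw, length(pre) * length(post))
    keep <- pairs$pre != pairs$post
    pairs <- pairs[keep, , drop = FALSE]
    relw <- relw[keep]
    if (nrow(pairs) == 0L) return(invisible())
    kind <- spec$kind
    params <- switch(kind,
      alpha = list(a_r = spec$a_r, a_d = spec$a_d),
      exp = list(tau = spec$tau),
      nmda = list(tau = spec$tau, alpha = spec$alpha, mg = spec$mg))
    g_bar <- spec$peak / synapse_unit_peak(kind, params)
    syn_rows[[length(syn_rows) + 1L]] <<- data.frame(
      pre = pairs$pre, post = pairs$post, conn_class = conn_class,
      kind = kind, sign = spec$sign, region = region, g_bar = g_bar,
      relw = relw,
      reversal = spec$reversal,
      a_r = if (kind == "alpha") spec$a_r else NA_real_,
      a_d = if (kind == "alpha") spec$a_d else NA_real_,
      tau = if (kind %in% c("exp", "nmda")) spec$tau else NA_real_,
      alpha = if (kind == "nmda") spec$alpha else NA_real_,
      mg = if (kind == "nmda") spec$mg else NA_real_,
      stringsAsFactors = FALSE)
  }
  by_class <- split(neurons$id, neurons$cell_class)
  nrn <- function(cls) if (is.null(by_class[[cls]])) character() else by_class[[cls]]

  for (cc in names(cfg$synapses)) {
    spec <- cfg$synapses[[cc]]
    halves <- strsplit(cc, "->", fixed = TRUE)[[1]]
    if (halves[1] == "input") next  # realized by the stimulus encoders
    pre_cls <- halves[1]; post_cls <- halves[2]
    if (pre_cls == "EB-LAL-PB" && post_cls %in% c("PB-EB-LAL", "PB-EB-NO")) {
      # axon terminals in the wedge's glomerulus pair; synapse in PB
      pre_tab <- neurons[neurons$cell_class == "EB-LAL-PB", ]
      for (i in seq_len(nrow(pre_tab))) {
        gloms <- topology$wedge_to_glom_pair[pre_tab$wedge[i] + 1L, ]
        posts <- neurons$id[neurons$cell_class == post_cls &
                            neurons$glom %in% gloms]
        add_syn(pre_tab$id[i], posts, cc, spec, "PB")
      }
    } else if (pre_cls %in% c("PB-EB-LAL", "PB-EB-NO") &&
               post_cls == "EB-LAL-PB") {
      off <- cfg$offsets[[pre_cls]]
      # axonal arborization across neighbouring wedges: relative weight per
      # wedge displacement from the (shifted) retinotopic target
      spread <- cfg$axon_spread
      if (is.null(spread)) spread <- c("0" = 1)
      pre_tab <- neurons[neurons$cell_class == pre_cls, ]
      for (i in seq_len(nrow(pre_tab))) {
        tw0 <- pb_eb_target_wedge(topology, pre_tab$glom[i], off)
        for (dnm in names(spread)) {
          tw <- (tw0 + as.integer(dnm)) %% topology$n_wedges
          posts <- neurons$id[neurons$cell_class == "EB-LAL-PB" &
                              neurons$wedge == tw]
          add_syn(pre_tab$id[i], posts, cc, spec, "EB",
                  relw = spread[[dnm]])
        }
      }
    } else if (pre_cls == "EB-LAL-PB" && post_cls == "PB-local") {
      add_syn(nrn("EB-LAL-PB"), nrn("PB-local"), cc, spec, "PB")
    } else if (pre_cls == "PB-local") {
      # global inhibition across all PB glomeruli
      add_syn(nrn("PB-local"), nrn(post_cls), cc, spec, "PB")
    } else if (pre_cls == "Ring" && post_cls == "EB-LAL-PB") {
      add_syn(nrn("Ring"), nrn("EB-LAL-PB"), cc, spec, "EB")
    } else if (pre_cls == "EB-LAL-PB" && post_cls == "Ring") {
      add_syn(nrn("EB-LAL-PB"), nrn("Ring"), cc, spec, "EB")
    } else {
      stop("no wiring rule for connection class '", cc, "'")
    }
  }
  if (length(syn_rows) == 0L) return(empty_synapse_table())
  syn <- do.call(rbind, syn_rows)
  rownames(syn) <- NULL
  if (normalize) {
    # configured peaks are the total converging conductance per target and
    # connection class; per-synapse weight is the (relative-weight) share of
    # that total. This keeps the recurrent drive per sector uniform even
    # where the wedge and glomerulus grids tile 360 degrees with different
    # counts.
    key <- paste(syn$conn_class, syn$post, sep = "\r")
    tot <- tapply(syn$relw, key, sum)
    syn$g_bar <- syn$g_bar * syn$relw / as.numeric(tot[key])
  } else {
    syn$g_bar <- syn$g_bar * syn$relw
  }
  syn$relw <- NULL
  syn
}

build_circuit <- function(topology, cfg) {
  need <- switch(cfg$model,
                 A = ALL_CLASSES,
                 B = c(CORE_CLASSES, "PB-local"),
                 C = c(CORE_CLASSES, "Ring"),
                 names(cfg$counts))
  missing_counts <- setdiff(need, names(cfg$counts))
  if (length(missing_counts) > 0L) {
    stop("configuration error: missing per-class counts for: ",
         paste(missing_counts, collapse = ", "))
  }
  neurons <- make_neuron_table(topology, cfg$counts, cfg$lif, cfg$model)
  synapses <- wire_circuit(topology, neurons, cfg)
  circ <- new_circuit(topology, neurons, synapses, cfg$model, cfg)
  validate_circuit(circ)
  circ
}

#' Build circuit Model A
#'
#' The most complete architecture: all five cell classes. Columnar neurons
#' (EB-LAL-PB, PB-EB-LAL, PB-EB-NO) form the recurrent PB-EB loop following
#' the wedge-glomerulus map with a configurable azimuthal wedge offset for
#' the PB-EB-* axons; PB-local neurons provide global inhibition across all
#' PB glomeruli; ring neurons inhibit EB-LAL-PB dendrites in all wedges and
#' are driven visually through BU microglomeruli. Alpha synapses throughout;
#' stimulus enters as injected current.
#'
#' @param topology A [make_topology()] scaffold.
#' @param cfg Configuration list, see [default_config()].
#' @return A `cx_circuit`.
#' @export
build_model_A <- function(topology = make_topology(),
                          cfg = default_config("A")) {
  cfg$model <- "A"
  build_circuit(topology, cfg)
}

#' Build circuit Model B
#'
#' Classes: EB-LAL-PB, PB-EB-LAL, PB-EB-NO and PB-local (no ring neurons).
#' Alpha synapses are used in place of the source's PSC-based synapse, with
#' kinetics chosen to match its time-to-peak and peak (see
#' [alpha_params_for_peak()]). Stimulus enters as Poisson spike trains onto
#' EB-LAL-PB neurons.
#'
#' @inheritParams build_model_A
#' @return A `cx_circuit`.
#' @export
build_model_B <- function(topology = make_topology(),
                          cfg = default_config("B")) {
  cfg$model <- "B"
  build_circuit(topology, cfg)
}

#' Build circuit Model C
#'
#' Classes: EB-LAL-PB, PB-EB-LAL, PB-EB-NO and three ring-neuron subtypes
#' (no PB-local neurons). The PB-EB-LAL/EB-LAL-PB loop uses NMDA synapses
#' (persistent bump); AMPA/GABA-A exponential synapses elsewhere. PB-EB-NO
#' neurons are built but disabled by default, matching the comparison
#' condition in which the darkness bump-shift pathway is switched off.
#' Stimulus enters as Poisson spike trains onto the glomerulus pairs of the
#' stimulated wedges.
#'
#' @inheritParams build_model_A
#' @return A `cx_circuit`.
#' @export
build_model_C <- function(topology = make_topology(),
                          cfg = default_config("C")) {
  cfg$model <- "C"
  build_circuit(topology, cfg)
}

#' Validate a circuit against its structural invariants
#'
#' Checks id uniqueness, synapse endpoint existence, the PB/EB-only synapse
#' constraint, and per-class innervation constraints. Called by all builders;
#' errors on the first violation.
#'
#' @param circuit A `cx_circuit`.
#' @return The circuit, invisibly.
#' @export
validate_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "cx_circuit"))
  n <- circuit$neurons; s <- circuit$synapses
  if (anyDuplicated(n$id)) stop("duplicate neuron ids")
  if (nrow(s) > 0L) {
    bad <- setdiff(c(s$pre, s$post), n$id)
    if (length(bad) > 0L) stop("synapse references missing neuron(s): ",
                               paste(utils::head(bad, 5), collapse = ", "))
    if (!all(s$region %in% c("PB", "EB")))
      stop("only synapses within PB and EB are allowed")
    inh <- s$sign == "inh"
    if (any(inh)) {
      v0 <- n$V0[match(s$post[inh], n$id)]
      if (!all(s$reversal[inh] < v0))
        stop("inhibitory synapses must have reversal below the resting ",
             "potential of the postsynaptic neuron")
    }
  }
  ok <- (n$cell_class == "EB-LAL-PB" & n$dend_region == "EB" & !is.na(n$wedge)) |
        (n$cell_class %in% c("PB-EB-LAL", "PB-EB-NO", "PB-local") &
           n$dend_region == "PB" & !is.na(n$glom)) |
        (n$cell_class == "Ring" & n$dend_region %in% c("BU", "EB"))
  if (!all(ok)) stop("innervation constraints violated for: ",
                     paste(utils::head(n$id[!ok], 5), collapse = ", "))
  invisible(circuit)
}

#' Extract the core PB-EB subcircuit
#'
#' Keeps only the three core cell classes (PB-EB-LAL, PB-EB-NO, EB-LAL-PB)
#' and the synapses among them. Idempotent.
#'
#' @param model A `cx_circuit`.
#' @return A `cx_circuit`.
#' @export
core_subcircuit <- function(model) {
  stopifnot(inherits(model, "cx_circuit"))
  keep <- model$neurons$cell_class %in% CORE_CLASSES
  neurons <- model$neurons[keep, , drop = FALSE]
  syn <- model$synapses
  syn <- syn[syn$pre %in% neurons$id & syn$post %in% neurons$id, ,
             drop = FALSE]
  rownames(neurons) <- NULL; rownames(syn) <- NULL
  out <- new_circuit(model$topology, neurons, syn,
                     paste0(model$label, "-core"), model$config)
  validate_circuit(out)
  out
}

match_selector <- function(model, selector) {
  if (length(selector) == 0L) return(character())
  hits <- character()
  unmatched <- character()
  for (sel in selector) {
    if (sel %in% model$neurons$id) {
      hits <- c(hits, sel)
    } else if (sel %in% model$neurons$cell_class) {
      hits <- c(hits, model$neurons$id[model$neurons$cell_class == sel])
    } else if (sel %in% model$neurons$subtype) {
      hits <- c(hits, model$neurons$id[!is.na(model$neurons$subtype) &
                                         model$neurons$subtype == sel])
    } else {
      unmatched <- c(unmatched, sel)
    }
  }
  if (length(unmatched) > 0L) {
    stop("selector matched no neuron id, cell class or subtype: ",
         paste(unmatched, collapse = ", "))
  }
  unique(hits)
}

#' Silence (ablate) neurons
#'
#' Marks the selected neurons as disabled: during simulation they emit no
#' spikes and their outgoing synapses contribute no current. The graph is
#' unchanged; the operation is reversed by [unsilence()].
#'
#' @param model A `cx_circuit`.
#' @param selector Character vector of neuron ids, cell-class names, or ring
#'   subtypes (`"r1".."r3"`); may be empty.
#' @return The modified circuit.
#' @export
silence <- function(model, selector) {
  stopifnot(inherits(model, "cx_circuit"))
  ids <- match_selector(model, selector)
  model$neurons$enabled[model$neurons$id %in% ids] <- FALSE
  model
}

#' @rdname silence
#' @export
unsilence <- function(model, selector) {
  stopifnot(inherits(model, "cx_circuit"))
  ids <- match_selector(model, selector)
  model$neurons$enabled[model$neurons$id %in% ids] <- TRUE
  model
}

#' Connectivity matrix of a circuit
#'
#' Entry `(i, j)` is the number of synapses (or the summed peak-conductance
#' weight) from neuron `i` to neuron `j`.
#'
#' @param model A `cx_circuit`.
#' @param weighted If `TRUE`, sum `g_bar` weights instead of counting.
#' @param exclude_disabled If `TRUE`, rows/columns of disabled neurons are
#'   dropped.
#' @return A square numeric matrix with neuron ids as dimnames.
#' @export
connectivity_matrix <- function(model, weighted = FALSE,
                                exclude_disabled = FALSE) {
  stopifnot(inherits(model, "cx_circuit"))
  n <- model$neurons
  if (exclude_disabled) n <- n[n$enabled, , drop = FALSE]
  ids <- n$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  s <- model$synapses
  s <- s[s$pre %in% ids & s$post %in% ids, , drop = FALSE]
  if (nrow(s) > 0L) {
    i <- match(s$pre, ids); j <- match(s$post, ids)
    val <- if (weighted) s$g_bar else rep(1, nrow(s))
    for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + val[k]
  }
  m
}

#' Miniature rotation-symmetric test circuit
#'
#' Builds a toy ring with one neuron per requested class per sector on an
#' aligned scaffold (`n_glomeruli == n_wedges`, so wedge and per-hemisphere
#' glomerulus grids coincide), default parameters, and the standard wiring
#' rules restricted to the requested classes. Intended for oracle-scale
#' engine tests.
#'
#' @param n_wedges Number of wedges (>= 2).
#' @param classes Cell classes to include.
#' @param model_like Which model's default parameters to use (`"A"/"B"/"C"`).
#' @param n_glomeruli Optional glomerulus count (defaults to `n_wedges`,
#'   rounded up to even, giving one neuron per class per sector).
#' @return List with elements `circuit` and `config`.
#' @export
make_toy_ring <- function(n_wedges = 4L,
                          classes = CORE_CLASSES,
                          model_like = "B",
                          n_glomeruli = NULL) {
  stopifnot(n_wedges >= 2)
  cfg <- default_config(model_like)
  n_glom <- if (is.null(n_glomeruli)) {
    as.integer(n_wedges + n_wedges %% 2)
  } else {
    as.integer(n_glomeruli)
  }
  cfg$topology <- list(n_wedges = as.integer(n_wedges), n_glomeruli = n_glom)
  cfg$counts <- cfg$counts[names(cfg$counts) %in% classes]
  for (cls in setdiff(classes, names(cfg$counts))) cfg$counts[[cls]] <- 1L
  cfg$lif <- cfg$lif[names(cfg$lif) %in% classes]
  for (cls in setdiff(classes, names(cfg$lif))) {
    cfg$lif[[cls]] <- lif_params(t_ref = 2e-3)
  }
  keep_syn <- vapply(names(cfg$synapses), function(cc) {
    halves <- strsplit(cc, "->", fixed = TRUE)[[1]]
    halves[1] != "input" && all(halves %in% classes)
  }, logical(1))
  cfg$synapses <- cfg$synapses[keep_syn]
  topo <- make_topology(cfg$topology$n_wedges, cfg$topology$n_glomeruli)
  neurons <- make_neuron_table(topo, cfg$counts, cfg$lif, cfg$model)
  synapses <- wire_circuit(topo, neurons, cfg)
  circ <- new_circuit(topo, neurons, synapses, "custom", cfg)
  validate_circuit(circ)
  list(circuit = circ, config = cfg)
}
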