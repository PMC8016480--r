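#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, validates it against the documented
#' schema (unknown keys are rejected with their path), fills in every
#' default from [default_config()] for the chosen model, and checks basic
#' invariants (positive `dt`, valid model tag, valid brightness).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated configuration list (class `cx_run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$model)) stop("config error at 'model': key required")
  if (!raw$model %in% c("A", "B", "C")) {
    stop("config error at 'model': unknown tag '", raw$model,
         "'; valid tags: A, B, C")
  }
  defaults <- default_config(raw$model)
  check_keys <- function(user, def, path_) {
    if (!is.list(user) || !is.list(def)) return(invisible())
    unknown <- setdiff(names(user), c(names(def), ""))
    if (length(unknown) > 0L) {
      stop("config error at '", paste0(path_, unknown[1]),
           "': unknown key")
    }
    for (nm in names(user)) {
      if (is.list(user[[nm]]) && is.list(def[[nm]]) &&
          !nm %in% c("synapses", "counts", "lif")) {
        check_keys(user[[nm]], def[[nm]], paste0(path_, nm, "."))
      }
    }
  }
  check_keys(raw, defaults, "")
  cfg <- utils::modifyList(defaults, raw)
  validate_run_config(cfg)
  class(cfg) <- c("cx_run_config", class(cfg))
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$engine$dt) || cfg$engine$dt <= 0) {
    stop("config error at 'engine.dt': must be > 0")
  }
  if (cfg$engine$delay_steps < 1) {
    stop("config error at 'engine.delay_steps': must be >= 1")
  }
  pr <- cfg$protocol
  for (k in c("moving_brightness", "static_brightness")) {
    if (pr[[k]] < 0 || pr[[k]] > 1) {
      stop("config error at 'protocol.", k, "': must lie in [0, 1]")
    }
  }
  if (pr$duration <= 0) stop("config error at 'protocol.duration': must be > 0")
  invisible(cfg)
}

#' Save a configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  cls <- class(cfg); class(cfg) <- "list"
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Serialize a circuit to JSON
#'
#' Canonical schema-versioned document holding the topology, the neuron
#' table and the synapse table. Round-trips through
#' [circuit_from_json()].
#'
#' @param model A `cx_circuit`.
#' @param path Output path (`.json`).
#' @export
circuit_to_json <- function(model, path) {
  stopifnot(inherits(model, "cx_circuit"))
  doc <- list(
    schema = "cxsim-circuit/1",
    label = model$label,
    topology = list(n_wedges = model$topology$n_wedges,
                    n_glomeruli = model$topology$n_glomeruli),
    neurons = model$neurons,
    synapses = model$synapses)
  jsonlite::write_json(doc, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname circuit_to_json
#' @export
circuit_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != "cxsim-circuit/1") {
    stop("not a cxsim circuit document: ", path)
  }
  topo <- make_topology(doc$topology$n_wedges, doc$topology$n_glomeruli)
  neurons <- as.data.frame(doc$neurons, stringsAsFactors = FALSE)
  synapses <- if (length(doc$synapses) == 0L) empty_synapse_table() else
    as.data.frame(doc$synapses, stringsAsFactors = FALSE)
  circ <- new_circuit(topo, neurons, synapses, doc$label, NULL)
  validate_circuit(circ)
  circ
}

#' Export a circuit as GraphML
#'
#' Nodes carry `cell_class`, `region` and `enabled`; edges carry `kind`,
#' `sign` and `weight` (the conductance scaling).
#'
#' @param model A `cx_circuit`.
#' @param path Output path (`.graphml`).
#' @export
circuit_to_graphml <- function(model, path) {
  stopifnot(inherits(model, "cx_circuit"))
  n <- model$neurons; s <- model$synapses
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = s$pre, to = s$post, kind = s$kind, sign = s$sign,
                   weight = s$g_bar, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = n$id, cell_class = n$cell_class,
                          region = n$dend_region, enabled = n$enabled,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run a complete experiment from a configuration
#'
#' Builds the circuit, the visual protocol and the input drive, simulates,
#' analyses the bump, and writes `circuit.json`, `spikes.csv`, `rates.csv`,
#' `metrics.json` and `manifest.json` into `out_dir`. Identical
#' configuration and seed give byte-identical `spikes.csv`.
#'
#' @param cfg A configuration list ([default_config()] or [load_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (overrides `cfg$seed` if given).
#' @param silence_selector Optional selector passed to [silence()] before
#'   simulation (ablation experiments).
#' @return The manifest list, invisibly.
#' @export
run_experiment <- function(cfg, out_dir, seed = NULL,
                           silence_selector = NULL) {
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 0L else cfg$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "build"
  res <- tryCatch({
    topo <- make_topology(cfg$topology$n_wedges, cfg$topology$n_glomeruli)
    builder <- switch(cfg$model, A = build_model_A, B = build_model_B,
                      C = build_model_C,
                      stop("unknown model tag: ", cfg$model))
    model <- builder(topo, cfg)
    if (!is.null(silence_selector)) model <- silence(model, silence_selector)
    stage <- "stimulus"
    protocol <- make_usecase4_protocol(cfg$protocol)
    stage <- "encode"
    dt <- cfg$engine$dt
    drive <- switch(cfg$model,
                    A = encode_model_A(model, protocol, cfg$encoder, dt),
                    B = encode_model_B(model, protocol, cfg$encoder, dt),
                    C = encode_model_C(model, protocol, cfg$encoder, dt))
    stage <- "simulate"
    eng <- engine_config(dt = dt, delay_steps = cfg$engine$delay_steps,
                         coupling = cfg$engine$coupling)
    spikes <- simulate(model, drive, eng, seed = seed)
    stage <- "analyze"
    rates <- wedge_rates(spikes, model, cfg$analysis)
    metrics <- bump_metrics(rates, cfg$analysis$min_prominence)
    err <- tracking_error(metrics, protocol)
    horizon <- min(1.5, cfg$protocol$duration - cfg$protocol$t_static_end)
    pers <- if (horizon > 0) {
      persistence(rates, t_off = cfg$protocol$t_static_end,
                  horizon = horizon, threshold = 0.3,
                  min_prominence = cfg$analysis$min_prominence)
    } else {
      list(verdict = NA, ratio = NA_real_, single_bump_fraction = NA_real_)
    }
    list(model = model, protocol = protocol, spikes = spikes,
         rates = rates, metrics = metrics, err = err, pers = pers)
  }, error = function(e) {
    # remove partial outputs, then rethrow with the stage name
    for (f in c("circuit.json", "spikes.csv", "rates.csv", "metrics.json",
                "manifest.json")) {
      unlink(file.path(out_dir, f))
    }
    stop("experiment failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  circuit_to_json(res$model, file.path(out_dir, "circuit.json"))
  utils::write.csv(spikes_as_df(res$spikes),
                   file.path(out_dir, "spikes.csv"), row.names = FALSE)
  rates_df <- data.frame(time = res$rates$time, res$rates$rates)
  utils::write.csv(rates_df, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  metr <- list(
    persistence = res$pers,
    tracking_error_median_deg =
      stats::median(res$err$error_deg[res$err$time >= 5 &
                                        res$err$time <= 30], na.rm = TRUE),
    single_bump_fraction =
      mean(res$metrics$n_bumps[res$metrics$time >= 5 &
                                 res$metrics$time <= 30] == 1, na.rm = TRUE),
    mean_width_deg = mean(res$metrics$width, na.rm = TRUE))
  jsonlite::write_json(metr, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    schema = "cxsim-manifest/1",
    model = cfg$model,
    seed = seed,
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = c("circuit.json", "spikes.csv", "rates.csv", "metrics.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
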