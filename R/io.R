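# Configuration files (YAML), CSV/JSON writers, run manifests and the
# synthetic fixture generator.

.call_with <- function(fn, args) {
  if (is.null(args)) args <- list()
  do.call(fn, args[intersect(names(args), names(formals(fn)))])
}

#' Read a run configuration file
#'
#' Parses a YAML file with blocks `device`, `plasticity`, `network`,
#' `protocol` and `run`, mirroring the constructor arguments of
#' [memristor_params()], [plasticity_rule()], [network_config()] and
#' [make_protocol()], and builds the corresponding objects.  Missing
#' blocks or fields fall back to the package defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with `device`, `rule`, `network`, `protocol` and `run`
#'   (a list with `dt`, `seed`, `snapshot_every`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  device <- .call_with(memristor_params, raw$device)
  rule <- .call_with(plasticity_rule, raw$plasticity)

  net_args <- raw$network
  if (!is.null(net_args$lif_feature)) {
    net_args$lif_feature <- .call_with(lif_params, net_args$lif_feature)
  }
  if (!is.null(net_args$lif_conj)) {
    net_args$lif_conj <- .call_with(lif_params, net_args$lif_conj)
  }
  if (!is.null(net_args$init_weight_range)) {
    net_args$init_weight_range <- as.numeric(net_args$init_weight_range)
  }
  net_args$device <- device
  network <- .call_with(network_config, net_args)

  prot_args <- raw$protocol
  protocol <- NULL
  if (!is.null(prot_args)) {
    objects <- lapply(prot_args$objects, function(o) {
      feature_object(o$name, unlist(o$features))
    })
    cues <- lapply(prot_args$cues, function(cu) {
      partial_cue(cu$object, dims = unlist(cu$dims),
                  duration = cu$duration, amplitude = cu$amplitude)
    })
    prot_args$objects <- NULL
    prot_args$cues <- NULL
    protocol <- .call_with(
      function(init_time = 50, stim_dur = 100, rest_dur = 50,
               amplitude = 2) {
        make_protocol(objects, init_time = init_time, stim_dur = stim_dur,
                      rest_dur = rest_dur, amplitude = amplitude,
                      cues = cues)
      },
      prot_args
    )
  }
  run <- raw$run
  if (is.null(run)) run <- list()
  if (is.null(run$dt)) run$dt <- 0.1
  if (is.null(run$snapshot_every)) run$snapshot_every <- 5
  list(device = device, rule = rule, network = network,
       protocol = protocol, run = run)
}

#' Write CSV outputs of a simulation
#'
#' `write_spikes_csv` writes the raster (`neuron_id`, `name`, `kind`,
#' `t_ms`); `write_weights_csv` the weight snapshots (`t_ms`, `syn_id`,
#' `x`, `weight`, ...); `write_trace_csv` a pulse-train or sweep tibble.
#'
#' @param result A `wm_sim`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spikes_csv <- function(result, path) {
  utils::write.csv(result$spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
write_weights_csv <- function(result, path) {
  utils::write.csv(result$weights, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param trace A tibble (e.g. from [run_pulse_train()] or [iv_sweep()]).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Write the machine-readable experiment report
#'
#' JSON report with per-epoch states, winners, rates, mapping scores and
#' retrieval outcomes.
#'
#' @param experiment A `wm_experiment` from [run_experiment()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(experiment, path) {
  rep <- list(
    epochs = tidy(experiment),
    summary = glance(experiment),
    retrieval = lapply(experiment$retrieval, function(r) {
      list(target = r$target, target_conj = r$target_conj,
           success = r$success, reason = r$reason,
           epoch = r$epoch)
    }),
    seed = experiment$seed
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the full configuration and seed of a run so it can be
#' reproduced bit-identically.
#'
#' @param path Output file path.
#' @param config The raw configuration list (as read from YAML) or any
#'   serialisable description of the run inputs.
#' @param seed Integer seed used for the run.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, seed = NULL) {
  jsonlite::write_json(
    list(package = "memwm",
         version = as.character(utils::packageVersion("memwm")),
         seed = seed, config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  invisible(path)
}

#' Generate synthetic fixtures
#'
#' `"device_trace"`: a 100-pulse conductance trace simulated from known
#' parameters (optionally with cycle-to-cycle noise), for
#' parameter-recovery tests -- the noise-free trace is exactly
#' reproducible by [run_pulse_train()] under the same parameters.
#' `"protocol"`: the canonical three-object stimulus protocol with a
#' single-colour retrieval cue.
#'
#' @param kind `"device_trace"` or `"protocol"`.
#' @param params A [memristor_params()] for the trace fixture.
#' @param train A [pulse_train()] for the trace fixture.
#' @param noisy Add cycle-to-cycle noise to the trace?
#' @param seed Seed for the noisy trace.
#' @param dir Optional output directory; when given, files are written
#'   (`device_trace.csv` or `protocol.yaml`).
#' @return The fixture object (a trace tibble with attributes `params`
#'   and `train`, or a `wm_protocol`).
#' @export
gen_fixtures <- function(kind = c("device_trace", "protocol"),
                         params = memristor_params(),
                         train = pulse_train(), noisy = FALSE,
                         seed = 42, dir = NULL) {
  kind <- match.arg(kind)
  if (kind == "device_trace") {
    noise <- if (noisy) noise_spec(seed = seed) else NULL
    tr <- run_pulse_train(memristor_state(p = params), train, params,
                          noise = noise)
    attr(tr, "params") <- params
    attr(tr, "train") <- train
    if (!is.null(dir)) {
      write_trace_csv(tr, file.path(dir, "device_trace.csv"))
      write_manifest(file.path(dir, "device_trace_manifest.json"),
                     list(params = unclass(params),
                          train = unclass(train), noisy = noisy),
                     seed = if (noisy) seed else NULL)
    }
    tr
  } else {
    prot <- make_protocol(wm_objects(),
                          cues = list(partial_cue("Obj1", dims = 1)))
    if (!is.null(dir)) {
      yaml::write_yaml(
        list(protocol = list(
          init_time = prot$init_time, stim_dur = prot$stim_dur,
          rest_dur = prot$rest_dur, amplitude = prot$amplitude,
          objects = lapply(prot$objects, function(o) {
            list(name = o$name, features = as.list(o$features))
          }),
          cues = list(list(object = "Obj1", dims = list(1)))
        )),
        file.path(dir, "protocol.yaml")
      )
    }
    prot
  }
}
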