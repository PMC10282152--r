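# Stimulus protocols and analysis of the dual functional states of
# working memory: focused (sustained firing of one freely-conjunctive
# neuron) and unfocused (content held silently in synaptic weights).

#' An object as a tuple of features
#'
#' @param name Object label.
#' @param features Integer vector with exactly one feature index per
#'   dimension (1-based).
#' @return An object of class `feature_object`.
#' @export
feature_object <- function(name, features) {
  stopifnot("features must be positive indices" = all(features >= 1))
  structure(list(name = name, features = as.integer(features)),
            class = "feature_object")
}

#' Canonical feature labels for the three-dimensional task
#'
#' Three dimensions (colour, orientation, location) with three features
#' each.
#' @return A named list of character vectors.
#' @export
wm_feature_names <- function() {
  list(color = c("red", "yellow", "blue"),
       orientation = c("-45deg", "0deg", "+45deg"),
       location = c("bottom-left", "top-left", "top-right"))
}

#' The three canonical objects of the reference experiment
#'
#' Obj1 (red, -45 degrees, bottom-left), Obj2 (yellow, 0 degrees,
#' top-left), Obj3 (blue, +45 degrees, top-right).
#' @return A list of [feature_object()]s.
#' @export
wm_objects <- function() {
  list(feature_object("Obj1", c(1, 1, 1)),
       feature_object("Obj2", c(2, 2, 2)),
       feature_object("Obj3", c(3, 3, 3)))
}

#' Partial retrieval cue
#'
#' A cue delivering sensory current to a subset of an object's features
#' (e.g. only its colour), used to probe activity-silent retrieval.
#'
#' @param object Name of the target object.
#' @param dims Indices of the dimensions included in the cue.
#' @param duration Cue duration (ms); `NULL` to inherit the protocol's
#'   stimulus duration.
#' @param amplitude Cue current; `NULL` scales the protocol amplitude so
#'   the cue delivers the same total sensory current as a full object
#'   (`amplitude * n_dims / n_cued` per cued neuron): a single-feature
#'   probe is a concentrated, salient input, not a proportionally weaker
#'   one.
#' @return An object of class `partial_cue`.
#' @export
partial_cue <- function(object, dims = 1, duration = NULL,
                        amplitude = NULL) {
  structure(list(object = object, dims = as.integer(dims),
                 duration = duration, amplitude = amplitude),
            class = "partial_cue")
}

#' Lay out a stimulus protocol on a timeline
#'
#' Sequence: an initialisation (settling) period, then each object
#' presented for `stim_dur` followed by `rest_dur` of rest, then any
#' partial cues, each followed by `rest_dur`.  Sensory current of
#' `amplitude` is delivered to exactly one feature-selective neuron per
#' stimulated dimension.
#'
#' @param objects List of [feature_object()]s, in presentation order.
#' @param init_time Settling period before the first stimulus (ms).
#' @param stim_dur Per-object stimulus duration (ms).
#' @param rest_dur Rest period after each stimulus or cue (ms).
#' @param amplitude Sensory current per stimulated feature neuron
#'   (threshold units).
#' @param cues List of [partial_cue()]s appended after the last rest.
#' @return An object of class `wm_protocol`: a list with `objects`,
#'   `events` (tibble: `label`, `type`, `object`, `onset`, `offset`,
#'   `amplitude`, `targets` list-column of `(dim, feature)` tibbles),
#'   timing fields and `duration`.
#' @examples
#' prot <- make_protocol(wm_objects(), cues = list(partial_cue("Obj1")))
#' prot$events[, c("label", "type", "onset", "offset")]
#' @export
make_protocol <- function(objects, init_time = 50, stim_dur = 100,
                          rest_dur = 50, amplitude = 1.5, cues = list()) {
  stopifnot(
    "objects must be feature_object()s" =
      all(vapply(objects, inherits, logical(1), "feature_object")),
    "cues must be partial_cue()s" =
      all(vapply(cues, inherits, logical(1), "partial_cue")),
    init_time >= 0, stim_dur > 0, rest_dur >= 0
  )
  names(objects) <- vapply(objects, `[[`, character(1), "name")
  cursor <- init_time
  rows <- list()
  for (ob in objects) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = paste0("stim:", ob$name), type = "stim", object = ob$name,
      onset = cursor, offset = cursor + stim_dur, amplitude = amplitude,
      targets = list(tibble::tibble(dim = seq_along(ob$features),
                                    feature = ob$features))
    )
    cursor <- cursor + stim_dur + rest_dur
  }
  for (cu in cues) {
    ob <- objects[[cu$object]]
    if (is.null(ob)) {
      stop("cue refers to unknown object '", cu$object, "'", call. = FALSE)
    }
    dur <- if (is.null(cu$duration)) stim_dur else cu$duration
    amp <- if (is.null(cu$amplitude)) {
      amplitude * length(ob$features) / length(cu$dims)
    } else {
      cu$amplitude
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = paste0("cue:", ob$name), type = "cue", object = ob$name,
      onset = cursor, offset = cursor + dur, amplitude = amp,
      targets = list(tibble::tibble(dim = cu$dims,
                                    feature = ob$features[cu$dims]))
    )
    cursor <- cursor + dur + rest_dur
  }
  events <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(label = character(), type = character(),
                   object = character(), onset = numeric(),
                   offset = numeric(), amplitude = numeric(),
                   targets = list())
  if (nrow(events) > 1 &&
      any(events$onset[-1] < events$offset[-nrow(events)])) {
    stop("protocol events overlap", call. = FALSE)
  }
  structure(list(objects = objects, events = events,
                 init_time = init_time, stim_dur = stim_dur,
                 rest_dur = rest_dur, amplitude = amplitude,
                 duration = cursor),
            class = "wm_protocol")
}

#' Total duration of a protocol (ms)
#' @param protocol A `wm_protocol`.
#' @export
protocol_duration <- function(protocol) protocol$duration

# External current matrix, neurons x steps; t of column k is k * dt.
.protocol_ext_matrix <- function(protocol, net, dt, steps) {
  n <- nrow(net$neurons)
  ext <- matrix(0, n, steps)
  for (i in seq_len(nrow(protocol$events))) {
    ev <- protocol$events[i, ]
    from <- floor(ev$onset / dt) + 1L
    to <- min(floor(ev$offset / dt), steps)
    if (to < from) next
    tg <- ev$targets[[1]]
    ids <- feature_neuron_id(net, tg$dim, tg$feature)
    ext[ids, from:to] <- ext[ids, from:to] + ev$amplitude
  }
  ext
}

#' Per-neuron firing rates in a time window
#'
#' Spike count divided by window length, per neuron (no smoothing).
#'
#' @param result A `wm_sim` from [run_simulation()].
#' @param window Numeric `c(from, to)` in ms, non-empty and within the
#'   run.
#' @return A tibble with `neuron_id`, `name`, `kind`, `n_spikes`,
#'   `rate_hz` for every neuron in the network.
#' @export
firing_rates <- function(result, window) {
  stopifnot(inherits(result, "wm_sim"), length(window) == 2)
  if (!(window[2] > window[1]) || window[1] < 0 ||
      window[2] > result$duration + 1e-9) {
    stop("window must be a non-empty interval within the run", call. = FALSE)
  }
  counts <- result$spikes |>
    dplyr::filter(.data$t_ms > window[1], .data$t_ms <= window[2]) |>
    dplyr::count(.data$neuron_id, name = "n_spikes")
  result$net$neurons |>
    dplyr::select(neuron_id = "id", "name", "kind") |>
    dplyr::left_join(counts, by = "neuron_id") |>
    dplyr::mutate(
      n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
      rate_hz = .data$n_spikes / (window[2] - window[1]) * 1000
    )
}

# Latest plastic-weight snapshot at or before time `at`.
.weights_at <- function(result, at = NULL) {
  w <- result$weights
  if (is.null(at)) at <- max(w$t_ms)
  ts <- unique(w$t_ms)
  ts <- ts[ts <= at + 1e-9]
  if (!length(ts)) ts <- min(w$t_ms)
  w[w$t_ms == max(ts), , drop = FALSE]
}

#' Object-to-neuron mapping scores
#'
#' For each object, the mean forward (feature-to-conjunctive) weight from
#' the object's feature neurons onto each conjunctive neuron; the mapped
#' neuron is the one receiving the largest mean weight and the mapping
#' score is its margin over the best competitor.
#'
#' @param result A `wm_sim`.
#' @param objects List of [feature_object()]s; defaults to the protocol's
#'   objects.
#' @param at Time (ms) at which weights are read (latest snapshot at or
#'   before `at`); default end of run.
#' @return A tibble with `object`, `conj_id`, `conj_name`, `mean_w` for
#'   every object x conjunctive neuron, plus `is_winner` and the
#'   per-object `score` (winner margin).
#' @export
mapping_scores <- function(result, objects = NULL, at = NULL) {
  stopifnot(inherits(result, "wm_sim"))
  if (is.null(objects)) objects <- result$protocol$objects
  w <- .weights_at(result, at)
  w <- w[w$kind == "feature_to_conj", , drop = FALSE]
  conj <- result$net$neurons[result$net$neurons$kind == "conjunctive", ]
  purrr::map_dfr(objects, function(ob) {
    ids <- feature_neuron_id(result$net, seq_along(ob$features),
                             ob$features)
    ws <- w[w$pre %in% ids, , drop = FALSE]
    means <- ws |>
      dplyr::group_by(conj_id = .data$post) |>
      dplyr::summarise(mean_w = mean(.data$x), .groups = "drop")
    best <- order(means$mean_w, decreasing = TRUE)
    score <- if (nrow(means) > 1) {
      means$mean_w[best[1]] - means$mean_w[best[2]]
    } else {
      means$mean_w[best[1]]
    }
    means |>
      dplyr::mutate(
        object = ob$name,
        conj_name = conj$name[match(.data$conj_id, conj$id)],
        is_winner = dplyr::row_number() == best[1],
        score = score
      ) |>
      dplyr::select("object", "conj_id", "conj_name", "mean_w",
                    "is_winner", "score")
  })
}

#' Classify the working-memory state in an epoch
#'
#' Focused: exactly one conjunctive neuron's firing rate in the
#' (stimulus-free) epoch exceeds `rate_min`.  Unfocused: no conjunctive
#' neuron is active, yet the mapping score of some already-encoded object
#' exceeds `contrast_min` -- the content survives only in the weights.
#' None: neither.
#'
#' @param result A `wm_sim`.
#' @param epoch Numeric `c(from, to)` (ms).
#' @param objects Candidate stored objects; defaults to the protocol
#'   objects whose stimulus ended before the epoch starts.
#' @param rate_min Sustained-firing criterion (Hz).
#' @param contrast_min Mapping-score criterion (normalised weight units).
#' @return An object of class `wm_state_report`: `epoch`, `state`
#'   (`"focused"`, `"unfocused"` or `"none"`), `winner` (conjunctive
#'   neuron name or `NA`), `rates` (conjunctive rates tibble) and
#'   `mapping` (tibble from [mapping_scores()] at the epoch end).
#' @export
classify_state <- function(result, epoch, objects = NULL,
                           rate_min = 20, contrast_min = 0.1) {
  stopifnot(inherits(result, "wm_sim"))
  if (is.null(objects)) {
    ev <- result$protocol$events
    done <- ev$object[ev$type == "stim" & ev$offset <= epoch[1]]
    objects <- result$protocol$objects[names(result$protocol$objects)
                                       %in% done]
  }
  rates <- firing_rates(result, epoch) |>
    dplyr::filter(.data$kind == "conjunctive")
  active <- rates$rate_hz > rate_min
  mapping <- if (length(objects)) {
    mapping_scores(result, objects, at = epoch[2])
  } else {
    NULL
  }
  if (sum(active) == 1) {
    state <- "focused"
    winner <- rates$name[active]
  } else if (sum(active) == 0 && !is.null(mapping) &&
             any(mapping$score[mapping$is_winner] > contrast_min)) {
    state <- "unfocused"
    winner <- NA_character_
  } else {
    state <- "none"
    winner <- NA_character_
  }
  structure(list(epoch = epoch, state = state, winner = winner,
                 rates = rates, mapping = mapping,
                 rate_min = rate_min, contrast_min = contrast_min),
            class = "wm_state_report")
}

#' @export
print.wm_state_report <- function(x, ...) {
  cat(sprintf("<wm_state_report> [%g, %g] ms: %s%s\n",
              x$epoch[1], x$epoch[2], x$state,
              if (!is.na(x$winner)) paste0(", winner ", x$winner) else ""))
  print(x$rates[, c("name", "rate_hz")])
  if (!is.null(x$mapping)) {
    print(dplyr::filter(x$mapping, .data$is_winner))
  }
  invisible(x)
}

#' Score cued retrieval of a stored object
#'
#' Retrieval succeeds when, after the cue onset, the conjunctive neuron
#' mapped to the target (from the weights immediately before the cue)
#' re-enters the focused state -- it alone fires above `rate_min` -- and
#' the target's non-cued feature-selective neurons, which receive no
#' external drive, fire above `baseline_hz` (associative pattern
#' completion).
#'
#' @param result A `wm_sim`.
#' @param cue A cue event row of `result$protocol$events` (or its label).
#' @param target The target [feature_object()].
#' @param epoch Scoring interval (ms); default from cue onset + 20 ms to
#'   cue offset.
#' @param rate_min Focused-firing criterion (Hz).
#' @param baseline_hz Reactivation criterion for non-cued features (Hz).
#' @return An object of class `wm_retrieval`: `success` (logical),
#'   `reason`, `target`, `target_conj`, `rates` and `epoch`.
#' @export
score_retrieval <- function(result, cue, target, epoch = NULL,
                            rate_min = 20, baseline_hz = 5) {
  stopifnot(inherits(result, "wm_sim"),
            inherits(target, "feature_object"))
  ev <- result$protocol$events
  if (is.character(cue)) cue <- ev[ev$label == cue, ]
  stopifnot("cue not found in protocol" = nrow(cue) == 1)
  if (is.null(epoch)) epoch <- c(cue$onset + 20, cue$offset)

  encoded <- any(ev$type == "stim" & ev$object == target$name &
                   ev$offset <= cue$onset)
  if (!encoded) {
    return(structure(list(success = FALSE,
                          reason = "target never encoded",
                          target = target$name,
                          target_conj = NA_character_,
                          rates = NULL, epoch = epoch),
                     class = "wm_retrieval"))
  }
  map_pre <- mapping_scores(result, list(target), at = cue$onset - 1e-6)
  target_conj <- map_pre$conj_name[map_pre$is_winner]
  target_id <- map_pre$conj_id[map_pre$is_winner]

  rates <- firing_rates(result, epoch)
  conj <- rates[rates$kind == "conjunctive", ]
  refocused <- conj$rate_hz[conj$neuron_id == target_id] > rate_min &&
    sum(conj$rate_hz > rate_min) == 1

  cued <- cue$targets[[1]]
  all_ids <- feature_neuron_id(result$net, seq_along(target$features),
                               target$features)
  cued_ids <- feature_neuron_id(result$net, cued$dim, cued$feature)
  noncued_ids <- setdiff(all_ids, cued_ids)
  completed <- length(noncued_ids) == 0 ||
    all(rates$rate_hz[match(noncued_ids, rates$neuron_id)] > baseline_hz)

  success <- refocused && completed
  reason <- if (success) {
    "target neuron refocused and non-cued features reactivated"
  } else if (!refocused) {
    "target conjunctive neuron did not re-enter the focused state"
  } else {
    "non-cued feature neurons were not reactivated"
  }
  structure(list(success = success, reason = reason,
                 target = target$name, target_conj = target_conj,
                 rates = rates, epoch = epoch),
            class = "wm_retrieval")
}

#' @export
print.wm_retrieval <- function(x, ...) {
  cat(sprintf("<wm_retrieval> %s: %s (%s)\n", x$target,
              if (x$success) "SUCCESS" else "FAILURE", x$reason))
  invisible(x)
}

#' Run the full encoding / attention / retrieval experiment
#'
#' End-to-end orchestration: build the network, run the protocol
#' (defaults to the three-object presentation followed by a single-colour
#' partial cue of the first object), classify the working-memory state in
#' every post-stimulus rest epoch and in the pre-cue epoch, and score
#' every cued retrieval.
#'
#' @param cfg A [network_config()]; its seed is overridden by `seed`.
#' @param protocol A [make_protocol()] protocol, or `NULL` for the
#'   default experiment.
#' @param rule A [plasticity_rule()].
#' @param seed Integer seed controlling the random initial weights.
#' @param dt Simulation step (ms).
#' @param rate_min,contrast_min,baseline_hz Classification thresholds,
#'   see [classify_state()] and [score_retrieval()].
#' @param settle Delay (ms) after stimulus offset before the rate window
#'   opens, letting stimulus-locked transients die out.
#' @param rate_window Length (ms) of the post-offset window over which
#'   sustained firing is judged.  The focused state is an attractor that
#'   decays as its synapses depress, so it is assessed over a short
#'   window right after offset rather than over the whole rest period.
#' @return An object of class `wm_experiment`: `sim`, `reports` (named
#'   list of [classify_state()] reports per epoch), `retrieval` (list of
#'   [score_retrieval()] outcomes), `protocol` and `config`.
#'   `tidy()` returns the per-epoch table, `glance()` a one-row summary.
#' @examples
#' \donttest{
#' ex <- run_experiment(seed = 1)
#' tidy(ex)
#' glance(ex)
#' }
#' @export
run_experiment <- function(cfg = network_config(), protocol = NULL,
                           rule = plasticity_rule(), seed = 1,
                           dt = 0.1, rate_min = 20, contrast_min = 0.1,
                           baseline_hz = 5, settle = 5,
                           rate_window = 30) {
  if (is.null(protocol)) {
    protocol <- make_protocol(wm_objects(),
                              cues = list(partial_cue("Obj1", dims = 1)))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  net <- build_network(cfg)
  sim <- run_simulation(net, protocol, dt = dt, rule = rule)

  ev <- protocol$events
  reports <- list()
  for (i in which(ev$type == "stim")) {
    epoch <- c(ev$offset[i] + settle, ev$offset[i] + settle + rate_window)
    reports[[paste0("post-", ev$object[i])]] <-
      classify_state(sim, epoch, rate_min = rate_min,
                     contrast_min = contrast_min)
  }
  cue_rows <- which(ev$type == "cue")
  if (length(cue_rows)) {
    pre <- c(ev$onset[cue_rows[1]] - 40, ev$onset[cue_rows[1]])
    reports[["pre-cue"]] <- classify_state(sim, pre, rate_min = rate_min,
                                           contrast_min = contrast_min)
  }
  retrieval <- lapply(cue_rows, function(i) {
    score_retrieval(sim, ev[i, ], protocol$objects[[ev$object[i]]],
                    rate_min = rate_min, baseline_hz = baseline_hz)
  })
  names(retrieval) <- ev$label[cue_rows]

  structure(list(sim = sim, reports = reports, retrieval = retrieval,
                 protocol = protocol, config = cfg, seed = seed,
                 rate_min = rate_min, contrast_min = contrast_min),
            class = "wm_experiment")
}

#' @rdname run_experiment
#' @param x A `wm_experiment`.
#' @param ... Unused.
#' @method tidy wm_experiment
#' @export
tidy.wm_experiment <- function(x, ...) {
  purrr::imap_dfr(x$reports, function(rep, label) {
    top <- rep$rates[which.max(rep$rates$rate_hz), ]
    best_map <- if (!is.null(rep$mapping)) {
      m <- dplyr::filter(rep$mapping, .data$is_winner)
      m[which.max(m$score), ]
    } else {
      NULL
    }
    tibble::tibble(
      epoch = label,
      t_from = rep$epoch[1], t_to = rep$epoch[2],
      state = rep$state, winner = rep$winner,
      top_rate_hz = top$rate_hz, top_neuron = top$name,
      best_mapped_object = if (is.null(best_map)) NA_character_ else
        best_map$object,
      best_mapping_score = if (is.null(best_map)) NA_real_ else
        best_map$score
    )
  })
}

#' @rdname run_experiment
#' @method glance wm_experiment
#' @export
glance.wm_experiment <- function(x, ...) {
  post <- x$reports[grepl("^post-", names(x$reports))]
  winners <- vapply(post, `[[`, character(1), "winner")
  tibble::tibble(
    n_spikes = nrow(x$sim$spikes),
    n_epochs = length(post),
    n_focused = sum(vapply(post, `[[`, character(1), "state") == "focused"),
    n_distinct_winners = dplyr::n_distinct(winners[!is.na(winners)]),
    retrieval_success = if (length(x$retrieval)) {
      mean(vapply(x$retrieval, `[[`, logical(1), "success"))
    } else {
      NA_real_
    }
  )
}
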