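# Spiking network: leaky integrate-and-fire neurons, memristive plastic
# synapses between feature-selective and freely-conjunctive neurons,
# fixed lateral-inhibition and self-excitation synapses, and the
# clock-driven simulation engine.

#' Leaky integrate-and-fire neuron parameters
#'
#' Normalised-potential LIF model: `dv/dt = (-(v - v_rest) +
#' (i_syn + i_ext) / c_m) / tau_m`, spike and reset at `v_thresh`.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential (normalised units).
#' @param v_thresh Firing threshold (must exceed `v_rest`).
#' @param v_reset Post-spike reset potential.
#' @param t_refract Absolute refractory period (ms).
#' @param c_m Membrane capacitance (normalised); currents are expressed in
#'   threshold units per membrane time constant.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, v_rest = 0, v_thresh = 1, v_reset = 0,
                       t_refract = 2, c_m = 1) {
  stopifnot(
    "v_thresh must be > v_rest" = v_thresh > v_rest,
    "tau_m must be > 0" = tau_m > 0,
    "t_refract must be >= 0" = t_refract >= 0,
    "c_m must be > 0" = c_m > 0
  )
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_refract = t_refract, c_m = c_m),
            class = "lif_params")
}

#' Single LIF integration step
#'
#' One explicit-Euler step of the membrane equation.  No integration
#' occurs during the refractory period; a spike resets the potential to
#' `v_reset` and opens a refractory window.
#'
#' @param n A list with fields `v`, `last_spike`, `refract_until`
#'   (a neuron state), e.g. `neuron_state()`.
#' @param i_syn,i_ext Synaptic and external input currents.
#' @param dt Step (ms, > 0).
#' @param p A [lif_params()] object.
#' @param t Current time (ms); defaults to `n$last_update + dt`.
#' @return A list `(state, spiked)`.
#' @export
lif_step <- function(n, i_syn, i_ext, dt, p, t = NULL) {
  stopifnot("dt must be > 0" = dt > 0)
  if (is.null(t)) t <- n$last_update + dt
  spiked <- FALSE
  if (t >= n$refract_until) {
    n$v <- n$v + dt * (-(n$v - p$v_rest) + (i_syn + i_ext) / p$c_m) / p$tau_m
    if (n$v >= p$v_thresh) {
      spiked <- TRUE
      n$v <- p$v_reset
      n$last_spike <- t
      n$refract_until <- t + p$t_refract
    }
  }
  n$last_update <- t
  list(state = n, spiked = spiked)
}

#' Fresh LIF neuron state
#' @param p A [lif_params()] object.
#' @return A neuron-state list for [lif_step()].
#' @export
neuron_state <- function(p = lif_params()) {
  list(v = p$v_rest, last_spike = -Inf, refract_until = -Inf,
       last_update = 0)
}

#' Working-memory network configuration
#'
#' Dimensions, neuron parameters, fixed weights and synaptic-current
#' parameters of the working-memory network.  Defaults instantiate the
#' reference experiment: 3 feature dimensions x 3 features, 3
#' freely-conjunctive neurons.
#'
#' @param n_dims Number of feature dimensions.
#' @param n_features_per_dim Features per dimension.
#' @param n_conj Number of freely-conjunctive neurons.
#' @param lif_feature,lif_conj [lif_params()] for the two neuron classes.
#' @param w_inhib Fixed lateral-inhibition weight (< 0).
#' @param w_selfexc Fixed self-excitation weight (> 0).
#' @param init_weight_range Interval in [0, 1] from which initial plastic
#'   states are drawn uniformly.
#' @param seed RNG seed for the initial plastic weights.
#' @param device [memristor_params()] shared by all plastic synapses.
#' @param psc_tau Default synaptic current decay time constant (ms).
#' @param psc_fc,psc_cf,psc_inhib,psc_selfexc Peak synaptic current per
#'   unit weight for feature-to-conjunctive, conjunctive-to-feature,
#'   lateral-inhibition and self-excitation synapses.
#' @param psc_tau_fc,psc_tau_cf,psc_tau_inhib,psc_tau_selfexc Per-kind
#'   current decay constants (ms); default `psc_tau`.  Short decays on
#'   the plastic synapses make transmission kick-like, which is what
#'   phase-locks post-synaptic firing into the LTP window; a slow
#'   inhibitory decay lets the winner suppress competitors between its
#'   spikes.
#' @param dim_names,feature_names Optional labels: a character vector of
#'   dimension names and a list of per-dimension feature labels.
#' @return An object of class `wm_config`.
#' @export
network_config <- function(n_dims = 3, n_features_per_dim = 3, n_conj = 3,
                           lif_feature = lif_params(tau_m = 5),
                           lif_conj = lif_params(tau_m = 5, t_refract = 4),
                           w_inhib = -1, w_selfexc = 1,
                           init_weight_range = c(0.1, 0.3),
                           seed = NULL,
                           device = memristor_params(),
                           psc_tau = 2,
                           psc_fc = 10, psc_cf = 20,
                           psc_inhib = 8, psc_selfexc = 0.5,
                           psc_tau_fc = psc_tau, psc_tau_cf = psc_tau,
                           psc_tau_inhib = 5, psc_tau_selfexc = 20,
                           dim_names = NULL, feature_names = NULL) {
  stopifnot(
    "counts must be >= 1" =
      n_dims >= 1 && n_features_per_dim >= 1 && n_conj >= 1,
    "init_weight_range must lie within [0, 1]" =
      length(init_weight_range) == 2 &&
      init_weight_range[1] <= init_weight_range[2] &&
      init_weight_range[1] >= 0 && init_weight_range[2] <= 1,
    "w_inhib must be < 0" = w_inhib < 0,
    "w_selfexc must be > 0" = w_selfexc > 0,
    "psc_tau must be > 0" = psc_tau > 0
  )
  if (is.null(dim_names)) dim_names <- paste0("dim", seq_len(n_dims))
  structure(list(
    n_dims = as.integer(n_dims),
    n_features_per_dim = as.integer(n_features_per_dim),
    n_conj = as.integer(n_conj),
    lif_feature = lif_feature, lif_conj = lif_conj,
    w_inhib = w_inhib, w_selfexc = w_selfexc,
    init_weight_range = init_weight_range,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    device = device, psc_tau = psc_tau,
    psc_fc = psc_fc, psc_cf = psc_cf,
    psc_inhib = psc_inhib, psc_selfexc = psc_selfexc,
    psc_tau_fc = psc_tau_fc, psc_tau_cf = psc_tau_cf,
    psc_tau_inhib = psc_tau_inhib, psc_tau_selfexc = psc_tau_selfexc,
    dim_names = dim_names, feature_names = feature_names
  ), class = "wm_config")
}

#' Neuron id of a feature-selective neuron
#' @param net A `wm_network` (or `wm_config`).
#' @param dim Feature dimension index.
#' @param feature Feature index within the dimension.
#' @return Integer neuron id.
#' @export
feature_neuron_id <- function(net, dim, feature) {
  cfg <- if (inherits(net, "wm_network")) net$config else net
  stopifnot(all(dim >= 1 & dim <= cfg$n_dims),
            all(feature >= 1 & feature <= cfg$n_features_per_dim))
  as.integer((dim - 1L) * cfg$n_features_per_dim + feature)
}

#' Build the working-memory network
#'
#' Creates `n_dims * n_features_per_dim` feature-selective neurons and
#' `n_conj` freely-conjunctive neurons; fully-bipartite plastic wiring in
#' both directions (forward feature-to-conjunctive and backward
#' conjunctive-to-feature synapses); all-pairs lateral inhibition among
#' the conjunctive neurons (no self-connections); and one self-excitatory
#' synapse per conjunctive neuron.  Initial plastic states are drawn
#' uniformly from `init_weight_range` under the configuration seed.
#'
#' @param cfg A [network_config()].
#' @return An object of class `wm_network`: a list with `config`,
#'   `neurons` (tibble: `id`, `name`, `kind`, `dim`, `feature`) and
#'   `synapses` (tibble: `syn_id`, `pre`, `post`, `kind`, `plastic`, `x`,
#'   `w_fixed`, `psc_amplitude`, `psc_tau`).
#' @examples
#' net <- build_network(network_config(seed = 1))
#' dplyr::count(net$synapses, kind)
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "wm_config"))
  n_feat <- cfg$n_dims * cfg$n_features_per_dim
  n <- n_feat + cfg$n_conj
  feat_grid <- expand.grid(feature = seq_len(cfg$n_features_per_dim),
                           dim = seq_len(cfg$n_dims))
  feat_label <- function(d, f) {
    if (!is.null(cfg$feature_names)) cfg$feature_names[[d]][f]
    else paste0(cfg$dim_names[d], ":", f)
  }
  neurons <- tibble::tibble(
    id = seq_len(n),
    kind = rep(c("feature", "conjunctive"), c(n_feat, cfg$n_conj)),
    dim = c(feat_grid$dim, rep(NA_integer_, cfg$n_conj)),
    feature = c(feat_grid$feature, rep(NA_integer_, cfg$n_conj)),
    name = c(mapply(feat_label, feat_grid$dim, feat_grid$feature),
             paste0("C", seq_len(cfg$n_conj)))
  )
  conj_ids <- n_feat + seq_len(cfg$n_conj)
  feat_ids <- seq_len(n_feat)

  fc <- expand.grid(pre = feat_ids, post = conj_ids)
  cf <- expand.grid(pre = conj_ids, post = feat_ids)
  inhib <- expand.grid(pre = conj_ids, post = conj_ids)
  inhib <- inhib[inhib$pre != inhib$post, , drop = FALSE]
  selfexc <- data.frame(pre = conj_ids, post = conj_ids)

  syn <- dplyr::bind_rows(
    dplyr::mutate(fc, kind = "feature_to_conj", plastic = TRUE,
                  w_fixed = NA_real_, psc_amplitude = cfg$psc_fc,
                  psc_tau = cfg$psc_tau_fc),
    dplyr::mutate(cf, kind = "conj_to_feature", plastic = TRUE,
                  w_fixed = NA_real_, psc_amplitude = cfg$psc_cf,
                  psc_tau = cfg$psc_tau_cf),
    dplyr::mutate(inhib, kind = "lateral_inhibition", plastic = FALSE,
                  w_fixed = cfg$w_inhib, psc_amplitude = cfg$psc_inhib,
                  psc_tau = cfg$psc_tau_inhib),
    dplyr::mutate(selfexc, kind = "self_excitation", plastic = FALSE,
                  w_fixed = cfg$w_selfexc, psc_amplitude = cfg$psc_selfexc,
                  psc_tau = cfg$psc_tau_selfexc)
  )
  n_plastic <- sum(syn$plastic)
  draw <- function() stats::runif(n_plastic, cfg$init_weight_range[1],
                                  cfg$init_weight_range[2])
  x0 <- if (is.null(cfg$seed)) draw() else withr::with_seed(cfg$seed, draw())
  syn$x <- NA_real_
  syn$x[syn$plastic] <- x0
  syn <- tibble::tibble(syn_id = seq_len(nrow(syn)),
                        tibble::as_tibble(syn))
  structure(list(config = cfg, neurons = neurons, synapses = syn),
            class = "wm_network")
}

#' @export
print.wm_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<wm_network> %d feature-selective (%d dims x %d) + %d conjunctive neurons\n",
              cfg$n_dims * cfg$n_features_per_dim, cfg$n_dims,
              cfg$n_features_per_dim, cfg$n_conj))
  print(dplyr::count(x$synapses, .data$kind, .data$plastic))
  invisible(x)
}

#' Remove synapses of a given kind
#'
#' Ablation helper for mechanism experiments, e.g. removing the
#' conjunctive-to-feature feedback to show that it is required for
#' sustained post-stimulus firing.
#'
#' @param net A `wm_network`.
#' @param kind Synapse kinds to remove.
#' @return The network without those synapses.
#' @export
ablate_synapses <- function(net, kind) {
  stopifnot(inherits(net, "wm_network"),
            all(kind %in% c("feature_to_conj", "conj_to_feature",
                            "lateral_inhibition", "self_excitation")))
  net$synapses <- net$synapses[!(net$synapses$kind %in% kind), , drop = FALSE]
  net
}

#' Run a clock-driven simulation of the working-memory network
#'
#' Advances all neurons on a fixed grid; spikes are propagated through
#' exponentially decaying synaptic current kernels scaled by the
#' normalised memristive weight (or the fixed weight); every
#' post-synaptic spike on a plastic synapse is judged against that
#' synapse's most recent pre-synaptic spike and the resulting LTP/LTD
#' decision is applied as a SET/RESET pulse on the synaptic memristor.
#' While a synapse is being programmed it does not transmit.  The run is
#' fully deterministic for a given network (randomness enters only via
#' the initial weights drawn in [build_network()]).
#'
#' @param net A `wm_network` from [build_network()].
#' @param protocol A `wm_protocol` from [make_protocol()].
#' @param dt Simulation step (ms); must not exceed the plasticity rule's
#'   `Tp` or LTP window, otherwise spike-timing decisions are
#'   unresolvable.
#' @param rule A [plasticity_rule()].
#' @param snapshot_every Interval (ms) between plastic-weight snapshots.
#' @param dt_pulse Euler sub-step (ms) for programming pulses.
#' @return An object of class `wm_sim`: a list with `spikes` (tibble:
#'   `neuron_id`, `name`, `kind`, `t_ms`), `weights` (tibble of
#'   snapshots: `t_ms`, `syn_id`, `kind`, `pre`, `post`, `x`, `weight`),
#'   `events` (tibble of plasticity events: `t_ms`, `syn_id`, `kind`,
#'   `dt_pair`), `net` (final network state), `protocol`, `rule`, `dt`
#'   and `duration`.
#' @export
run_simulation <- function(net, protocol, dt = 0.1,
                           rule = plasticity_rule(),
                           snapshot_every = 5, dt_pulse = 0.05) {
  stopifnot(inherits(net, "wm_network"), inherits(protocol, "wm_protocol"))
  if (dt > rule$Tp || dt > rule$window) {
    stop("dt (", dt, " ms) must not exceed the plasticity Tp (", rule$Tp,
         " ms) or LTP window (", rule$window,
         " ms): spike-timing rules would be unresolvable", call. = FALSE)
  }
  cfg <- net$config
  p <- cfg$device
  neurons <- net$neurons
  syn <- net$synapses
  n <- nrow(neurons)
  n_syn <- nrow(syn)
  duration <- protocol_duration(protocol)
  steps <- as.integer(ceiling(duration / dt))
  ext <- .protocol_ext_matrix(protocol, net, dt, steps)

  is_conj <- neurons$kind == "conjunctive"
  pick <- function(field) {
    ifelse(is_conj, cfg$lif_conj[[field]], cfg$lif_feature[[field]])
  }
  tau_m <- pick("tau_m"); v_rest <- pick("v_rest")
  v_thresh <- pick("v_thresh"); v_reset <- pick("v_reset")
  t_ref <- pick("t_refract"); c_m <- pick("c_m")

  pre <- syn$pre; post <- syn$post
  plastic <- syn$plastic
  amp <- syn$psc_amplitude
  w_fix <- syn$w_fixed
  x <- syn$x
  decay <- exp(-dt / syn$psc_tau)
  inc <- matrix(0, n, n_syn)
  inc[cbind(post, seq_len(n_syn))] <- 1
  out_syn <- split(seq_len(n_syn), factor(pre, levels = seq_len(n)))
  post_plastic <- split(which(plastic),
                        factor(post[plastic], levels = seq_len(n)))

  last_pre <- rep(-Inf, n_syn)
  blocked_until <- rep(-Inf, n_syn)
  i_psc <- numeric(n_syn)
  v <- v_rest
  refract_until <- rep(-Inf, n)

  cap <- 4096L
  sp_id <- integer(cap); sp_t <- numeric(cap); n_sp <- 0L
  ecap <- 4096L
  ev_t <- numeric(ecap); ev_syn <- integer(ecap)
  ev_kind <- character(ecap); ev_dt <- numeric(ecap); n_ev <- 0L

  set_width <- rule$set_width_factor * rule$Tp
  snap_k <- max(1L, as.integer(round(snapshot_every / dt)))
  plastic_idx <- which(plastic)
  snaps <- list(list(t = 0, x = x[plastic_idx]))

  for (step in seq_len(steps)) {
    t <- step * dt
    i_psc <- i_psc * decay
    i_in <- as.vector(inc %*% i_psc) + ext[, step]
    active <- t >= refract_until
    v[active] <- v[active] +
      dt * (-(v[active] - v_rest[active]) + i_in[active] / c_m[active]) /
      tau_m[active]
    spiked <- which(active & v >= v_thresh)
    for (j in spiked) {
      v[j] <- v_reset[j]
      refract_until[j] <- t + t_ref[j]
      n_sp <- n_sp + 1L
      if (n_sp > cap) {
        cap <- cap * 2L
        sp_id <- c(sp_id, integer(cap / 2L))
        sp_t <- c(sp_t, numeric(cap / 2L))
      }
      sp_id[n_sp] <- j; sp_t[n_sp] <- t

      # this spike as POST on plastic inputs: one decision per post spike
      for (s in post_plastic[[j]]) {
        lp <- last_pre[s]
        if (is.finite(lp)) {
          kd <- .classify_dt(t - lp, rule)
          if (kd != "NONE") {
            x[s] <- .apply_kind_x(x[s], kd, rule, p, dt_max = dt_pulse)
            blocked_until[s] <- t + if (kd == "LTP") set_width else rule$Tp
            n_ev <- n_ev + 1L
            if (n_ev > ecap) {
              ecap <- ecap * 2L
              ev_t <- c(ev_t, numeric(ecap / 2L))
              ev_syn <- c(ev_syn, integer(ecap / 2L))
              ev_kind <- c(ev_kind, character(ecap / 2L))
              ev_dt <- c(ev_dt, numeric(ecap / 2L))
            }
            ev_t[n_ev] <- t; ev_syn[n_ev] <- s
            ev_kind[n_ev] <- kd; ev_dt[n_ev] <- t - lp
          }
        }
      }

      # this spike as PRE: deliver current on unblocked synapses, then
      # update the pre-spike bookkeeping
      idx <- out_syn[[j]]
      if (length(idx)) {
        open <- idx[blocked_until[idx] <= t]
        if (length(open)) {
          w_eff <- ifelse(plastic[open], x[open], w_fix[open])
          i_psc[open] <- i_psc[open] + amp[open] * w_eff
        }
        pl <- idx[plastic[idx]]
        if (length(pl)) last_pre[pl] <- t
      }
    }
    if (step %% snap_k == 0L) {
      snaps[[length(snaps) + 1L]] <- list(t = t, x = x[plastic_idx])
    }
  }

  spikes <- tibble::tibble(neuron_id = sp_id[seq_len(n_sp)],
                           t_ms = sp_t[seq_len(n_sp)])
  spikes <- dplyr::left_join(
    spikes, dplyr::select(neurons, neuron_id = "id", "name", "kind"),
    by = "neuron_id"
  )
  syn_meta <- syn[plastic_idx, c("syn_id", "kind", "pre", "post")]
  weights <- purrr::map_dfr(snaps, function(sn) {
    tibble::tibble(t_ms = sn$t, syn_meta, x = sn$x,
                   weight = weight_of(sn$x, p))
  })
  events <- tibble::tibble(
    t_ms = ev_t[seq_len(n_ev)], syn_id = ev_syn[seq_len(n_ev)],
    kind = ev_kind[seq_len(n_ev)], dt_pair = ev_dt[seq_len(n_ev)]
  )
  net$synapses$x <- x
  structure(list(spikes = spikes, weights = weights, events = events,
                 net = net, protocol = protocol, rule = rule,
                 dt = dt, duration = duration),
            class = "wm_sim")
}

#' @export
print.wm_sim <- function(x, ...) {
  cat(sprintf("<wm_sim> %.0f ms, dt = %g ms: %d spikes, %d plasticity events (%d LTP / %d LTD)\n",
              x$duration, x$dt, nrow(x$spikes), nrow(x$events),
              sum(x$events$kind == "LTP"), sum(x$events$kind == "LTD")))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `wm_sim` object.
#' @param ... Unused.
#' @method tidy wm_sim
#' @export
tidy.wm_sim <- function(x, ...) x$spikes

#' @rdname run_simulation
#' @method glance wm_sim
#' @export
glance.wm_sim <- function(x, ...) {
  tibble::tibble(
    duration_ms = x$duration,
    n_spikes = nrow(x$spikes),
    n_ltp = sum(x$events$kind == "LTP"),
    n_ltd = sum(x$events$kind == "LTD"),
    programming_time_ms = sum(x$events$kind == "LTP") *
      x$rule$set_width_factor * x$rule$Tp +
      sum(x$events$kind == "LTD") * x$rule$Tp
  )
}
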