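# Simplified timing-window Hebbian rule.
#
# A causal pre->post spike pair inside a short window elicits LTP; any
# other qualifying pair (too late, or post before pre) elicits LTD.  Each
# decision is realised physically as a single programming pulse on the
# synapse's memristor: a positive SET pulse of width `set_width_factor *
# Tp` for LTP, a negative RESET pulse of width `Tp` for LTD.

#' Plasticity rule parameters
#'
#' @param window LTP time window (ms): a post-synaptic spike no more than
#'   `window` after a pre-synaptic spike potentiates the synapse.
#' @param Tp Pulse-width time scalar (ms): the RESET pulse width; the SET
#'   width is `set_width_factor * Tp`.
#' @param set_width_factor SET width as a multiple of the RESET width.
#' @param v_hat Polarity convention of the programming pulse: `+1` means
#'   SET pulses are positive and RESET pulses negative.
#' @param pulse_amplitude Programming voltage magnitude (V); must exceed
#'   the device thresholds to have any effect.
#' @param pairing_horizon Maximum pre-to-post separation (ms) for a pair
#'   to qualify; beyond it the pair is ignored.  Default `Inf`: every
#'   post-synaptic spike is judged against the most recent pre-synaptic
#'   spike, so a post-synaptic neuron firing without recent pre-synaptic
#'   drive depresses the synapse (heterosynaptic depression), which is
#'   what makes the winner's receptive field selective.
#' @return An object of class `plasticity_rule`.
#' @export
plasticity_rule <- function(window = 2, Tp = 1, set_width_factor = 3,
                            v_hat = 1, pulse_amplitude = 1.5,
                            pairing_horizon = Inf) {
  stopifnot(
    "window must be > 0" = window > 0,
    "Tp must be > 0" = Tp > 0,
    "set_width_factor must be > 0" = set_width_factor > 0,
    "v_hat must be +1 or -1" = v_hat %in% c(-1, 1),
    "pairing_horizon must be >= window" = pairing_horizon >= window
  )
  structure(list(window = window, Tp = Tp,
                 set_width_factor = set_width_factor,
                 v_hat = v_hat, pulse_amplitude = pulse_amplitude,
                 pairing_horizon = pairing_horizon),
            class = "plasticity_rule")
}

# Vectorised decision kernel on dt = t_post - t_pre.
.classify_dt <- function(dt, rule) {
  kind <- rep("LTD", length(dt))
  kind[dt > 0 & dt <= rule$window] <- "LTP"
  kind[abs(dt) > rule$pairing_horizon | !is.finite(dt)] <- "NONE"
  kind
}

#' Classify a pre/post spike pair
#'
#' Total partition of the pair interval `dt = t_post - t_pre`:
#' LTP iff `0 < dt <= window`; LTD iff `|dt| <= pairing_horizon` but the
#' pair is not in the LTP window (including post-before-pre and exactly
#' simultaneous spikes); NONE iff `|dt| > pairing_horizon`.
#'
#' @param t_pre,t_post Spike times (ms), finite.
#' @param rule A [plasticity_rule()].
#' @return An object of class `plasticity_decision`: a list with `kind`
#'   (`"LTP"`, `"LTD"` or `"NONE"`) and `dt_pair` (ms).
#' @examples
#' r <- plasticity_rule(pairing_horizon = 10)
#' classify_pair(10, 11, r)  # LTP
#' classify_pair(10, 9, r)   # LTD (post first)
#' classify_pair(10, 25, r)  # NONE (beyond horizon)
#' @export
classify_pair <- function(t_pre, t_post, rule) {
  stopifnot("spike times must be finite" =
              is.finite(t_pre) && is.finite(t_post))
  dt <- t_post - t_pre
  structure(list(kind = .classify_dt(dt, rule), dt_pair = dt),
            class = "plasticity_decision")
}

# Fast path used by the simulation engine: returns the new state value x
# after one programming pulse of the given kind.
.apply_kind_x <- function(x, kind, rule, p, dt_max = 0.05) {
  if (kind == "NONE") return(x)
  if (kind == "LTP") {
    V <- rule$v_hat * rule$pulse_amplitude
    width <- rule$set_width_factor * rule$Tp
  } else {
    V <- -rule$v_hat * rule$pulse_amplitude
    width <- rule$Tp
  }
  .integrate_const_v(x, p$eta * threshold_motion(V, p), width, p,
                     dt_max_ms = dt_max)
}

#' Apply a plasticity decision to a synaptic memristor
#'
#' Translates an LTP (LTD) decision into a single positive SET (negative
#' RESET) pulse of amplitude `pulse_amplitude` and width
#' `set_width_factor * Tp` (`Tp`), advanced through the device model.
#' A NONE decision leaves the state untouched.
#'
#' @param syn_state A [memristor_state()] for the synapse.
#' @param d A `plasticity_decision` from [classify_pair()].
#' @param rule A [plasticity_rule()].
#' @param p A [memristor_params()] object.
#' @param dt_max Euler sub-step (ms).
#' @return The updated `memristor_state`; time advances by the pulse
#'   width (the synapse does not transmit while being programmed).
#' @export
apply_decision <- function(syn_state, d, rule, p, dt_max = 0.05) {
  if (d$kind == "NONE") return(syn_state)
  width <- if (d$kind == "LTP") rule$set_width_factor * rule$Tp else rule$Tp
  x <- .apply_kind_x(syn_state$x, d$kind, rule, p, dt_max = dt_max)
  memristor_state(x = x, t = syn_state$t + width)
}

#' Normalised synaptic weight of a memristive synapse
#'
#' The conductance at the read voltage, min-max normalised between the
#' model's conductance rails at x = 0 and x = 1, giving a weight in
#' [0, 1] (exactly 0 at x = 0 and 1 at x = 1).  Because the conductance
#' factor is linear in x, the weight equals x analytically; it is still
#' computed from the I-V law so the mapping holds for any conductance
#' parametrisation.
#'
#' @param syn_state A [memristor_state()], or a numeric state value.
#' @param p A [memristor_params()] object.
#' @param v_read Read voltage (V).
#' @return Weight in [0, 1].
#' @export
weight_of <- function(syn_state, p, v_read = 0.1) {
  x <- if (inherits(syn_state, "memristor_state")) syn_state$x else syn_state
  g <- read_conductance(x, p, v_read)
  g0 <- read_conductance(0, p, v_read)
  g1 <- read_conductance(1, p, v_read)
  (g - g0) / (g1 - g0)
}
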