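# Nonlinear threshold memristor device model.
#
# The device is described by a state variable x in [0, 1] (x = 0: highest
# resistance, x = 1: lowest resistance).  The instantaneous I-V law is a
# hyperbolic sine scaled by a conductance factor linear in x; state motion
# only occurs above a programming threshold and is confined to [0, 1] by
# exponential-decay window functions.  Time is handled in milliseconds at
# the user interface and in seconds inside the ODE integrator.

#' Memristor device model parameters
#'
#' Constructs the parameter set of the generalized threshold memristor
#' model with a bounded resistance range.  Defaults are the fitted values
#' for an Au/LNO/Pt device (lithium-niobate insulating layer).
#'
#' @param a1 Current scale for non-negative voltage (A).
#' @param a2 Current scale for negative voltage (A).
#' @param b Argument scale of the hyperbolic sine (1/V).
#' @param r Ratio of highest to lowest resistance (dimensionless, > 1).
#'   Bounds the conductance range so neither resistance rail diverges.
#' @param Vp Positive programming threshold (V, >= 0).
#' @param Vn Magnitude of the negative programming threshold (V, >= 0).
#' @param Ap,An Magnitudes of the exponential motion above the positive /
#'   below the negative threshold (1/s).
#' @param xp,xn Boundary points in (0, 1) beyond which the window
#'   functions throttle positive / negative state motion.
#' @param alpha_p,alpha_n Exponential decay rates of the positive /
#'   negative window functions.
#' @param x0 Initial state in [0, 1].
#' @param eta Polarity direction of state motion, +1 or -1.
#'
#' @return An object of class `memristor_params` (a named list).
#' @examples
#' p <- memristor_params()
#' memristor_current(0.2, x = 1, p = p)
#' @export
memristor_params <- function(a1 = 7e-7, a2 = 7e-7, b = 1.5, r = 9,
                             Vp = 0.5, Vn = 0.5, Ap = 0.95, An = 35,
                             xp = 0.05, xn = 0.3,
                             alpha_p = 1.5, alpha_n = 5,
                             x0 = 0.01, eta = 1) {
  p <- list(a1 = a1, a2 = a2, b = b, r = r, Vp = Vp, Vn = Vn,
            Ap = Ap, An = An, xp = xp, xn = xn,
            alpha_p = alpha_p, alpha_n = alpha_n, x0 = x0, eta = eta)
  p <- lapply(p, as.numeric)
  stopifnot(
    "r must be > 1" = p$r > 1,
    "x0 must lie in [0, 1]" = p$x0 >= 0 && p$x0 <= 1,
    "Vp and Vn must be >= 0" = p$Vp >= 0 && p$Vn >= 0,
    "xp must lie in (0, 1)" = p$xp > 0 && p$xp < 1,
    "xn must lie in (0, 1)" = p$xn > 0 && p$xn < 1,
    "eta must be +1 or -1" = p$eta %in% c(-1, 1)
  )
  structure(p, class = "memristor_params")
}

#' @export
print.memristor_params <- function(x, ...) {
  cat("<memristor_params>\n")
  vals <- vapply(unclass(x), format, character(1), digits = 4)
  cat(paste0("  ", format(names(vals)), " = ", vals), sep = "\n")
  invisible(x)
}

#' Memristor state
#'
#' Pairs the dimensionless state variable `x` with the simulation time at
#' which it was last updated.
#'
#' @param x State in [0, 1]; defaults to the model's `x0`.
#' @param t Time (ms).
#' @param p Optional [memristor_params()] supplying the default `x`.
#' @return An object of class `memristor_state`.
#' @export
memristor_state <- function(x = NULL, t = 0, p = NULL) {
  if (is.null(x)) x <- if (is.null(p)) 0 else p$x0
  stopifnot("x must lie in [0, 1]" = x >= 0 && x <= 1)
  structure(list(x = as.numeric(x), t = as.numeric(t)),
            class = "memristor_state")
}

.check_x <- function(x) {
  if (any(x < 0 | x > 1)) {
    stop("state variable x must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Instantaneous memristor current
#'
#' The I-V law: a hyperbolic sine in the applied voltage scaled by a
#' conductance factor `1/r + (r - 1) x / r` that interpolates between the
#' highest-resistance (x = 0) and lowest-resistance (x = 1) rails.
#'
#' @param V Applied voltage (V); vectorised.
#' @param x State in [0, 1]; vectorised (recycled against `V`).
#' @param p A [memristor_params()] object.
#' @return Current (A).
#' @export
memristor_current <- function(V, x, p) {
  .check_x(x)
  scale <- ifelse(V >= 0, p$a1, p$a2)
  scale * (1 / p$r + (p$r - 1) * x / p$r) * sinh(p$b * V)
}

#' Small-signal conductance readout
#'
#' Conductance `I(v_read) / v_read` at a sub-threshold read voltage, the
#' quantity reported after each programming pulse.
#'
#' @param x State in [0, 1].
#' @param p A [memristor_params()] object.
#' @param v_read Read voltage (V); must sit inside the programming dead
#'   zone so the readout does not perturb the state.
#' @return Conductance (S).
#' @export
read_conductance <- function(x, p, v_read = 0.1) {
  memristor_current(v_read, x, p) / v_read
}

#' Threshold motion function
#'
#' Magnitude of state motion as a function of voltage.  Zero on the closed
#' dead zone `[-Vn, Vp]` (the exponential differences vanish at the
#' endpoints, so the closed convention is continuous), exponential beyond
#' either threshold.
#'
#' @param V Applied voltage (V); vectorised.
#' @param p A [memristor_params()] object.
#' @return Motion magnitude g(V) in 1/s (signed: negative below `-Vn`).
#' @export
threshold_motion <- function(V, p) {
  out <- numeric(length(V))
  pos <- V > p$Vp
  neg <- V < -p$Vn
  out[pos] <- p$Ap * (exp(V[pos]) - exp(p$Vp))
  out[neg] <- -p$An * (exp(-V[neg]) - exp(p$Vn))
  out
}

#' Window function bounding state motion
#'
#' Keeps the state variable inside [0, 1]: motion in each direction is
#' unthrottled until a boundary point (`xp` going up, `1 - xn` going
#' down), then decays exponentially and vanishes exactly at the rail.
#'
#' @param x State in [0, 1]; vectorised.
#' @param direction `"positive"` (state increasing) or `"negative"`.
#' @param p A [memristor_params()] object.
#' @return f(x) >= 0.
#' @export
window_fn <- function(x, direction = c("positive", "negative"), p) {
  direction <- match.arg(direction)
  .check_x(x)
  if (direction == "positive") {
    wp <- (p$xp - x) / (1 - p$xp) + 1
    ifelse(x < p$xp, 1, exp(-p$alpha_p * (x - p$xp)) * wp)
  } else {
    wn <- x / (1 - p$xn)
    ifelse(x > 1 - p$xn, 1, exp(p$alpha_n * (x + p$xn - 1)) * wn)
  }
}

# Tight Euler loop at constant voltage.  g_eta = eta * g(V) (1/s), width in
# ms.  The window function is inlined so per-pulse integration stays cheap
# even when called once per plasticity event.
.integrate_const_v <- function(x, g_eta, width_ms, p, dt_max_ms = 0.05) {
  if (g_eta == 0 || width_ms <= 0) {
    return(min(max(x, 0), 1))
  }
  n <- ceiling(width_ms / dt_max_ms)
  h <- (width_ms / n) / 1000
  if (g_eta > 0) {
    xp <- p$xp; ap <- p$alpha_p
    for (i in seq_len(n)) {
      f <- if (x < xp) 1 else exp(-ap * (x - xp)) * ((xp - x) / (1 - xp) + 1)
      x <- x + h * g_eta * f
      if (x > 1) x <- 1 else if (x < 0) x <- 0
    }
  } else {
    xn <- p$xn; an <- p$alpha_n
    for (i in seq_len(n)) {
      f <- if (x > 1 - xn) 1 else exp(an * (x + xn - 1)) * (x / (1 - xn))
      x <- x + h * g_eta * f
      if (x > 1) x <- 1 else if (x < 0) x <- 0
    }
  }
  x
}

#' Advance the memristor state under a constant voltage
#'
#' Explicit Euler integration of `dx/dt = eta * g(V) * f(x)` over `dt`,
#' with the appropriate direction's window function and the result clamped
#' to [0, 1].  Voltages inside the programming dead zone leave the state
#' exactly unchanged.
#'
#' @param s A [memristor_state()].
#' @param V Applied voltage (V), held constant over the step.
#' @param dt Step duration (ms, > 0).
#' @param p A [memristor_params()] object.
#' @param dt_max Maximum internal Euler sub-step (ms).
#' @return An updated `memristor_state`.
#' @export
step_state <- function(s, V, dt, p, dt_max = 0.05) {
  stopifnot("dt must be > 0" = dt > 0)
  g_eta <- p$eta * threshold_motion(V, p)
  x <- .integrate_const_v(s$x, g_eta, dt, p, dt_max_ms = dt_max)
  memristor_state(x = x, t = s$t + dt)
}

#' Programming pulse train
#'
#' Describes a train of identical rectangular voltage pulses used for
#' LTP/LTD characterisation (e.g. 100 pulses of +1.5 V, 5 ms each).
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param amplitude Pulse voltage (V, signed) on the driven electrode.
#' @param width Pulse duration (ms, > 0).
#' @param interval Gap between pulses (ms); the device sits at 0 V during
#'   the gap, inside the dead zone, so the state is untouched there.
#' @param polarity_convention `"top-positive"` (voltage as given, top
#'   electrode referenced) or `"bottom-negative"` (the bottom electrode is
#'   driven, so the voltage across the device is the negative of
#'   `amplitude`).
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(n_pulses = 100, amplitude = 1.5, width = 5,
                        interval = 5,
                        polarity_convention = c("top-positive",
                                                "bottom-negative")) {
  polarity_convention <- match.arg(polarity_convention)
  stopifnot("n_pulses must be >= 1" = n_pulses >= 1,
            "width must be > 0" = width > 0)
  structure(list(n_pulses = as.integer(n_pulses),
                 amplitude = as.numeric(amplitude),
                 width = as.numeric(width),
                 interval = as.numeric(interval),
                 polarity_convention = polarity_convention),
            class = "pulse_train")
}

#' Effective top-referenced voltage of a pulse train
#' @param train A [pulse_train()].
#' @return Signed voltage across the device (V).
#' @export
effective_voltage <- function(train) {
  if (train$polarity_convention == "bottom-negative") {
    -train$amplitude
  } else {
    train$amplitude
  }
}

#' Cycle-to-cycle / device-to-device variability
#'
#' Relative noise fractions applied to the motion parameters `alpha_p`,
#' `alpha_n`, `Ap` and `An`.  Defaults are 40, 10, 25 and 20 %.
#'
#' @param frac_alpha_p,frac_alpha_n,frac_Ap,frac_An Relative noise
#'   fractions (>= 0).
#' @param seed Optional RNG seed for reproducible sampling.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(frac_alpha_p = 0.40, frac_alpha_n = 0.10,
                       frac_Ap = 0.25, frac_An = 0.20, seed = NULL) {
  fr <- c(frac_alpha_p, frac_alpha_n, frac_Ap, frac_An)
  stopifnot("noise fractions must be >= 0" = all(fr >= 0))
  structure(list(frac_alpha_p = frac_alpha_p, frac_alpha_n = frac_alpha_n,
                 frac_Ap = frac_Ap, frac_An = frac_An,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

# Perturb one parameter set; assumes the RNG is already seeded by caller.
.perturb_params <- function(p, noise, floor = 1e-12) {
  fr <- c(alpha_p = noise$frac_alpha_p, alpha_n = noise$frac_alpha_n,
          Ap = noise$frac_Ap, An = noise$frac_An)
  for (nm in names(fr)) {
    p[[nm]] <- max(p[[nm]] * (1 + stats::runif(1, -fr[[nm]], fr[[nm]])),
                   floor)
  }
  p
}

#' Sample a perturbed device instance
#'
#' Draws a copy of the parameter set with `alpha_p`, `alpha_n`, `Ap` and
#' `An` independently perturbed by uniform relative noise on
#' `+/- fraction` about the nominal value, emulating device-to-device
#' variation.  Sampled magnitudes are truncated at a small positive floor
#' (1e-12) so the motion terms keep their sign.
#'
#' @param p A [memristor_params()] object.
#' @param noise A [noise_spec()]; when its `seed` is non-NULL the draw is
#'   reproducible.
#' @return A perturbed `memristor_params` object.
#' @export
sample_device <- function(p, noise) {
  draw <- function() .perturb_params(p, noise)
  out <- if (is.null(noise$seed)) draw() else withr::with_seed(noise$seed, draw())
  structure(out, class = "memristor_params")
}

#' Apply a programming pulse train and record the conductance trace
#'
#' Applies each pulse with [step_state()] and reads the small-signal
#' conductance after every pulse.  With a `noise_spec`, the motion
#' parameters are resampled independently for every pulse (cycle-to-cycle
#' variation); under a fixed seed the trace is reproducible.
#'
#' @param s A [memristor_state()]; the starting state.
#' @param train A [pulse_train()].
#' @param p A [memristor_params()] object.
#' @param noise Optional [noise_spec()] for per-pulse parameter noise.
#' @param v_read Read voltage (V) for the conductance readout.
#' @param dt_max Maximum Euler sub-step (ms).
#' @return A tibble with columns `pulse_index`, `voltage_V`, `width_ms`
#'   and `conductance_S`; the final device state is attached as attribute
#'   `"final_state"`.
#' @examples
#' p <- memristor_params()
#' ltp <- run_pulse_train(memristor_state(p = p), pulse_train(), p)
#' @export
run_pulse_train <- function(s, train, p, noise = NULL,
                            v_read = 0.1, dt_max = 0.05) {
  V <- effective_voltage(train)
  run <- function() {
    x <- s$x
    g <- numeric(train$n_pulses)
    for (i in seq_len(train$n_pulses)) {
      pp <- if (is.null(noise)) p else .perturb_params(p, noise)
      g_eta <- pp$eta * threshold_motion(V, pp)
      x <- .integrate_const_v(x, g_eta, train$width, pp, dt_max_ms = dt_max)
      g[i] <- read_conductance(x, p, v_read)
    }
    list(g = g, x = x)
  }
  res <- if (is.null(noise) || is.null(noise$seed)) {
    run()
  } else {
    withr::with_seed(noise$seed, run())
  }
  period <- train$width + train$interval
  out <- tibble::tibble(
    pulse_index = seq_len(train$n_pulses),
    voltage_V = V,
    width_ms = train$width,
    conductance_S = res$g
  )
  attr(out, "final_state") <- memristor_state(
    x = res$x, t = s$t + train$n_pulses * period
  )
  out
}

#' Quasi-static I-V sweep
#'
#' Drives a triangular voltage sweep `v_min -> v_max -> v_min` at a fixed
#' rate while integrating the state variable, producing the pinched
#' hysteresis loop characteristic of memristive devices (the current is
#' exactly zero whenever the voltage is zero).
#'
#' @param p A [memristor_params()] object.
#' @param v_min,v_max Sweep extremes (V), `v_min < v_max`.
#' @param rate Sweep rate (V/s).
#' @param x0 Starting state; defaults to the model's `x0`.
#' @param dt_max Integration step (ms); also the sampling interval.
#' @return A tibble with columns `t_ms`, `voltage_V`, `current_A`, `x`
#'   and `branch` (`"up"` or `"down"`).
#' @export
iv_sweep <- function(p, v_min = -2, v_max = 2, rate = 100,
                     x0 = NULL, dt_max = 0.05) {
  stopifnot("v_min must be < v_max" = v_min < v_max)
  if (is.null(x0)) x0 <- p$x0
  dv <- rate * dt_max / 1000
  up <- seq(v_min, v_max, by = dv)
  down <- seq(v_max, v_min, by = -dv)[-1]
  volts <- c(up, down)
  branch <- rep(c("up", "down"), c(length(up), length(down)))
  n <- length(volts)
  x <- numeric(n)
  cur <- x0
  for (i in seq_len(n)) {
    g_eta <- p$eta * threshold_motion(volts[i], p)
    cur <- .integrate_const_v(cur, g_eta, dt_max, p, dt_max_ms = dt_max)
    x[i] <- cur
  }
  tibble::tibble(
    t_ms = seq_len(n) * dt_max,
    voltage_V = volts,
    current_A = memristor_current(volts, x, p),
    x = x,
    branch = branch
  )
}
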