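# Least-squares fitting of the device model to a measured (or synthetic)
# pulse-train conductance trace.  Fitting is done on the log of the chosen
# parameters (all are positive magnitudes) with Levenberg-Marquardt.

#' Fit memristor model parameters to a conductance trace
#'
#' Minimises the sum of squared differences between a given per-pulse
#' conductance trace and the trace simulated by [run_pulse_train()] under
#' candidate parameters, over a chosen subset of the motion parameters.
#' Optimisation is Levenberg-Marquardt ([minpack.lm::nls.lm()]) on the log
#' scale; residuals are normalised by the trace maximum so convergence is
#' insensitive to the absolute conductance magnitude.
#'
#' A degenerate problem (a constant trace, or a protocol whose pulses sit
#' inside the programming dead zone and therefore cannot move the state)
#' is flagged rather than fitted.  Non-convergence is reported in the
#' returned object, never silently.
#'
#' @param trace Numeric vector of per-pulse conductances (S), or a tibble
#'   with a `conductance_S` column as produced by [run_pulse_train()].
#' @param protocol The [pulse_train()] that generated the trace.
#' @param init A [memristor_params()] object: starting values, and fixed
#'   values for parameters not in `fit`.
#' @param fit Character vector of parameter names to optimise; any of
#'   `"Ap"`, `"An"`, `"alpha_p"`, `"alpha_n"`, `"b"`, `"a1"`, `"a2"`.
#' @param x_start Starting state of the device before the train; defaults
#'   to `init$x0`.
#' @param v_read Read voltage (V) used for the trace.
#' @param dt_max Euler sub-step (ms) for the simulated traces.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `memristor_fit` with elements `params`
#'   (fitted `memristor_params`), `fitted` (simulated trace), `residuals`,
#'   `ssr`, `converged`, `degenerate`, `info`, `message` and `n_iter`.
#'   Use [generics::tidy()] / [generics::glance()] to extract summaries.
#' @examples
#' p <- memristor_params()
#' tr <- run_pulse_train(memristor_state(p = p), pulse_train(), p)
#' init <- memristor_params(Ap = 1.2, alpha_p = 2)
#' f <- fit_params(tr, pulse_train(), init)
#' tidy(f)
#' @export
fit_params <- function(trace, protocol, init,
                       fit = c("alpha_p", "Ap"),
                       x_start = NULL, v_read = 0.1, dt_max = 0.05,
                       control = minpack.lm::nls.lm.control(maxiter = 100)) {
  if (is.data.frame(trace)) trace <- trace$conductance_S
  trace <- as.numeric(trace)
  stopifnot(
    "trace and protocol lengths are inconsistent" =
      length(trace) == protocol$n_pulses,
    "unknown parameter in `fit`" =
      all(fit %in% c("Ap", "An", "alpha_p", "alpha_n", "b", "a1", "a2"))
  )
  if (is.null(x_start)) x_start <- init$x0
  g_scale <- max(abs(trace))

  V <- effective_voltage(protocol)
  dead <- V <= init$Vp & V >= -init$Vn
  degenerate <- dead || stats::sd(trace) == 0 || g_scale == 0
  simulate <- function(p) {
    run_pulse_train(memristor_state(x = x_start), protocol, p,
                    v_read = v_read, dt_max = dt_max)$conductance_S
  }

  if (degenerate) {
    fitted <- simulate(init)
    res <- structure(list(
      params = init, fitted = fitted, residuals = trace - fitted,
      ssr = sum((trace - fitted)^2), converged = FALSE, degenerate = TRUE,
      info = NA_integer_, n_iter = 0L, fit_names = fit, init = init,
      message = "degenerate fit: trace is constant or protocol cannot move the state"
    ), class = "memristor_fit")
    return(res)
  }

  make_params <- function(logtheta) {
    p <- init
    p[fit] <- as.list(exp(logtheta))
    structure(p, class = "memristor_params")
  }
  resid_fn <- function(logtheta) {
    (simulate(make_params(logtheta)) - trace) / g_scale
  }
  start <- log(unlist(init[fit]))
  lm_fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, control = control)

  params <- make_params(lm_fit$par)
  fitted <- simulate(params)
  structure(list(
    params = params, fitted = fitted, residuals = trace - fitted,
    ssr = sum((trace - fitted)^2),
    converged = lm_fit$info %in% 1:3, degenerate = FALSE,
    info = lm_fit$info, n_iter = lm_fit$niter,
    fit_names = fit, init = init, message = lm_fit$message
  ), class = "memristor_fit")
}

#' @export
print.memristor_fit <- function(x, ...) {
  cat("<memristor_fit>\n")
  if (x$degenerate) {
    cat("  DEGENERATE:", x$message, "\n")
  } else if (!x$converged) {
    cat("  NOT CONVERGED (info =", x$info, "):", trimws(x$message), "\n")
  }
  est <- unlist(x$params[x$fit_names])
  ini <- unlist(x$init[x$fit_names])
  cat(sprintf("  %-8s start %-10.4g fitted %-10.4g\n",
              x$fit_names, ini, est), sep = "")
  cat(sprintf("  SSR %.4g over %d pulses\n", x$ssr, length(x$fitted)))
  invisible(x)
}

#' @rdname fit_params
#' @param x A `memristor_fit` object.
#' @param ... Unused.
#' @method tidy memristor_fit
#' @export
tidy.memristor_fit <- function(x, ...) {
  tibble::tibble(
    term = x$fit_names,
    estimate = unlist(x$params[x$fit_names], use.names = FALSE),
    start = unlist(x$init[x$fit_names], use.names = FALSE)
  )
}

#' @rdname fit_params
#' @method glance memristor_fit
#' @export
glance.memristor_fit <- function(x, ...) {
  tibble::tibble(
    ssr = x$ssr,
    rmse = sqrt(mean(x$residuals^2)),
    n_pulses = length(x$fitted),
    n_iter = x$n_iter,
    converged = x$converged,
    degenerate = x$degenerate
  )
}
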