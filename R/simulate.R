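# Time integration of the HH / MHH membrane systems.
#
# Fixed-step classical 4th-order Runge-Kutta (deSolve's "rk4" method) on a
# uniform grid: deterministic, reproducible traces that a tiny-step Euler
# integration can cross-check. Initial state is the resting potential with
# the gates at their steady state there (and the flux at its configured
# preset for the memristive model).

.assert_dt <- function(dt, duration) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    rlang::abort("`dt` must be a positive step size.",
                 class = "memhh_invalid_parameter")
  }
  if (duration / dt > 1e7) {
    rlang::abort("duration / dt exceeds 1e7 steps.",
                 class = "memhh_invalid_parameter")
  }
}

.check_finite <- function(out, what) {
  bad <- !stats::complete.cases(out) | rowSums(!is.finite(as.matrix(out))) > 0
  if (any(bad)) {
    t_bad <- out[which(bad)[1], 1]
    rlang::abort(
      sprintf("%s diverged: non-finite state at t = %g ms.", what, t_bad),
      class = "memhh_divergence_error")
  }
}

# Assemble the derived series (conductances, currents, dV/dt) and the trace
# tibble from the raw integrator output.
.build_trace <- function(out, model, params, options, mem, protocol, kind, dt,
                         clamped_V = NULL) {
  t <- out[, 1]
  V <- if (is.null(clamped_V)) out[, 2] else rep(clamped_V, length(t))
  m <- out[, 3]; n <- out[, 4]; h <- out[, 5]
  J_ext <- if (kind == "current_clamp") stimulus_value(protocol, t) else rep(0, length(t))
  if (model == "hh") {
    g_Na <- params$g_Na_max * m^3 * h
    g_K <- params$g_K_max * n^4
    extra <- NULL
  } else {
    f_Na <- out[, 6]
    f_K <- if (mem$shared_flux) out[, 6] else out[, 7]
    M_Na <- memristance(f_Na, mem)
    M_K <- memristance(f_K, mem)
    g_Na <- 1000 * m^3 * h / M_Na   # memductance expressed in mS/cm^2
    g_K <- 1000 * n^4 / M_K
    extra <- tibble::tibble(flux_Na = f_Na, flux_K = f_K,
                            M_Na = M_Na, M_K = M_K)
  }
  J_Na <- g_Na * (V - params$E_Na) / 1000
  J_K <- g_K * (V - params$E_K) / 1000
  J_L <- params$g_L_max * (V - params$E_L) / 1000
  J_total <- J_Na + J_K + J_L
  dVdt <- if (kind == "current_clamp") 1000 * (J_ext - J_total) / params$C
          else rep(0, length(t))
  tr <- tibble::tibble(t = t, V = V, m = m, n = n, h = h,
                       g_Na = g_Na, g_K = g_K,
                       J_Na = J_Na, J_K = J_K, J_L = J_L, J_total = J_total,
                       J_ext = J_ext, dVdt = dVdt)
  if (!is.null(extra)) tr <- dplyr::bind_cols(tr, extra)
  meta <- list(model = model, kind = kind, dt = dt,
               params = unclass(params), options = unclass(options),
               mem = if (model == "mhh") unclass(mem) else NULL,
               protocol = unclass(protocol))
  attr(tr, "memhh_meta") <- meta
  class(tr) <- c("memhh_trace", class(tr))
  tr
}

#' Trace metadata
#'
#' Returns the run metadata attached to a simulated trace: model variant,
#' protocol, step size, and the parameter/option/memristor settings used.
#'
#' @param trace A trace from [run_current_clamp()] or [run_voltage_clamp()].
#' @return A named list.
#' @export
trace_meta <- function(trace) attr(trace, "memhh_meta")

#' Simulate under current clamp
#'
#' Integrates the chosen model from its resting initial condition (V at the
#' resting potential, gates at their steady state there, flux at the
#' configured preset) while injecting the given stimulus, and returns the
#' densely sampled trace.
#'
#' @param model `"hh"` or `"mhh"`.
#' @param stim A stimulus from the [stimulus] constructors.
#' @param params A [neuron_params()] object.
#' @param options A [kinetics_options()] context.
#' @param mem A [memristor_config()] object (used by `"mhh"` only).
#' @param dt Integration step, ms. Default 0.005.
#' @param duration Run length, ms; defaults to the stimulus duration.
#' @return A `memhh_trace` tibble with the uniform time grid `t` and columns
#'   `V`, `m`, `n`, `h`, conductances `g_Na`/`g_K` (mS/cm^2; for the
#'   memristive model these are the memductances expressed in mS/cm^2),
#'   current densities `J_Na`, `J_K`, `J_L`, `J_total`, `J_ext` (mA/cm^2),
#'   the model derivative `dVdt`, and for `"mhh"` additionally `flux_Na`,
#'   `flux_K`, `M_Na`, `M_K`. Metadata via [trace_meta()].
#' @examples
#' tr <- run_current_clamp("hh", stim_pulse(0.1, 0.5, 0.1, 5),
#'                         options = kinetics_options(18.5))
#' max(tr$V)
#' @export
run_current_clamp <- function(model = c("hh", "mhh"), stim,
                              params = neuron_params(),
                              options = kinetics_options(),
                              mem = memristor_config(),
                              dt = 0.005, duration = stim$duration) {
  model <- match.arg(model)
  if (!inherits(stim, "memhh_stimulus")) {
    rlang::abort("`stim` must be a memhh stimulus.", class = "memhh_config_error")
  }
  .assert_dt(dt, duration)
  phi <- temperature_factor(options$temperature)
  bdiv <- options$beta_m_divisor
  eps <- options$singularity_epsilon
  g0 <- .gate_steady(params$v_rest, options)
  times <- seq(0, duration, by = dt)
  if (model == "hh") {
    y0 <- c(params$v_rest, g0$m, g0$n, g0$h)
    func <- function(t, y, p) {
      list(.hh_deriv(y, stimulus_value(stim, t), params, phi, bdiv, eps))
    }
  } else {
    f0 <- .flux_initial(mem)
    y0 <- c(params$v_rest, g0$m, g0$n, g0$h, f0, f0)
    func <- function(t, y, p) {
      list(.mhh_deriv(y, stimulus_value(stim, t), params, mem, phi, bdiv, eps))
    }
  }
  out <- deSolve::ode(y0, times, func, parms = NULL, method = "rk4")
  .check_finite(out, paste(model, "current clamp"))
  .build_trace(out, model, params, options, mem, stim, "current_clamp", dt)
}

#' Simulate under ideal voltage clamp
#'
#' Holds the membrane potential at `V_clamp + v_rest` from t = 0 (an ideal
#' instantaneous step, no series resistance) and integrates the gate
#' dynamics - and, for the memristive model, the flux states - at the
#' clamped potential, recording currents and conductances.
#'
#' @param clamp A [clamp_spec()] protocol.
#' @inheritParams run_current_clamp
#' @return A `memhh_trace` tibble (see [run_current_clamp()]); `V` is the
#'   constant held potential and `J_ext` is reported as 0.
#' @examples
#' tr <- run_voltage_clamp("hh", clamp_spec(20, 10))
#' max(tr$g_K)
#' @export
run_voltage_clamp <- function(model = c("hh", "mhh"), clamp,
                              params = neuron_params(),
                              options = kinetics_options(),
                              mem = memristor_config(),
                              dt = 0.005) {
  model <- match.arg(model)
  if (!inherits(clamp, "memhh_clamp_spec")) {
    rlang::abort("`clamp` must be a clamp_spec().", class = "memhh_config_error")
  }
  .assert_dt(dt, clamp$duration)
  V_hold <- clamp$V_clamp + params$v_rest
  phi <- temperature_factor(options$temperature)
  bdiv <- options$beta_m_divisor
  eps <- options$singularity_epsilon
  g0 <- .gate_steady(params$v_rest, options)
  times <- seq(0, clamp$duration, by = dt)
  gate_deriv <- function(y) {
    r <- .rates(V_hold - params$v_rest, phi, bdiv, eps)
    c(r$alpha_m * (1 - y[1]) - r$beta_m * y[1],
      r$alpha_n * (1 - y[2]) - r$beta_n * y[2],
      r$alpha_h * (1 - y[3]) - r$beta_h * y[3])
  }
  if (model == "hh") {
    y0 <- c(g0$m, g0$n, g0$h)
    func <- function(t, y, p) list(gate_deriv(y))
  } else {
    f0 <- .flux_initial(mem)
    y0 <- c(g0$m, g0$n, g0$h, f0, f0)
    dflux <- mem$flux_gain * (V_hold - params$v_rest)
    func <- function(t, y, p) list(c(gate_deriv(y[1:3]), dflux, dflux))
  }
  out <- deSolve::ode(y0, times, func, parms = NULL, method = "rk4")
  .check_finite(out, paste(model, "voltage clamp"))
  # reshape to the (t, V, m, n, h, flux...) layout .build_trace expects
  full <- cbind(out[, 1], V_hold, out[, -1, drop = FALSE])
  .build_trace(full, model, params, options, mem, clamp, "voltage_clamp", dt,
               clamped_V = V_hold)
}
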