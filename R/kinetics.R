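# Voltage- and temperature-dependent gating kinetics of the Na+/K+ channels.
#
# All rates are in 1/ms, voltages in mV, and every rate function is written in
# terms of the deviation v = V_m - V_rest from the resting potential.

#' Kinetics evaluation context
#'
#' Bundles the quantities every rate evaluation needs: the temperature (which
#' enters through the Q10-style factor [temperature_factor()]), the resting
#' potential used to form the deviation voltage `v = V_m - v_rest`, the
#' divisor of the exponential in `beta_m`, and the window below which the
#' removable singularity of `x / (exp(x) - 1)` is evaluated by its series.
#'
#' Two `beta_m` variants are in circulation for this model family:
#' `beta_m = 4 * phi * exp(-v / 18)` (the canonical squid-axon fit, the
#' default here, which reproduces the classic voltage-clamp conductance peaks)
#' and the divisor-20 variant `4 * phi * exp(-v / 20)`. Both are exposed via
#' `beta_m_divisor`.
#'
#' @param temperature Temperature in degrees Celsius. Default 6.3.
#' @param v_rest Resting potential in mV. Default -65.
#' @param beta_m_divisor Divisor (mV) of the exponential in `beta_m`;
#'   18 (default) or 20.
#' @param singularity_epsilon Half-width of the series window around the
#'   removable singular points of `alpha_m` and `alpha_n`.
#' @return A list of class `memhh_kinetics_options`.
#' @examples
#' kinetics_options(temperature = 18.5)
#' @export
kinetics_options <- function(temperature = 6.3, v_rest = -65,
                             beta_m_divisor = 18,
                             singularity_epsilon = 1e-7) {
  if (!is.numeric(temperature) || length(temperature) != 1 || !is.finite(temperature)) {
    rlang::abort("`temperature` must be a single finite number.",
                 class = "memhh_invalid_parameter")
  }
  if (!is.numeric(beta_m_divisor) || beta_m_divisor <= 0) {
    rlang::abort("`beta_m_divisor` must be a positive number.",
                 class = "memhh_invalid_parameter")
  }
  structure(
    list(temperature = temperature, v_rest = v_rest,
         beta_m_divisor = beta_m_divisor,
         singularity_epsilon = singularity_epsilon),
    class = "memhh_kinetics_options")
}

#' Temperature factor of the transition rates
#'
#' All six transition rates scale with the common factor
#' `phi = 3^((T - 6.3) / 10)`, i.e. a Q10 of 3 referenced to 6.3 degrees C.
#'
#' @param temperature Temperature in degrees Celsius.
#' @return The positive scalar `3^((temperature - 6.3) / 10)`.
#' @examples
#' temperature_factor(6.3)   # 1
#' temperature_factor(16.3)  # 3
#' @export
temperature_factor <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature))) {
    rlang::abort("`temperature` must be finite.",
                 class = "memhh_invalid_parameter")
  }
  3^((temperature - 6.3) / 10)
}

# x / (exp(x) - 1), continued through x = 0 by its second-order series.
# Vectorised; `eps` is the window below which the series is used.
xexpm1 <- function(x, eps = 1e-7) {
  out <- numeric(length(x))
  small <- abs(x) < eps
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

# Internal fast path: plain list of rate vectors, no tibble allocation.
# v is the deviation voltage V_m - v_rest.
.rates <- function(v, phi, beta_m_divisor, eps) {
  list(
    alpha_m = phi * xexpm1(2.5 - 0.1 * v, eps),
    beta_m  = 4 * phi * exp(-v / beta_m_divisor),
    alpha_n = 0.1 * phi * xexpm1(1 - 0.1 * v, eps),
    beta_n  = 0.125 * phi * exp(-v / 80),
    alpha_h = 0.07 * phi * exp(-v / 20),
    beta_h  = phi / (exp(3 - 0.1 * v) + 1))
}

#' Channel opening/closing transition rates
#'
#' Evaluates the six voltage-dependent transition rates of the m, n and h
#' gates at membrane potential `v_m`, scaled by the temperature factor.
#' `alpha_x` is the closed-to-open rate, `beta_x` the open-to-closed rate.
#' The removable singularities of `alpha_m` (at `v = 25` mV above rest) and
#' `alpha_n` (at `v = 10` mV above rest) are evaluated by a series expansion
#' within `singularity_epsilon` of the singular point, so the returned rates
#' are finite and continuous everywhere.
#'
#' @param v_m Membrane potential(s), mV. Vectorised.
#' @param options A [kinetics_options()] context.
#' @return A tibble with one row per `v_m` and columns `v_m`, `alpha_m`,
#'   `beta_m`, `alpha_n`, `beta_n`, `alpha_h`, `beta_h` (all rates in 1/ms).
#' @examples
#' rate_constants(-65, kinetics_options())
#' @export
rate_constants <- function(v_m, options = kinetics_options()) {
  if (!is.numeric(v_m) || any(!is.finite(v_m))) {
    rlang::abort("`v_m` must be finite.", class = "memhh_invalid_parameter")
  }
  phi <- temperature_factor(options$temperature)
  r <- .rates(v_m - options$v_rest, phi, options$beta_m_divisor,
              options$singularity_epsilon)
  tibble::tibble(v_m = v_m, !!!r)
}

#' Steady-state gate values and time constants
#'
#' From a set of transition rates, the steady state of each gate is
#' `x_inf = alpha_x / (alpha_x + beta_x)` and its relaxation time constant is
#' `tau_x = 1 / (alpha_x + beta_x)`.
#'
#' @param rates A data frame as returned by [rate_constants()] (columns
#'   `alpha_m`, `beta_m`, `alpha_n`, `beta_n`, `alpha_h`, `beta_h`).
#' @return A tibble with columns `m_inf`, `n_inf`, `h_inf` (dimensionless, in
#'   \[0, 1\]) and `tau_m`, `tau_n`, `tau_h` (ms); a `v_m` column is carried
#'   through when present.
#' @examples
#' gate_steady_tau(rate_constants(seq(-100, 60, by = 20)))
#' @export
gate_steady_tau <- function(rates) {
  need <- c("alpha_m", "beta_m", "alpha_n", "beta_n", "alpha_h", "beta_h")
  if (!all(need %in% names(rates))) {
    rlang::abort("`rates` must contain the six alpha/beta columns.",
                 class = "memhh_invalid_parameter")
  }
  sums <- lapply(c("m", "n", "h"), function(g) {
    rates[[paste0("alpha_", g)]] + rates[[paste0("beta_", g)]]
  })
  if (any(unlist(sums) <= 0)) {
    rlang::abort("alpha + beta must be positive for every gate.",
                 class = "memhh_degenerate_kinetics")
  }
  out <- tibble::tibble(
    m_inf = rates$alpha_m / sums[[1]], tau_m = 1 / sums[[1]],
    n_inf = rates$alpha_n / sums[[2]], tau_n = 1 / sums[[2]],
    h_inf = rates$alpha_h / sums[[3]], tau_h = 1 / sums[[3]])
  if ("v_m" %in% names(rates)) {
    out <- tibble::add_column(out, v_m = rates$v_m, .before = 1)
  }
  out
}

#' First-order gate relaxation derivative
#'
#' Each gate relaxes toward its voltage-dependent steady state with
#' `dx/dt = (x_inf - x) / tau`.
#'
#' @param x Current gate value (dimensionless).
#' @param x_inf Steady-state value at the present membrane potential.
#' @param tau Time constant, ms; must be positive.
#' @return The derivative in 1/ms.
#' @examples
#' gate_derivative(0, 1, 2)  # 0.5
#' @export
gate_derivative <- function(x, x_inf, tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    rlang::abort("`tau` must be positive.",
                 class = "memhh_degenerate_kinetics")
  }
  (x_inf - x) / tau
}

# Steady-state gate triple at a given membrane potential; used to initialise
# simulations at the resting potential.
.gate_steady <- function(v_m, options) {
  phi <- temperature_factor(options$temperature)
  r <- .rates(v_m - options$v_rest, phi, options$beta_m_divisor,
              options$singularity_epsilon)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       n = r$alpha_n / (r$alpha_n + r$beta_n),
       h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Gate steady state at a holding potential
#'
#' Convenience wrapper returning the steady-state values of m, n and h at a
#' fixed membrane potential, used as the initial condition of every
#' simulation (gates start at the steady state of the resting potential).
#'
#' @param v_m Holding potential, mV.
#' @param options A [kinetics_options()] context.
#' @return A named list with elements `m`, `n`, `h`.
#' @examples
#' resting_gates(-65)
#' @export
resting_gates <- function(v_m = -65, options = kinetics_options()) {
  .gate_steady(v_m, options)
}
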