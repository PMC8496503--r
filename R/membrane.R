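# Membrane equations of the HH model and its memristive variant.
#
# Conductances: g_K = g_K_max n^4, g_Na = g_Na_max m^3 h (mS/cm^2); currents
# J_x = g_x (V - E_x) converted to mA/cm^2; membrane equation
# C dV/dt = 1000 (J_ext - J_m). In the memristive variant the conductance
# scales come from flux-controlled memristances: g_MK = n^4 / M_K,
# g_MNa = m^3 h / M_Na in Ohm^-1 cm^-2 (S/cm^2), so those currents are in
# mA/cm^2 without the 1/1000 factor.

#' Channel conductances from the gate variables
#'
#' @param gates A list or one-row data frame with elements `m`, `n`, `h`
#'   (vectorised: equal-length vectors give one row per element).
#' @param params A [neuron_params()] object.
#' @return A tibble with columns `g_Na`, `g_K`, `g_L` in mS/cm^2.
#' @examples
#' channel_conductances(list(m = 1, n = 1, h = 1), neuron_params())
#' @export
channel_conductances <- function(gates, params = neuron_params()) {
  g <- as.list(gates)
  if (any(unlist(g[c("m", "n", "h")]) < 0 | unlist(g[c("m", "n", "h")]) > 1)) {
    rlang::abort("gate values must lie in [0, 1].", class = "memhh_invalid_state")
  }
  tibble::tibble(
    g_Na = params$g_Na_max * g$m^3 * g$h,
    g_K  = params$g_K_max * g$n^4,
    g_L  = rep(params$g_L_max, length(g$n)))
}

#' Ionic current densities
#'
#' Ohmic branch currents `J_x = g_x (V - E_x)` with conductances in mS/cm^2
#' and potentials in mV, converted to mA/cm^2 (division by 1000), plus their
#' sum `J_total`.
#'
#' @param V Membrane potential(s), mV.
#' @param conductances A data frame with columns `g_Na`, `g_K`, `g_L`
#'   (mS/cm^2), as from [channel_conductances()].
#' @param params A [neuron_params()] object.
#' @return A tibble with columns `J_Na`, `J_K`, `J_L`, `J_total` in mA/cm^2;
#'   `J_total` equals the sum of the three branches exactly.
#' @examples
#' g <- channel_conductances(list(m = 0.05, n = 0.32, h = 0.6))
#' ionic_current_densities(-65, g)
#' @export
ionic_current_densities <- function(V, conductances, params = neuron_params()) {
  J_Na <- conductances$g_Na * (V - params$E_Na) / 1000
  J_K  <- conductances$g_K * (V - params$E_K) / 1000
  J_L  <- conductances$g_L * (V - params$E_L) / 1000
  tibble::tibble(J_Na = J_Na, J_K = J_K, J_L = J_L,
                 J_total = J_Na + J_K + J_L)
}

# Fast internal HH derivative; y = c(V, m, n, h), J_ext scalar (mA/cm^2).
.hh_deriv <- function(y, J_ext, params, phi, bdiv, eps) {
  V <- y[1]; m <- y[2]; n <- y[3]; h <- y[4]
  r <- .rates(V - params$v_rest, phi, bdiv, eps)
  J_m <- (params$g_Na_max * m^3 * h * (V - params$E_Na) +
          params$g_K_max * n^4 * (V - params$E_K) +
          params$g_L_max * (V - params$E_L)) / 1000
  c(1000 * (J_ext - J_m) / params$C,
    r$alpha_m * (1 - m) - r$beta_m * m,
    r$alpha_n * (1 - n) - r$beta_n * n,
    r$alpha_h * (1 - h) - r$beta_h * h)
}

#' HH state derivative
#'
#' Right-hand side of the space-clamped HH system: the membrane equation
#' `dV/dt = 1000 (J_ext - J_total) / C` (mV/ms) together with the first-order
#' gate relaxations.
#'
#' @param state Named list or vector with `V` (mV) and gates `m`, `n`, `h`.
#' @param J_ext External current density, mA/cm^2.
#' @param params A [neuron_params()] object.
#' @param options A [kinetics_options()] context.
#' @return Named numeric vector of derivatives `(V, m, n, h)` in
#'   mV/ms and 1/ms.
#' @examples
#' hh_rhs(list(V = -65, m = 0.05, n = 0.32, h = 0.6), J_ext = 0)
#' @export
hh_rhs <- function(state, J_ext, params = neuron_params(),
                   options = kinetics_options()) {
  s <- as.list(state)
  phi <- temperature_factor(options$temperature)
  d <- .hh_deriv(c(s$V, s$m, s$n, s$h), J_ext, params, phi,
                 options$beta_m_divisor, options$singularity_epsilon)
  stats::setNames(d, c("V", "m", "n", "h"))
}

#' Piecewise memristance law
#'
#' Evaluates the flux-controlled memristance: `M_high` below the lower
#' breakpoint, the linear segment `slope * phi + intercept` between the
#' breakpoints, `M_low` above the upper breakpoint, and always clipped to
#' `[M_low, M_high]`.
#'
#' @param flux Flux value(s), flux units. Vectorised.
#' @param config A [memristor_config()] object.
#' @return Memristance in Ohm cm^2, one value per flux.
#' @examples
#' memristance(c(-1, 0, 0.5), memristor_config())
#' @export
memristance <- function(flux, config = memristor_config()) {
  if (any(!is.finite(flux))) {
    rlang::abort("`flux` must be finite.", class = "memhh_invalid_parameter")
  }
  M <- ifelse(flux < config$flux_lo, config$M_high,
       ifelse(flux >= config$flux_hi, config$M_low,
              config$slope * flux + config$intercept))
  pmin(pmax(M, config$M_low), config$M_high)
}

#' Memductances of the memristive channels
#'
#' The memristors supply the conductance scale of each channel:
#' `g_MK = n^4 / M_K` and `g_MNa = m^3 h / M_Na`, in Ohm^-1 cm^-2 (S/cm^2).
#'
#' @param gates A list or data frame with `m`, `n`, `h`.
#' @param M_Na,M_K Memristances, Ohm cm^2; must be positive.
#' @return A tibble with columns `g_MNa`, `g_MK` in S/cm^2.
#' @examples
#' memductances(list(m = 1, n = 1, h = 1), 20000, 20000)
#' @export
memductances <- function(gates, M_Na, M_K) {
  if (any(M_Na <= 0) || any(M_K <= 0)) {
    rlang::abort("memristances must be positive.", class = "memhh_invalid_state")
  }
  g <- as.list(gates)
  tibble::tibble(g_MNa = g$m^3 * g$h / M_Na, g_MK = g$n^4 / M_K)
}

# Fast internal MHH derivative; y = c(V, m, n, h, flux_Na, flux_K).
.mhh_deriv <- function(y, J_ext, params, mem, phi, bdiv, eps) {
  V <- y[1]; m <- y[2]; n <- y[3]; h <- y[4]
  f_Na <- y[5]; f_K <- if (mem$shared_flux) y[5] else y[6]
  r <- .rates(V - params$v_rest, phi, bdiv, eps)
  M_Na <- memristance(f_Na, mem)
  M_K <- memristance(f_K, mem)
  J_M <- m^3 * h / M_Na * (V - params$E_Na) +
         n^4 / M_K * (V - params$E_K) +
         params$g_L_max * (V - params$E_L) / 1000
  dflux <- mem$flux_gain * (V - params$v_rest)
  c(1000 * (J_ext - J_M) / params$C,
    r$alpha_m * (1 - m) - r$beta_m * m,
    r$alpha_n * (1 - n) - r$beta_n * n,
    r$alpha_h * (1 - h) - r$beta_h * h,
    dflux, dflux)
}

#' MHH state derivative
#'
#' Right-hand side of the memristive HH system: as [hh_rhs()] but with the
#' Na/K conductances supplied by the memductances of two flux-controlled
#' memristors whose flux integrates the voltage deviation from rest,
#' `dphi/dt = flux_gain * (V - v_rest)` (one shared flux when
#' `shared_flux`).
#'
#' @param state Named list or vector with `V`, `m`, `n`, `h`, `flux_Na`,
#'   `flux_K`.
#' @param J_ext External current density, mA/cm^2.
#' @param params A [neuron_params()] object.
#' @param mem A [memristor_config()] object.
#' @param options A [kinetics_options()] context.
#' @return Named numeric vector of derivatives
#'   `(V, m, n, h, flux_Na, flux_K)`.
#' @examples
#' mhh_rhs(list(V = -65, m = 0.05, n = 0.32, h = 0.6,
#'              flux_Na = 0, flux_K = 0), J_ext = 0)
#' @export
mhh_rhs <- function(state, J_ext, params = neuron_params(),
                    mem = memristor_config(), options = kinetics_options()) {
  s <- as.list(state)
  phi <- temperature_factor(options$temperature)
  d <- .mhh_deriv(c(s$V, s$m, s$n, s$h, s$flux_Na, s$flux_K), J_ext,
                  params, mem, phi, options$beta_m_divisor,
                  options$singularity_epsilon)
  stats::setNames(d, c("V", "m", "n", "h", "flux_Na", "flux_K"))
}
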