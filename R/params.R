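# Parameter containers for the membrane models.

#' Membrane parameters
#'
#' Electrical constants of the space-clamped membrane. Units follow the
#' conventional mixed system in which the membrane equation closes without
#' unit prefixes on the state: capacitance in uF/cm^2, potentials in mV,
#' conductances in mS/cm^2, current densities in mA/cm^2, time in ms, so that
#' `dV/dt = 1000 * (J_ext - J_m) / C` in mV/ms.
#'
#' @param C Membrane capacitance, uF/cm^2.
#' @param E_Na,E_K,E_L Reversal potentials of the sodium, potassium and leak
#'   branches, mV.
#' @param g_Na_max,g_K_max,g_L_max Maximal conductances, mS/cm^2.
#' @param v_rest Resting potential, mV.
#' @return A list of class `memhh_neuron_params`.
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(C = 1, E_Na = 50, E_K = -70, E_L = -50,
                          g_Na_max = 120, g_K_max = 36, g_L_max = 0.3,
                          v_rest = -65) {
  if (!is.numeric(C) || C <= 0) {
    rlang::abort("`C` must be positive.", class = "memhh_invalid_parameter")
  }
  if (any(c(g_Na_max, g_K_max, g_L_max) < 0)) {
    rlang::abort("maximal conductances must be non-negative.",
                 class = "memhh_invalid_parameter")
  }
  structure(
    list(C = C, E_Na = E_Na, E_K = E_K, E_L = E_L,
         g_Na_max = g_Na_max, g_K_max = g_K_max, g_L_max = g_L_max,
         v_rest = v_rest),
    class = "memhh_neuron_params")
}

#' Flux-controlled memristor configuration
#'
#' The memristive variant replaces the two channel conductance scales with
#' flux-controlled memristors whose memristance follows a piecewise-linear
#' law in the flux state phi: a high plateau `M_high`, a descending linear
#' segment, and a low plateau `M_low`, always clipped to
#' `[M_low, M_high]`.
#'
#' Two law variants are provided. `"reconstructed_continuous"` (default) uses
#' slope -3.98e4 Ohm cm^2 per flux unit, intercept 1e4 Ohm cm^2 and
#' breakpoints at -0.25 and +0.25, which joins the plateaus near-continuously
#' and gives M(0) = 10000 Ohm cm^2. `"as_printed"` keeps the published
#' constants (slope -3.98e8, intercept 1e8, lower breakpoint -0.75); its
#' linear segment lies far above `M_high`, so after clipping it degenerates
#' to a step between the plateaus at phi = 0.25. It is retained for
#' comparison.
#'
#' The flux of each memristor integrates the voltage deviation from rest:
#' `dphi/dt = flux_gain * (V - v_rest)`, independently for the Na and K
#' devices unless `shared_flux` is TRUE. `flux_init` selects the initial
#' flux: `"fig8"` starts on the edge of the high plateau (memristance ~
#' `M_high`, matching an initial memductance of 1 / 20000 Ohm^-1 cm^-2) and
#' `"midpoint"` starts at phi = 0 (memristance 10000 Ohm cm^2 under the
#' default law).
#'
#' @param law_variant `"reconstructed_continuous"` or `"as_printed"`.
#' @param M_high,M_low Memristance plateaus, Ohm cm^2.
#' @param slope,intercept Linear-segment coefficients, Ohm cm^2 (per flux
#'   unit for `slope`). Defaults depend on `law_variant`.
#' @param flux_lo,flux_hi Breakpoints of the linear segment, flux units.
#'   Defaults depend on `law_variant`.
#' @param flux_gain Flux gain k, flux units per mV ms.
#' @param shared_flux Share one flux state between the Na and K devices.
#' @param flux_init `"fig8"` (start at `flux_lo`) or `"midpoint"` (start at
#'   phi = 0).
#' @return A list of class `memhh_memristor_config`.
#' @examples
#' memristor_config()
#' memristor_config(law_variant = "as_printed")
#' @export
memristor_config <- function(law_variant = c("reconstructed_continuous", "as_printed"),
                             M_high = 20000, M_low = 100,
                             slope = NULL, intercept = NULL,
                             flux_lo = NULL, flux_hi = NULL,
                             flux_gain = 1e-3, shared_flux = FALSE,
                             flux_init = c("fig8", "midpoint")) {
  law_variant <- match.arg(law_variant)
  flux_init <- match.arg(flux_init)
  if (law_variant == "reconstructed_continuous") {
    if (is.null(slope)) slope <- -3.98e4
    if (is.null(intercept)) intercept <- 1e4
    if (is.null(flux_lo)) flux_lo <- -0.25
    if (is.null(flux_hi)) flux_hi <- 0.25
  } else {
    if (is.null(slope)) slope <- -3.98e8
    if (is.null(intercept)) intercept <- 1e8
    if (is.null(flux_lo)) flux_lo <- -0.75
    if (is.null(flux_hi)) flux_hi <- 0.25
  }
  if (M_low <= 0 || M_high < M_low) {
    rlang::abort("need 0 < M_low <= M_high.", class = "memhh_invalid_parameter")
  }
  if (slope > 0) {
    rlang::abort("`slope` must be <= 0 (memristance is non-increasing in flux).",
                 class = "memhh_invalid_parameter")
  }
  if (flux_hi < flux_lo) {
    rlang::abort("need flux_lo <= flux_hi.", class = "memhh_invalid_parameter")
  }
  structure(
    list(law_variant = law_variant, M_high = M_high, M_low = M_low,
         slope = slope, intercept = intercept,
         flux_lo = flux_lo, flux_hi = flux_hi,
         flux_gain = flux_gain, shared_flux = shared_flux,
         flux_init = flux_init),
    class = "memhh_memristor_config")
}

# Initial flux value implied by the configured preset.
.flux_initial <- function(mem) {
  switch(mem$flux_init, fig8 = mem$flux_lo, midpoint = 0)
}

#' Voltage-clamp protocol
#'
#' An ideal clamp holds the membrane potential at `V_clamp + v_rest` from
#' t = 0 (the clamp value is expressed as an offset above rest, as in the
#' classic experiments).
#'
#' @param V_clamp Clamp offset above the resting potential, mV.
#' @param duration Clamp duration, ms.
#' @return A list of class `memhh_clamp_spec`.
#' @examples
#' clamp_spec(20, 10)
#' @export
clamp_spec <- function(V_clamp, duration = 10) {
  if (!is.numeric(V_clamp) || !is.finite(V_clamp)) {
    rlang::abort("`V_clamp` must be finite.", class = "memhh_invalid_parameter")
  }
  if (!is.numeric(duration) || duration <= 0) {
    rlang::abort("`duration` must be positive.", class = "memhh_invalid_parameter")
  }
  structure(list(V_clamp = V_clamp, duration = duration),
            class = "memhh_clamp_spec")
}
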