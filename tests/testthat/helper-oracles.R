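# Independent oracles used across the suite.

# Forward-Euler integration of the package's right-hand sides: same model,
# independent stepping scheme. Returns V sampled every `keep_every` steps.
euler_voltage <- function(model, stim, params, options,
                          mem = memristor_config(),
                          duration, dt, keep_every) {
  g0 <- resting_gates(params$v_rest, options)
  if (model == "hh") {
    y <- c(V = params$v_rest, m = g0$m, n = g0$n, h = g0$h)
    rhs <- function(y, J) hh_rhs(y, J, params, options)
  } else {
    f0 <- if (mem$flux_init == "fig8") mem$flux_lo else 0
    y <- c(V = params$v_rest, m = g0$m, n = g0$n, h = g0$h,
           flux_Na = f0, flux_K = f0)
    rhs <- function(y, J) mhh_rhs(y, J, params, mem, options)
  }
  nt <- round(duration / dt)
  V <- numeric(nt %/% keep_every + 1)
  V[1] <- y[["V"]]
  j <- 1
  for (i in seq_len(nt)) {
    y <- y + dt * rhs(y, stimulus_value(stim, (i - 1) * dt))
    if (i %% keep_every == 0) {
      j <- j + 1
      V[j] <- y[["V"]]
    }
  }
  V
}

# Quiescent membrane potential: root of the steady-state total ionic
# current, found independently of any time integration.
steady_fixed_point <- function(params, options, lower = -64.9, upper = -30) {
  f <- function(V) {
    s <- gate_steady_tau(rate_constants(V, options))
    g <- channel_conductances(list(m = s$m_inf, n = s$n_inf, h = s$h_inf),
                              params)
    ionic_current_densities(V, g, params)$J_total
  }
  stats::uniroot(f, c(lower, upper), tol = 1e-12)$root
}

# Closed-form gate relaxation under a fixed potential.
clamped_gate <- function(x0, x_inf, tau, t) x_inf + (x0 - x_inf) * exp(-t / tau)

opts_5 <- function() kinetics_options(18.5, beta_m_divisor = 20)
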