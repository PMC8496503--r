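# Declarative stimulus waveforms.
#
# A stimulus spec is data, not code: it serialises into experiment configs and
# is evaluated pointwise by stimulus_value(). Amplitudes are current
# densities in mA/cm^2, times in ms.

new_stimulus <- function(kind, duration, fields) {
  if (!is.numeric(duration) || duration <= 0) {
    rlang::abort("`duration` must be positive.", class = "memhh_config_error")
  }
  structure(c(list(kind = kind, duration = duration), fields),
            class = "memhh_stimulus")
}

#' Stimulus waveforms
#'
#' Constructors for the injected-current protocols used throughout the model
#' comparisons:
#'
#' * `stim_none()` - no injected current.
#' * `stim_constant()` - a constant current density for the whole run.
#' * `stim_pulse()` - a single rectangular pulse (negative amplitudes give
#'   the reverse pulse).
#' * `stim_pulse_train()` - `n_pulses` rectangles starting at `onset`,
#'   repeating with the given `period`.
#' * `stim_sinusoid()` - `amplitude * sin(2 * pi * t / sine_period)`.
#'
#' @param amplitude Current density, mA/cm^2.
#' @param duration Total run duration, ms.
#' @param onset Pulse onset, ms.
#' @param width Pulse width, ms.
#' @param n_pulses Number of pulses in a train.
#' @param period Train period, ms; defaults to `duration / n_pulses`.
#' @param sine_period Period of the sinusoid, ms.
#' @return A list of class `memhh_stimulus`.
#' @examples
#' stim_pulse(0.1, onset = 0.5, width = 0.1, duration = 5)
#' stim_pulse_train(1, n_pulses = 18, duration = 20, width = 0.01)
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_none <- function(duration) new_stimulus("none", duration, list())

#' @rdname stimulus
#' @export
stim_constant <- function(amplitude, duration) {
  new_stimulus("constant", duration, list(amplitude = amplitude))
}

#' @rdname stimulus
#' @export
stim_pulse <- function(amplitude, onset = 0.5, width = 0.1, duration = 5) {
  if (width <= 0 || onset < 0) {
    rlang::abort("pulse needs `width` > 0 and `onset` >= 0.",
                 class = "memhh_config_error")
  }
  new_stimulus("pulse", duration,
               list(amplitude = amplitude, onset = onset, width = width))
}

#' @rdname stimulus
#' @export
stim_pulse_train <- function(amplitude, n_pulses, duration,
                             period = duration / n_pulses,
                             width = period / 2, onset = 0) {
  if (n_pulses < 1 || period <= 0 || width <= 0 || width > period) {
    rlang::abort("train needs n_pulses >= 1, period > 0 and 0 < width <= period.",
                 class = "memhh_config_error")
  }
  new_stimulus("pulse_train", duration,
               list(amplitude = amplitude, n_pulses = as.integer(n_pulses),
                    period = period, width = width, onset = onset))
}

#' @rdname stimulus
#' @export
stim_sinusoid <- function(amplitude, sine_period, duration) {
  if (sine_period <= 0) {
    rlang::abort("`sine_period` must be positive.", class = "memhh_config_error")
  }
  new_stimulus("sinusoid", duration,
               list(amplitude = amplitude, sine_period = sine_period))
}

#' Evaluate a stimulus at given times
#'
#' Pointwise piecewise evaluation of a stimulus spec. Rectangles are
#' half-open: the current is `amplitude` for `onset <= t < onset + width`.
#'
#' @param spec A stimulus created by one of the [stimulus] constructors.
#' @param t Time(s), ms; must be non-negative.
#' @return Current density in mA/cm^2, one value per element of `t`.
#' @examples
#' stimulus_value(stim_pulse(0.1, 0.5, 0.1, 5), c(0.55, 0.7))
#' @export
stimulus_value <- function(spec, t) {
  if (!inherits(spec, "memhh_stimulus")) {
    rlang::abort("`spec` must be a memhh stimulus.", class = "memhh_config_error")
  }
  if (any(t < 0)) {
    rlang::abort("`t` must be non-negative.", class = "memhh_invalid_parameter")
  }
  switch(
    spec$kind,
    none = rep(0, length(t)),
    constant = rep(spec$amplitude, length(t)),
    pulse = ifelse(t >= spec$onset & t < spec$onset + spec$width,
                   spec$amplitude, 0),
    pulse_train = {
      rel <- t - spec$onset
      idx <- floor(rel / spec$period)
      phase <- rel - idx * spec$period
      ifelse(rel >= 0 & idx < spec$n_pulses & phase < spec$width,
             spec$amplitude, 0)
    },
    sinusoid = spec$amplitude * sin(2 * pi * t / spec$sine_period),
    rlang::abort(paste0("unknown stimulus kind: ", spec$kind),
                 class = "memhh_config_error"))
}
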