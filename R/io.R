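# Trace serialisation, experiment configs, presets and analytic fixtures.

TRACE_COLS <- c("t", "V", "m", "n", "h", "g_Na", "g_K",
                "J_Na", "J_K", "J_L", "J_total", "J_ext", "dVdt")

#' Write / read a trace as CSV
#'
#' `write_trace()` stores a simulated trace as plain CSV preceded by
#' `#`-comment header lines holding the run metadata (model variant, step
#' size, and the full protocol as JSON). `read_trace()` restores the trace
#' and its metadata. The round trip preserves all series at full double
#' precision.
#'
#' @param trace A `memhh_trace`.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the `memhh_trace`.
#' @examples
#' tr <- run_current_clamp("hh", stim_constant(0.08, 2))
#' p <- tempfile(fileext = ".csv")
#' write_trace(tr, p)
#' identical(read_trace(p)$V, tr$V)
#' @export
write_trace <- function(trace, path) {
  meta <- trace_meta(trace)
  if (is.null(meta)) {
    rlang::abort("`trace` carries no metadata; was it simulated by memhh?",
                 class = "memhh_invalid_input")
  }
  header <- c(
    "# memhh trace",
    paste0("# model: ", meta$model),
    paste0("# kind: ", meta$kind),
    paste0("# dt: ", format(meta$dt, digits = 17)),
    paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)))
  body <- readr::format_csv(tibble::as_tibble(trace))
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "memhh_parse_error")
  }
  lines <- readLines(path, n = 50L)
  meta_line <- grep("^# meta: ", lines, value = TRUE)
  if (!length(meta_line)) {
    rlang::abort("missing '# meta:' header line.", class = "memhh_parse_error")
  }
  meta <- jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1]))
  tr <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(TRACE_COLS, names(tr))
  if (length(missing)) {
    header_line <- sum(startsWith(lines, "#")) + 1L
    rlang::abort(
      sprintf("line %d: missing column(s): %s", header_line,
              paste(missing, collapse = ", ")),
      class = "memhh_parse_error")
  }
  attr(tr, "memhh_meta") <- meta
  class(tr) <- c("memhh_trace", class(tr))
  tr
}

# ---- experiment configuration ------------------------------------------

.config_keys <- list(
  top = c("name", "model", "temperature", "beta_m_divisor", "v_rest", "dt",
          "params", "memristor", "stimulus", "clamp", "threshold",
          "min_separation"),
  params = c("C", "E_Na", "E_K", "E_L", "g_Na_max", "g_K_max", "g_L_max"),
  memristor = c("law_variant", "M_high", "M_low", "slope", "intercept",
                "flux_lo", "flux_hi", "flux_gain", "shared_flux", "flux_init"),
  stimulus = c("kind", "amplitude", "onset", "width", "n_pulses", "period",
               "sine_period", "duration"),
  clamp = c("V_clamp", "duration"))

.reject_unknown <- function(x, section) {
  bad <- setdiff(names(x), .config_keys[[section]])
  if (length(bad)) {
    rlang::abort(
      sprintf("unknown key(s) in %s: %s",
              if (section == "top") "config" else paste0("'", section, "'"),
              paste(bad, collapse = ", ")),
      class = "memhh_config_error")
  }
}

.build_stimulus <- function(s) {
  .reject_unknown(s, "stimulus")
  if (is.null(s$kind) || is.null(s$duration)) {
    rlang::abort("stimulus needs `kind` and `duration`.",
                 class = "memhh_config_error")
  }
  switch(as.character(s$kind),
    none = stim_none(s$duration),
    constant = stim_constant(s$amplitude, s$duration),
    pulse = do.call(stim_pulse, c(list(amplitude = s$amplitude),
      s[intersect(names(s), c("onset", "width", "duration"))])),
    pulse_train = do.call(stim_pulse_train,
      c(list(amplitude = s$amplitude, n_pulses = s$n_pulses,
             duration = s$duration),
        s[intersect(names(s), c("period", "width", "onset"))])),
    sinusoid = stim_sinusoid(s$amplitude, s$sine_period, s$duration),
    rlang::abort(paste0("unknown stimulus kind: ", s$kind),
                 class = "memhh_config_error"))
}

# Resolve a raw config list into validated component objects with defaults.
.resolve_config <- function(raw) {
  .reject_unknown(raw, "top")
  model <- raw$model %||% "hh"
  if (!model %in% c("hh", "mhh", "both")) {
    rlang::abort("`model` must be hh, mhh or both.",
                 class = "memhh_config_error")
  }
  dt <- raw$dt %||% 0.005
  if (!is.numeric(dt) || dt <= 0) {
    rlang::abort("`dt` must be positive.", class = "memhh_config_error")
  }
  options <- kinetics_options(
    temperature = raw$temperature %||% 6.3,
    v_rest = raw$v_rest %||% -65,
    beta_m_divisor = raw$beta_m_divisor %||% 18)
  p <- raw$params %||% list()
  .reject_unknown(p, "params")
  params <- do.call(neuron_params, c(p, list(v_rest = options$v_rest)))
  m <- raw$memristor %||% list()
  .reject_unknown(m, "memristor")
  mem <- do.call(memristor_config, m)
  if (!is.null(raw$stimulus) && !is.null(raw$clamp)) {
    rlang::abort("give either `stimulus` or `clamp`, not both.",
                 class = "memhh_config_error")
  }
  if (is.null(raw$stimulus) && is.null(raw$clamp)) {
    rlang::abort("config needs a `stimulus` or a `clamp` section.",
                 class = "memhh_config_error")
  }
  protocol <- if (!is.null(raw$stimulus)) {
    .build_stimulus(raw$stimulus)
  } else {
    .reject_unknown(raw$clamp, "clamp")
    clamp_spec(raw$clamp$V_clamp, raw$clamp$duration %||% 10)
  }
  structure(
    list(name = raw$name %||% "unnamed", model = model, dt = dt,
         params = params, options = options, mem = mem, protocol = protocol,
         threshold = raw$threshold %||% 0,
         min_separation = raw$min_separation %||% 1),
    class = "memhh_config")
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description, rejects unknown keys at every level,
#' fills defaults (dt 0.005 ms, threshold 0 mV, min_separation 1 ms,
#' temperature 6.3 C, standard membrane parameters), and returns the
#' resolved configuration. Exactly one of a `stimulus` or a `clamp` section
#' must be present.
#'
#' @param path Path to a YAML config file.
#' @return A `memhh_config` list with components `name`, `model`, `dt`,
#'   `params`, `options`, `mem`, `protocol`, `threshold`, `min_separation`.
#' @seealso [run_config()], [preset_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "memhh_config_error")
  }
  .resolve_config(yaml::read_yaml(path))
}

#' Run a resolved configuration
#'
#' Executes the simulation a config describes. For `model: both` a named
#' list of two traces (`hh`, `mhh`) is returned, otherwise a single trace.
#'
#' @param config A `memhh_config` from [load_config()] or [preset_config()].
#' @return A `memhh_trace`, or `list(hh =, mhh =)` for `model: both`.
#' @export
run_config <- function(config) {
  if (!inherits(config, "memhh_config")) {
    rlang::abort("`config` must be a memhh_config.", class = "memhh_config_error")
  }
  run_one <- function(model) {
    if (inherits(config$protocol, "memhh_clamp_spec")) {
      run_voltage_clamp(model, config$protocol, config$params,
                        config$options, config$mem, dt = config$dt)
    } else {
      run_current_clamp(model, config$protocol, config$params,
                        config$options, config$mem, dt = config$dt)
    }
  }
  if (config$model == "both") {
    list(hh = run_one("hh"), mhh = run_one("mhh"))
  } else {
    run_one(config$model)
  }
}

# ---- presets ------------------------------------------------------------

# Each preset encodes one published protocol exactly once, so tests, the
# acceptance script and users share identical definitions. The section-5
# presets (fig11 onwards) use the as-printed beta_m divisor 20; the earlier
# figures use the canonical divisor 18 (see the vignette for why both
# appear).
.presets <- function() {
  const20 <- function(T, J, bdiv = 18, model = "hh") {
    list(model = model, temperature = T, beta_m_divisor = bdiv,
         stimulus = list(kind = "constant", amplitude = J, duration = 20))
  }
  s5 <- function(amplitude) {
    list(model = "both", temperature = 18.5, beta_m_divisor = 20,
         stimulus = list(kind = "pulse", amplitude = amplitude, onset = 0.5,
                         width = 0.1, duration = 5))
  }
  train <- function(duration) {
    list(model = "both", temperature = 18.5, beta_m_divisor = 20,
         stimulus = list(kind = "pulse_train", amplitude = 1, n_pulses = 18,
                         period = duration / 18, width = 0.01, onset = 0,
                         duration = duration))
  }
  sine <- function(T_in, dt = 0.005) {
    list(model = "both", temperature = 18.5, beta_m_divisor = 20, dt = dt,
         stimulus = list(kind = "sinusoid", amplitude = 0.01,
                         sine_period = T_in, duration = 60))
  }
  clampfig <- function(model, V) {
    list(model = model, temperature = 6.3, beta_m_divisor = 18,
         clamp = list(V_clamp = V, duration = 10))
  }
  pulse7 <- function(width) {
    list(model = "hh", temperature = 6.3, beta_m_divisor = 18,
         stimulus = list(kind = "pulse", amplitude = 0.08, onset = 0,
                         width = width, duration = width + 10))
  }
  list(
    fig5a = const20(6.3, 0.08), fig5b = const20(15, 0.08),
    fig5c = const20(20, 0.08), fig5d = const20(35, 0.08),
    fig5e = const20(-20, 0.08),
    fig6a = const20(18.5, 0.001), fig6b = const20(18.5, 0.01),
    fig6c = const20(18.5, 0.09), fig6d = const20(18.5, 0.2),
    fig7a = pulse7(1), fig7b = pulse7(10), fig7c = pulse7(20),
    fig7d = pulse7(50),
    fig8 = const20(6.3, 0.08, model = "mhh"),
    fig10a = clampfig("hh", 20), fig10b = clampfig("mhh", 20),
    fig10c = clampfig("hh", 80), fig10d = clampfig("mhh", 80),
    fig11 = s5(0.1),
    fig11r = s5(-0.1),
    fig12a = s5(0.5), fig12b = s5(1), fig12c = s5(2),
    fig13 = train(20), fig13b = train(100), fig13c = train(200),
    fig14a = sine(0.01, dt = 5e-4), fig14b = sine(1), fig14c = sine(5),
    fig14d = sine(20), fig14e = sine(60))
}

#' Experiment presets
#'
#' `preset_names()` lists the built-in protocol presets (named after the
#' published figures they reproduce); `preset_config(name)` resolves one
#' into a full validated configuration; `run_preset(name)` resolves and
#' runs it.
#'
#' @param name Preset name, one of `preset_names()`.
#' @return `preset_names()`: character vector. `preset_config()`: a
#'   `memhh_config`. `run_preset()`: a trace or `list(hh =, mhh =)`.
#' @examples
#' preset_names()
#' cfg <- preset_config("fig5a")
#' cfg$options$temperature
#' @export
preset_names <- function() names(.presets())

#' @rdname preset_names
#' @export
preset_config <- function(name) {
  p <- .presets()
  if (!name %in% names(p)) {
    rlang::abort(paste0("unknown preset: ", name,
                        " (see preset_names())"),
                 class = "memhh_config_error")
  }
  raw <- p[[name]]
  raw$name <- name
  .resolve_config(raw)
}

#' @rdname preset_names
#' @export
run_preset <- function(name) run_config(preset_config(name))

# ---- analytic fixtures --------------------------------------------------

#' Analytic trace fixtures
#'
#' Builds small synthetic voltage traces with known structure so the
#' analysis layer can be tested without running a simulation:
#'
#' * `"sine"`: `offset + amplitude * sin(2 pi t / period)`.
#' * `"constant"`: a flat trace at `value`.
#' * `"rectangles"`: `n` rectangular events of height `amplitude` above
#'   `base`, evenly spaced.
#' * `"exp_decay"`: `base + amplitude * exp(-t / tau)`.
#'
#' @param kind Fixture kind.
#' @param amplitude,offset,period,value,base,n,tau,duration,dt Shape
#'   parameters (mV, ms).
#' @return A tibble with columns `t` and `V` on a uniform grid.
#' @examples
#' make_fixture("sine", amplitude = 40, offset = -10, period = 5,
#'              duration = 20)
#' @export
make_fixture <- function(kind = c("sine", "constant", "rectangles", "exp_decay"),
                         amplitude = 40, offset = -10, period = 5,
                         value = -65, base = -65, n = 3, tau = 2,
                         duration = 20, dt = 0.005) {
  kind <- match.arg(kind)
  t <- seq(0, duration, by = dt)
  V <- switch(kind,
    sine = offset + amplitude * sin(2 * pi * t / period),
    constant = rep(value, length(t)),
    rectangles = {
      # each period starts low so every rectangle has a rising edge
      per <- duration / n
      phase <- t %% per
      ifelse(t < duration & phase >= per / 4 & phase < 3 * per / 4,
             base + amplitude, base)
    },
    exp_decay = base + amplitude * exp(-t / tau))
  tibble::tibble(t = t, V = V)
}
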