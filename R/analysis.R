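# Spike detection and trace metrics.
#
# Two operational spike criteria are provided, because the model produces
# both full action potentials (overshooting 0 mV) and trains of damped
# membrane-potential oscillations whose visible maxima sit below 0 mV.
#
# "threshold" (default): a spike is an upward crossing of the threshold
# followed by the local maximum before the next downward crossing. This
# counts full action potentials only and never counts subthreshold bumps.
#
# "prominence": a spike is a local maximum of V whose prominence (height
# above the higher of its two flanking minima) is at least min_prominence.
# This reproduces counting the visible peaks of a damped oscillation on a
# published trace: an action-potential-like event rises tens of mV above its
# surroundings, while post-block ringing stays below a few mV.

.local_extrema <- function(V) {
  d <- diff(V)
  s <- sign(d)
  # treat flat runs as continuation of previous slope
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  ch <- diff(s)
  list(max = which(ch < 0) + 1L, min = which(ch > 0) + 1L)
}

.peak_prominence <- function(V, peaks, mins) {
  vapply(peaks, function(p) {
    lm <- mins[mins < p]; rm_ <- mins[mins > p]
    left <- if (length(lm)) V[max(lm)] else V[1]
    right <- if (length(rm_)) V[min(rm_)] else V[length(V)]
    V[p] - max(left, right)
  }, numeric(1))
}

# Merge peak indices closer than min_separation, keeping the higher peak.
.merge_peaks <- function(t, V, peaks, min_separation) {
  if (length(peaks) < 2) return(peaks)
  keep <- peaks[1]
  for (p in peaks[-1]) {
    last <- keep[length(keep)]
    if (t[p] - t[last] >= min_separation) {
      keep <- c(keep, p)
    } else if (V[p] > V[last]) {
      keep[length(keep)] <- p
    }
  }
  keep
}

# Full width at half maximum of the peak at index p, measured at the level
# halfway between `base` and the peak value.
.fwhm_at <- function(t, V, p, base) {
  half <- (V[p] + base) / 2
  i <- p
  while (i > 1 && V[i] > half) i <- i - 1
  t_left <- if (V[i] > half) t[i] else {
    t[i] + (t[i + 1] - t[i]) * (half - V[i]) / (V[i + 1] - V[i])
  }
  j <- p
  nV <- length(V)
  while (j < nV && V[j] > half) j <- j + 1
  t_right <- if (V[j] > half) t[j] else {
    t[j - 1] + (t[j] - t[j - 1]) * (half - V[j - 1]) / (V[j] - V[j - 1])
  }
  t_right - t_left
}

#' Detect spikes in a voltage trace
#'
#' Finds spike peaks in the `V` series of a trace (or any data frame with
#' columns `t` and `V` on a uniform grid). With `method = "threshold"` a
#' spike is an upward crossing of `threshold` followed by a local maximum
#' before the next downward crossing; peaks closer than `min_separation`
#' are merged, keeping the higher one. With `method = "prominence"` a spike
#' is any local maximum whose prominence is at least `min_prominence` - the
#' criterion that reproduces counting the visible peaks of a damped spike
#' train on a published figure (see the package vignette).
#'
#' @param trace A `memhh_trace` or data frame with columns `t` (ms, uniform
#'   grid) and `V` (mV).
#' @param threshold Spike threshold, mV (threshold method). Default 0.
#' @param min_separation Minimal peak separation, ms. Default 1.
#' @param method `"threshold"` (default) or `"prominence"`.
#' @param min_prominence Minimal peak prominence, mV (prominence method).
#'   Default 10.
#' @return An object of class `memhh_spikes`: a list with `count`,
#'   `peak_times` (ms), `peak_values` (mV), `isi` (ms, length
#'   `max(count - 1, 0)`), `fwhm` (ms), `threshold` and `method`. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' tr <- make_fixture("sine", amplitude = 40, offset = -10,
#'                    period = 5, duration = 20)
#' detect_spikes(tr)$count
#' @export
detect_spikes <- function(trace, threshold = 0, min_separation = 1,
                          method = c("threshold", "prominence"),
                          min_prominence = 10) {
  method <- match.arg(method)
  if (is.null(trace$t) || is.null(trace$V) || nrow(trace) == 0) {
    rlang::abort("`trace` must be non-empty with columns `t` and `V`.",
                 class = "memhh_invalid_input")
  }
  t <- trace$t; V <- trace$V
  ext <- .local_extrema(V)
  if (method == "threshold") {
    n <- length(V)
    up <- which(V[-n] <= threshold & V[-1] > threshold)
    down <- which(V[-n] > threshold & V[-1] <= threshold)
    peaks <- vapply(up, function(u) {
      d <- down[down >= u]
      e <- if (length(d)) d[1] else n
      u - 1L + which.max(V[u:e])
    }, integer(1))
    base <- threshold
  } else {
    prom <- .peak_prominence(V, ext$max, ext$min)
    peaks <- ext$max[prom >= min_prominence]
    base <- NA_real_
  }
  peaks <- .merge_peaks(t, V, peaks, min_separation)
  fwhm <- vapply(peaks, function(p) {
    b <- if (is.na(base)) {
      lm <- ext$min[ext$min < p]
      if (length(lm)) V[max(lm)] else V[1]
    } else base
    .fwhm_at(t, V, p, b)
  }, numeric(1))
  structure(
    list(count = length(peaks),
         peak_times = t[peaks], peak_values = V[peaks],
         isi = if (length(peaks) > 1) diff(t[peaks]) else numeric(0),
         fwhm = fwhm, threshold = threshold, method = method),
    class = "memhh_spikes")
}

#' @export
print.memhh_spikes <- function(x, ...) {
  cat(sprintf("<memhh_spikes> %d spike(s) [%s method]\n", x$count, x$method))
  if (x$count > 0) {
    cat(" peak times (ms):", paste(signif(x$peak_times, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy spike metrics: one row per detected spike
#'
#' @param x A `memhh_spikes` object.
#' @param ... Unused.
#' @return A tibble with columns `spike`, `peak_time`, `peak_value`, `fwhm`.
#' @export
tidy.memhh_spikes <- function(x, ...) {
  tibble::tibble(spike = seq_len(x$count),
                 peak_time = x$peak_times,
                 peak_value = x$peak_values,
                 fwhm = x$fwhm)
}

#' One-row spike summary
#'
#' @param x A `memhh_spikes` object.
#' @param ... Unused.
#' @return A one-row tibble with `count`, `mean_isi`, `mean_fwhm`,
#'   `first_spike_latency`.
#' @export
glance.memhh_spikes <- function(x, ...) spike_stats(x)

#' Summary statistics of detected spikes
#'
#' Mean interspike interval (the between-peak "spike duration" quoted for
#' repetitive traces), mean full width at half maximum, and first-spike
#' latency. ISI statistics are `NA` when fewer than two spikes were
#' detected; the latency is `NA` when none was.
#'
#' @param metrics A `memhh_spikes` object from [detect_spikes()].
#' @return A one-row tibble with `count`, `mean_isi`, `mean_fwhm`,
#'   `first_spike_latency` (ms).
#' @export
spike_stats <- function(metrics) {
  tibble::tibble(
    count = metrics$count,
    mean_isi = if (metrics$count > 1) mean(metrics$isi) else NA_real_,
    mean_fwhm = if (metrics$count > 0) mean(metrics$fwhm) else NA_real_,
    first_spike_latency = if (metrics$count > 0) metrics$peak_times[1] else NA_real_)
}

#' Per-series extrema of a trace
#'
#' Maximum and minimum of every recorded numeric series together with the
#' times at which they occur.
#'
#' @param trace A `memhh_trace` or data frame with a `t` column.
#' @return A tibble with columns `series`, `max`, `t_max`, `min`, `t_min`.
#' @examples
#' tr <- run_voltage_clamp("hh", clamp_spec(20, 10))
#' trace_extrema(tr)
#' @export
trace_extrema <- function(trace) {
  if (is.null(trace$t) || nrow(trace) == 0) {
    rlang::abort("`trace` must be non-empty with a `t` column.",
                 class = "memhh_invalid_input")
  }
  series <- setdiff(names(trace)[vapply(trace, is.numeric, logical(1))], "t")
  purrr::map_dfr(series, function(s) {
    x <- trace[[s]]
    tibble::tibble(series = s,
                   max = max(x), t_max = trace$t[which.max(x)],
                   min = min(x), t_min = trace$t[which.min(x)])
  })
}

#' Compare an HH trace with an MHH trace
#'
#' Tabulates the paired spike counts, peak membrane potentials and times,
#' and peak conductances/currents of two traces recorded under the same
#' protocol, with their differences (MHH minus HH).
#'
#' @param trace_hh,trace_mhh Traces from [run_current_clamp()] /
#'   [run_voltage_clamp()], run under identical protocols.
#' @param ... Passed on to [detect_spikes()] (e.g. `method`).
#' @return A tibble with columns `metric`, `hh`, `mhh`, `delta`.
#' @examples
#' stim <- stim_pulse(0.1, 0.5, 0.1, 5)
#' opts <- kinetics_options(18.5, beta_m_divisor = 20)
#' compare_models(run_current_clamp("hh", stim, options = opts),
#'                run_current_clamp("mhh", stim, options = opts))
#' @export
compare_models <- function(trace_hh, trace_mhh, ...) {
  m1 <- trace_meta(trace_hh); m2 <- trace_meta(trace_mhh)
  if (is.null(m1) || is.null(m2) ||
      !identical(m1$protocol, m2$protocol) ||
      !identical(m1$kind, m2$kind) || !identical(m1$dt, m2$dt)) {
    rlang::abort("traces were not recorded under the same protocol.",
                 class = "memhh_invalid_comparison")
  }
  one <- function(tr) {
    sp <- detect_spikes(tr, ...)
    c(spike_count = sp$count,
      peak_V = max(tr$V), t_peak_V = tr$t[which.max(tr$V)],
      peak_g_Na = max(tr$g_Na), peak_g_K = max(tr$g_K),
      peak_J_K = max(tr$J_K), min_J_Na = min(tr$J_Na),
      min_V = min(tr$V))
  }
  a <- one(trace_hh); b <- one(trace_mhh)
  tibble::tibble(metric = names(a), hh = unname(a), mhh = unname(b),
                 delta = unname(b - a))
}
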