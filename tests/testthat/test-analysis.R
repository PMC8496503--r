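test_that("threshold detection counts analytic sine peaks exactly", {
  # 40 sin(2 pi t / 5) - 10 over 20 ms crosses 0 mV once per 5 ms period
  tr <- make_fixture("sine", amplitude = 40, offset = -10, period = 5,
                     duration = 20)
  sp <- detect_spikes(tr, threshold = 0)
  expect_equal(sp$count, 4)
  expect_equal(sp$peak_times, c(1.25, 6.25, 11.25, 16.25), tolerance = 1e-6)
  expect_equal(sp$peak_values, rep(30, 4), tolerance = 1e-6)
  expect_equal(sp$isi, rep(5, 3), tolerance = 1e-6)
  # prominence criterion agrees on these full-size peaks
  expect_equal(detect_spikes(tr, method = "prominence")$count, 4)
})

test_that("flat and monotone traces contain no spikes", {
  expect_equal(detect_spikes(make_fixture("constant", value = -65))$count, 0)
  expect_equal(detect_spikes(make_fixture("constant", value = -65),
                             method = "prominence")$count, 0)
  decay <- make_fixture("exp_decay", base = -70, amplitude = 30, tau = 3,
                        duration = 10)
  expect_equal(detect_spikes(decay, threshold = -50)$count, 0)
  expect_error(detect_spikes(tibble::tibble(t = numeric(0), V = numeric(0))),
               class = "memhh_invalid_input")
})

test_that("rectangle-train fixtures yield one event per rectangle", {
  tr <- make_fixture("rectangles", n = 3, amplitude = 80, base = -65,
                     duration = 20)
  expect_equal(detect_spikes(tr, threshold = 0)$count, 3)
})

test_that("peaks closer than min_separation merge, keeping the higher one", {
  t <- seq(0, 10, by = 0.005)
  # two bumps 0.4 ms apart (heights 20 and 25), one isolated bump at 7 ms
  V <- -65 +
    85 * exp(-((t - 3.0) / 0.1)^2) +
    90 * exp(-((t - 3.4) / 0.1)^2) +
    80 * exp(-((t - 7.0) / 0.1)^2)
  sp <- detect_spikes(tibble::tibble(t = t, V = V), threshold = 0,
                      min_separation = 1)
  expect_equal(sp$count, 2)
  expect_equal(sp$peak_times[1], 3.4, tolerance = 0.01)
  sp2 <- detect_spikes(tibble::tibble(t = t, V = V), threshold = 0,
                       min_separation = 0.2)
  expect_equal(sp2$count, 3)
})

test_that("detection is invariant to time shift and to 2x subsampling", {
  tr <- run_current_clamp("hh", stim_constant(0.08, 20),
                          options = kinetics_options(15))
  for (method in c("threshold", "prominence")) {
    sp <- detect_spikes(tr, method = method)
    shifted <- dplyr::mutate(tibble::as_tibble(tr), t = t + 5)
    expect_equal(detect_spikes(shifted, method = method)$count, sp$count)
    sub <- tibble::as_tibble(tr)[seq(1, nrow(tr), by = 2), ]
    expect_equal(detect_spikes(sub, method = method)$count, sp$count)
  }
})

test_that("ISIs are positive and sum to the peak span; stats handle empty cases", {
  tr <- run_current_clamp("hh", stim_constant(0.08, 20),
                          options = kinetics_options(15))
  sp <- detect_spikes(tr, method = "prominence")
  expect_true(all(sp$isi > 0))
  expect_equal(sum(sp$isi), max(sp$peak_times) - min(sp$peak_times))
  st <- spike_stats(sp)
  expect_equal(st$count, sp$count)
  expect_equal(st$first_spike_latency, sp$peak_times[1])
  empty <- detect_spikes(make_fixture("constant"))
  expect_equal(empty$isi, numeric(0))
  est <- spike_stats(empty)
  expect_true(is.na(est$mean_isi) && is.na(est$first_spike_latency))
  one <- detect_spikes(make_fixture("exp_decay", base = -65, amplitude = 100,
                                    tau = 0.5, duration = 5))
  expect_true(is.na(spike_stats(one)$mean_isi))
})

test_that("tidy and glance return the documented shapes", {
  tr <- make_fixture("sine", amplitude = 40, offset = -10, period = 5,
                     duration = 20)
  sp <- detect_spikes(tr)
  td <- generics::tidy(sp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_named(td, c("spike", "peak_time", "peak_value", "fwhm"))
  gl <- generics::glance(sp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$count, 4)
})

test_that("trace extrema report per-series max/min with their times", {
  tr <- make_fixture("exp_decay", base = -70, amplitude = 30, tau = 3,
                     duration = 10)
  ex <- trace_extrema(tr)
  v <- ex[ex$series == "V", ]
  expect_equal(v$t_max, 0)          # monotone decay: max at start
  expect_equal(v$t_min, 10)         # ... and min at the final sample
  expect_equal(v$max, -40)
  cl <- run_voltage_clamp("hh", clamp_spec(20, 10))
  exc <- trace_extrema(cl)
  expect_true(all(exc$t_max >= 0 & exc$t_max <= 10))
  expect_true(all(c("g_K", "g_Na", "J_K") %in% exc$series))
})

test_that("any spiking run carries inward sodium and outward potassium current", {
  tr <- run_current_clamp("hh", stim_pulse(0.1, 0.5, 0.1, 5),
                          options = opts_5())
  expect_lt(min(tr$J_Na), 0)
  expect_gt(max(tr$J_K), 0)
})

test_that("reverse pulses hyperpolarise without spiking and the perturbation decays", {
  o <- opts_5()
  rev_stim <- stim_pulse(-0.1, onset = 0.5, width = 0.1, duration = 5)
  for (model in c("hh", "mhh")) {
    tr <- run_current_clamp(model, rev_stim, options = o)
    expect_equal(detect_spikes(tr)$count, 0)
    expect_equal(detect_spikes(tr, method = "prominence")$count, 0)
    expect_lt(min(tr$V), -65)   # transient hyperpolarisation below rest
    # the membrane recovers from the hyperpolarised minimum and stays
    # subthreshold for the rest of the window
    expect_gt(tr$V[nrow(tr)], min(tr$V) + 5)
    expect_lt(max(tr$V), 0)
  }
})

test_that("model comparison pairs metrics and rejects mismatched protocols", {
  o <- opts_5()
  stim <- stim_pulse(0.1, 0.5, 0.1, 5)
  hh <- run_current_clamp("hh", stim, options = o)
  mhh <- run_current_clamp("mhh", stim, options = o)
  cmp <- compare_models(hh, mhh)
  expect_named(cmp, c("metric", "hh", "mhh", "delta"))
  expect_equal(cmp$delta, cmp$mhh - cmp$hh)
  # identical traces: all deltas zero
  cmp0 <- compare_models(hh, hh)
  expect_true(all(cmp0$delta == 0))
  other <- run_current_clamp("mhh", stim_pulse(0.1, 0.5, 0.2, 5), options = o)
  expect_error(compare_models(hh, other), class = "memhh_invalid_comparison")
})
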