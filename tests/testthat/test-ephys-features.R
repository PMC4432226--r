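test_that("detect_spikes handles flat traces, refractory-close peaks, and bad input", {
  pr <- pulse_protocol(onset = 10, duration = 80)
  flat <- trace(rep(-70, 2000), dt = 0.05)
  expect_identical(detect_spikes(flat, pr), numeric(0))
  # two spikes 1 ms apart remain two distinct peaks
  t <- seq(0, 100, by = 0.05)
  v <- -70 + 70 * exp(-(t - 40)^2 / (2 * 0.2^2)) + 65 * exp(-(t - 41)^2 / (2 * 0.2^2))
  sp <- detect_spikes(trace(v, dt = 0.05), pr)
  expect_length(sp, 2)
  expect_equal(sp, c(40, 41), tolerance = 0.06)
  cur <- trace(rep(0, 100), dt = 0.05, kind = "current")
  expect_error(detect_spikes(cur, pr), "voltage")
})

test_that("detect_spikes finds generator spikes at sample resolution", {
  p <- mean_params("FSI")
  pr <- standard_protocols()$train
  g <- gen_interneuron_trace(p, pr, seed = 2)
  sp <- detect_spikes(g$trace, pr)
  expect_equal(sp, g$truth$peaks, tolerance = 0.06)
})

test_that("firing frequencies follow the ISI definitions", {
  pr <- pulse_protocol(onset = 0, duration = 1000)
  # 10 spikes over a 1000 ms pulse
  ff <- firing_frequencies(seq(50, 950, length.out = 10), pr)
  expect_equal(ff$f_total, 10)
  # regular 50-ms ISI train: all instantaneous rates 20 Hz
  ff2 <- firing_frequencies(seq(10, 960, by = 50), pr)
  expect_equal(ff2$f_init, 20)
  expect_equal(ff2$f_200, 20)
  expect_equal(ff2$f_final, 20)
  # first ISI of 25 ms
  ff3 <- firing_frequencies(c(10, 35, 100, 300, 600), pr)
  expect_equal(ff3$f_init, 40)
  # fewer than two spikes: flagged, not zero
  ff4 <- firing_frequencies(c(100), pr)
  expect_false(ff4$complete)
  expect_true(is.na(ff4$f_init))
})

test_that("accommodation follows the percent formulas", {
  expect_equal(unlist(accommodation(40, 30, 30)), c(early = 25, late = 0))
  expect_equal(unlist(accommodation(30, 30, 30)), c(early = 0, late = 0))
  expect_equal(unlist(accommodation(50, 40, 30)), c(early = 20, late = 20))
  expect_error(accommodation(0, 10, 10), "positive")
})

test_that("frequencies and accommodation are invariant to a uniform time shift", {
  base <- seq(110, 1060, by = 38)
  pr <- pulse_protocol(onset = 100, duration = 1000)
  ff <- firing_frequencies(base, pr)
  for (shift in c(-50, 250, 1000)) {
    pr2 <- pulse_protocol(onset = 100 + shift, duration = 1000)
    ff2 <- firing_frequencies(base + shift, pr2)
    expect_equal(ff2, ff)
  }
})

test_that("spike threshold errors on a pure ramp", {
  t <- seq(0, 100, by = 0.05)
  ramp <- trace(-70 + 0.3 * t, dt = 0.05)
  expect_error(spike_threshold(ramp, 80), "no derivative doubling|not localized")
})

test_that("spike amplitude and reduction are simple differences", {
  tr <- gaussian_spike_trace(amp = 70, peak_t = 50)
  expect_equal(spike_amplitude(tr, 50, -36), (-70 + 70) - -36)
  expect_equal(amplitude_reduction(70, 64.7), 100 * (70 - 64.7) / 70)
  expect_equal(amplitude_reduction(70, 70), 0)
})

test_that("Gaussian FWHM identity holds to < 0.1% and scales with sigma", {
  for (sigma in c(0.5, 1.0)) {
    tr <- gaussian_spike_trace(amp = 70, sigma = sigma)
    d <- spike_duration(tr, 50, -70 + 1e-9)
    expect_equal(d, 2 * sqrt(2 * log(2)) * sigma, tolerance = 1e-3)
  }
  d1 <- spike_duration(gaussian_spike_trace(sigma = 0.5), 50, -70 + 1e-9)
  d2 <- spike_duration(gaussian_spike_trace(sigma = 1.0), 50, -70 + 1e-9)
  expect_equal(d2 / d1, 2, tolerance = 1e-3)
})

test_that("duration increase formula and fit failure behave as specified", {
  expect_equal(duration_increase(1.37, 1.46), 100 * (1.46 - 1.37) / 1.37)
  # 6.57% is consistent with the tabulated values given rounding
  expect_equal(duration_increase(1.37, 1.46), 6.569, tolerance = 1e-3)
  # degenerate segment (threshold just below the peak): diagnostic error
  tr <- gaussian_spike_trace(amp = 70, sigma = 0.5)
  expect_error(spike_duration(tr, 50, -0.01), "curvature|too few")
})

test_that("AHP metrics recover a parabolic trough analytically", {
  t <- seq(0, 100, by = 0.05)
  thr <- -40
  w <- 8 # parabola reaches threshold at +/- w around the trough
  v <- rep(thr + 5, length(t))
  spike <- 60 * exp(-(t - 30)^2 / (2 * 0.4^2))
  par <- -12 * pmax(0, 1 - ((t - 45) / w)^2)
  tr <- trace(v + spike + par, dt = 0.05)
  m <- ahp_metrics(tr, 30, thr + 5)
  expect_false(m$missing)
  expect_equal(m$ahp, -12, tolerance = 1e-3)
  expect_equal(m$peak_to_ahp, 15, tolerance = 0.06)
  # half depth at (t-45)/w = 1/sqrt(2): FWHM = sqrt(2) * w
  expect_equal(m$ahp_width, sqrt(2) * w, tolerance = 0.01)
  # monotonic repolarization to rest above threshold: flagged missing
  mono <- trace(thr + 5 + 60 * exp(-(t - 30)^2 / (2 * 0.4^2)), dt = 0.05)
  expect_true(ahp_metrics(mono, 30, thr)$missing)
})

test_that("AP slopes match the analytic sinusoid derivative", {
  a <- 30
  omega <- 2 * pi / 10 # per ms
  t <- seq(0, 40, by = 0.01)
  tr <- trace(a * sin(omega * t) - 40, dt = 0.01)
  sl <- ap_slopes(tr, 2.5, window_ms = 10)
  expect_equal(sl$depol, a * omega, tolerance = 0.01)
  expect_equal(sl$hyperpol, -a * omega, tolerance = 0.01)
  expect_error(ap_slopes(trace(rep(-70, 4001), dt = 0.01), 20), "flat")
})

test_that("AP slopes of a template match a finite-difference oracle", {
  g <- gen_interneuron_trace(mean_params("FSI"), standard_protocols()$waveform,
                             seed = 9)
  sp <- detect_spikes(g$trace, standard_protocols()$waveform)
  sl <- ap_slopes(g$trace, sp[1])
  t <- trace_times(g$trace)
  sel <- which(abs(t - sp[1]) <= 10)
  d_or <- diff(g$trace$samples[sel]) / g$trace$dt
  expect_equal(sl$depol, max(d_or), tolerance = 0.01)
  expect_equal(sl$hyperpol, min(d_or), tolerance = 0.01)
})

test_that("input resistance from steady-state deflection", {
  pr <- pulse_protocol(holding = -60, amplitude = -200, onset = 100, duration = 500)
  t <- seq(0, 800, by = 0.05)
  dv <- -40 # mV at steady state -> 200 MOhm
  v <- rep(-60, length(t))
  inp <- t >= 100 & t <= 600
  v[inp] <- -60 + dv * (1 - exp(-(t[inp] - 100) / 15))
  v[t > 600] <- -60 + dv * exp(-(t[t > 600] - 600) / 15)
  expect_equal(input_resistance(trace(v, dt = 0.05), pr), 200, tolerance = 1e-3)
  expect_error(input_resistance(trace(v, dt = 0.05),
                                pulse_protocol(amplitude = 0)), "zero current")
})

test_that("RC-model input resistance recovers 400 MOhm within 0.5%", {
  p <- mean_params("FSI")
  p$means[["r_in"]] <- 400
  g <- gen_interneuron_trace(p, standard_protocols()$hyper, seed = 21)
  r <- input_resistance(g$trace, standard_protocols()$hyper)
  expect_lt(abs(r - 400) / 400, 0.005)
})

test_that("extract_feature_set flags what it cannot compute", {
  # single-spike waveform trace: second-spike features missing
  p <- mean_params("FSI")
  cell <- gen_interneuron_cell(p, seed = 30)
  short <- cell$traces
  # truncate the waveform trace before the second spike
  wt <- short$waveform
  keep <- trace_times(wt) < 160
  short$waveform <- trace(wt$samples[keep], dt = wt$dt)
  fs <- extract_feature_set(short, cell$protocols)
  expect_true(is.na(fs$a2))
  expect_true("a2" %in% attr(fs, "missing"))
  # only the AHP can vote: a single definite vote is not enough to label
  expect_identical(as.character(classify_interneuron(fs)), "ambiguous")
})
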