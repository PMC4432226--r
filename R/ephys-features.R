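# Extraction of the 19 electrophysiological parameters from current-clamp
# traces: four firing frequencies, two accommodation indices, spike
# threshold, two amplitudes and their reduction, two durations and their
# increase, AHP depth/width/latency, the two AP slopes, and input resistance.

#' Detect action-potential peaks within a protocol step
#'
#' Local maxima above `min_height` inside the step window, with a minimum
#' peak separation enforced by keeping the larger of two competing maxima.
#'
#' @param tr voltage `ng2_trace`.
#' @param protocol `ng2_protocol` whose step must overlap the trace.
#' @param min_height minimum peak voltage (mV) to count as a spike.
#' @param min_sep minimum separation between peaks (ms).
#' @return ordered numeric vector of spike peak times (ms); empty if none.
#' @export
detect_spikes <- function(tr, protocol, min_height = -10, min_sep = 0.5) {
  check_that(inherits(tr, "ng2_trace"), "tr must be an ng2_trace")
  check_that(tr$kind == "voltage", "spike detection needs a voltage trace")
  t <- trace_times(tr)
  v <- tr$samples
  w_end <- protocol$onset + protocol$duration
  check_that(protocol$onset < max(t) && w_end > min(t), "protocol step does not overlap trace")
  inw <- which(t >= protocol$onset & t <= w_end)
  if (length(inw) < 3) return(numeric(0))
  vi <- v[inw]
  core <- 2:(length(vi) - 1)
  is_pk <- vi[core] > vi[core - 1] & vi[core] >= vi[core + 1] & vi[core] >= min_height
  pk_idx <- inw[core[is_pk]]
  if (!length(pk_idx)) return(numeric(0))
  # enforce minimum separation, preferring the taller peak
  keep <- integer(0)
  for (i in pk_idx) {
    if (length(keep) && (t[i] - t[keep[length(keep)]]) < min_sep) {
      if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  t[keep]
}

#' Firing frequencies of a spike train
#'
#' `f_total` is the spike count divided by the pulse duration. The three
#' instantaneous rates are reciprocals of interspike intervals: the first
#' ISI (`f_init`), the ISI containing the time point 200 ms after pulse
#' onset (`f_200`), and the last ISI (`f_final`). With fewer than two
#' spikes the instantaneous rates are undefined and returned as `NA` with
#' `complete = FALSE` rather than silently zero.
#'
#' @param spike_times spike peak times in ms.
#' @param protocol the `ng2_protocol` of the pulse.
#' @return list with `f_total`, `f_init`, `f_200`, `f_final` (Hz),
#'   `n_spikes`, and logical `complete`.
#' @export
firing_frequencies <- function(spike_times, protocol) {
  n <- length(spike_times)
  f_total <- 1000 * n / protocol$duration
  if (n < 2) {
    return(list(f_total = f_total, f_init = NA_real_, f_200 = NA_real_,
                f_final = NA_real_, n_spikes = n, complete = FALSE))
  }
  isi <- diff(spike_times)
  t200 <- protocol$onset + 200
  i200 <- which(spike_times[-n] <= t200 & spike_times[-1] > t200)
  f_200 <- if (length(i200)) 1000 / isi[i200[1]] else NA_real_
  list(
    f_total = f_total,
    f_init = 1000 / isi[1],
    f_200 = f_200,
    f_final = 1000 / isi[n - 1],
    n_spikes = n,
    complete = !is.na(f_200)
  )
}

#' Early and late spike-frequency accommodation (percent)
#'
#' Early accommodation is `100 * (f_init - f_200) / f_init`; late
#' accommodation is `100 * (f_200 - f_final) / f_init`.
#'
#' @param f_init,f_200,f_final instantaneous frequencies in Hz.
#' @return list with `early` and `late` in percent.
#' @export
accommodation <- function(f_init, f_200, f_final) {
  check_that(is.finite(f_init) && f_init > 0, "f_init must be positive")
  list(
    early = 100 * (f_init - f_200) / f_init,
    late = 100 * (f_200 - f_final) / f_init
  )
}

# derivative-doubling search shared by threshold code: baseline derivative is
# the median |dV/dt| over a 5-ms window well before the peak, floored at
# 1 mV/ms; walking back from the peak, the threshold sample is the last one
# (nearest the onset) at which dV/dt still exceeds twice that level.
threshold_index <- function(t, v, dv, peak_idx, dt) {
  b0 <- peak_idx - round(16 / dt)
  b1 <- peak_idx - round(11 / dt)
  walk_lo <- peak_idx - round(10 / dt)
  check_that(b0 >= 1, "not enough pre-spike baseline for threshold estimation")
  level <- 2 * max(stats::median(abs(dv[b0:b1])), 1)
  i <- peak_idx
  # skip the low-slope cap around the peak itself
  while (i > walk_lo && dv[i - 1] <= level) i <- i - 1
  check_that(i > walk_lo, "no derivative doubling found before peak (no spike?)")
  # then walk down the steep flank to its foot
  while (i > walk_lo && dv[i - 1] > level) i <- i - 1
  check_that(i > walk_lo, "spike onset not localized within search window")
  i
}

#' Spike threshold by the derivative-doubling rule
#'
#' The threshold is the voltage at the sample, nearest the spike onset, where
#' dV/dt first exceeds twice the pre-spike baseline derivative (median
#' |dV/dt| over a 5-ms window ending 3 ms before the peak, floored at
#' 1 mV/ms).
#'
#' @param tr voltage `ng2_trace`.
#' @param spike_time spike peak time (ms).
#' @return threshold voltage (mV).
#' @export
spike_threshold <- function(tr, spike_time) {
  check_that(tr$kind == "voltage", "need a voltage trace")
  t <- trace_times(tr)
  v <- tr$samples
  pk <- which.min(abs(t - spike_time))
  dv <- deriv_dt(v, tr$dt)
  v[threshold_index(t, v, dv, pk, tr$dt)]
}

#' Spike amplitude from threshold to peak
#' @param tr voltage `ng2_trace`.
#' @param spike_time spike peak time (ms).
#' @param threshold threshold voltage (mV), e.g. from [spike_threshold()].
#' @return amplitude in mV.
#' @export
spike_amplitude <- function(tr, spike_time, threshold) {
  t <- trace_times(tr)
  pk <- which.min(abs(t - spike_time))
  tr$samples[pk] - threshold
}

#' Spike-amplitude reduction between the first two spikes (percent)
#' @param a1,a2 first and second spike amplitudes (mV).
#' @return `100 * (a1 - a2) / a1`.
#' @export
amplitude_reduction <- function(a1, a2) {
  check_that(a1 > 0, "first spike amplitude must be positive")
  100 * (a1 - a2) / a1
}

#' Spike-duration increase between the first two spikes (percent)
#' @param d1,d2 first and second spike durations (ms).
#' @return `100 * (d2 - d1) / d1`.
#' @export
duration_increase <- function(d1, d2) {
  check_that(d1 > 0, "first spike duration must be positive")
  100 * (d2 - d1) / d1
}

#' Spike duration as Gaussian-fit FWHM of the depolarized face
#'
#' Fits a Gaussian to the above-threshold segment around the peak. For a
#' Gaussian bump the fit is exact: regressing `log(V - threshold)` on a
#' quadratic in time recovers sigma in closed form, and
#' FWHM = 2*sqrt(2*log(2)) * sigma.
#'
#' @param tr voltage `ng2_trace`.
#' @param spike_time spike peak time (ms).
#' @param threshold threshold voltage (mV).
#' @return FWHM duration in ms.
#' @export
spike_duration <- function(tr, spike_time, threshold) {
  t <- trace_times(tr)
  v <- tr$samples
  pk <- which.min(abs(t - spike_time))
  check_that(v[pk] > threshold, "spike peak must lie above threshold")
  # rising (depolarizing) face: contiguous above-threshold samples up to the
  # peak; the falling face is skipped because the incipient AHP distorts it
  lo <- pk
  while (lo > 1 && v[lo - 1] > threshold) lo <- lo - 1
  seg <- lo:pk
  # keep samples with appreciable height so log() is well conditioned
  amp <- v[pk] - threshold
  use <- seg[v[seg] - threshold > 0.05 * amp]
  check_that(length(use) >= 5, "too few above-threshold samples for a Gaussian fit")
  x <- t[use]
  y <- log(v[use] - threshold)
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  c2 <- fit$coefficients[3]
  check_that(is.finite(c2) && c2 < 0,
             "Gaussian fit failed: non-negative curvature of log-waveform")
  sigma <- sqrt(-1 / (2 * unname(c2)))
  FWHM_SIGMA * sigma
}

#' After-hyperpolarization depth, width and latency
#'
#' Depth is the trough voltage minus threshold (negative by convention),
#' width is the FWHM of the hyperpolarizing lobe (crossings of the level
#' halfway between threshold and trough, linearly interpolated), and
#' latency is trough time minus peak time. If the trace never falls below
#' threshold after the spike, the AHP is flagged missing.
#'
#' @param tr voltage `ng2_trace`.
#' @param spike_time spike peak time (ms).
#' @param threshold threshold voltage (mV).
#' @param search_ms window after the peak searched for the trough.
#' @return list with `ahp` (mV), `ahp_width` (ms), `peak_to_ahp` (ms) and
#'   logical `missing`.
#' @export
ahp_metrics <- function(tr, spike_time, threshold, search_ms = 80) {
  t <- trace_times(tr)
  v <- tr$samples
  pk <- which.min(abs(t - spike_time))
  hi <- min(length(v), pk + round(search_ms / tr$dt))
  # trough = minimum after the downstroke crosses threshold
  below <- which(v[pk:hi] < threshold)
  if (!length(below)) {
    return(list(ahp = NA_real_, ahp_width = NA_real_, peak_to_ahp = NA_real_,
                missing = TRUE))
  }
  start <- pk + below[1] - 1
  # limit to the contiguous below-threshold lobe
  end <- start
  while (end < hi && v[end + 1] < threshold) end <- end + 1
  lobe <- start:end
  tr_idx <- lobe[which.min(v[lobe])]
  depth <- v[tr_idx] - threshold
  half <- threshold + depth / 2
  # half-crossing times on both flanks of the trough
  li <- tr_idx
  while (li > start && v[li - 1] < half) li <- li - 1
  ri <- tr_idx
  while (ri < end && v[ri + 1] < half) ri <- ri + 1
  t_left <- if (li > 1) cross_time(t, v, li - 1, half) else t[li]
  t_right <- if (ri < length(v)) cross_time(t, v, ri, half) else t[ri]
  list(
    ahp = depth,
    ahp_width = t_right - t_left,
    peak_to_ahp = t[tr_idx] - t[pk],
    missing = FALSE
  )
}

#' Maximal depolarizing and hyperpolarizing slopes of an AP waveform
#'
#' Maximum and minimum of the centered finite-difference dV/dt over a window
#' around the spike peak.
#'
#' @param tr voltage `ng2_trace`.
#' @param spike_time spike peak time (ms).
#' @param window_ms half-width of the analysis window around the peak.
#' @return list with `depol` and `hyperpol` in mV/ms.
#' @export
ap_slopes <- function(tr, spike_time, window_ms = 10) {
  t <- trace_times(tr)
  pk <- which.min(abs(t - spike_time))
  lo <- max(1, pk - round(window_ms / tr$dt))
  hi <- min(length(tr$samples), pk + round(window_ms / tr$dt))
  check_that(hi - lo >= 4, "window too short for slope estimation")
  seg <- tr$samples[lo:hi]
  check_that(max(seg) - min(seg) > 1, "no spike in slope window (flat trace)")
  dv <- deriv_dt(seg, tr$dt)
  list(depol = max(dv), hyperpol = min(dv))
}

#' Input resistance from a hyperpolarizing step
#'
#' Steady-state voltage deflection divided by the current step. The steady
#' state is the mean over the final 20% of the step; the baseline is the
#' 20 ms preceding the step.
#'
#' @param tr voltage `ng2_trace`.
#' @param protocol the hyperpolarizing `ng2_protocol`; amplitude must be
#'   non-zero.
#' @return input resistance in MOhm.
#' @export
input_resistance <- function(tr, protocol) {
  check_that(protocol$amplitude != 0, "zero current step: input resistance undefined")
  t <- trace_times(tr)
  v <- tr$samples
  base <- v[t >= protocol$onset - 20 & t < protocol$onset]
  check_that(length(base) > 0, "no pre-step baseline in trace")
  end <- protocol$onset + protocol$duration
  ss <- v[t >= end - 0.2 * protocol$duration & t <= end]
  check_that(length(ss) > 0, "step window not contained in trace")
  dv <- mean(ss) - mean(base)
  1000 * dv / protocol$amplitude # mV / pA -> MOhm
}

#' Extract the full 19-parameter feature set for one cell
#'
#' Frequencies and accommodation come from the long train trace, waveform
#' features from the first two APs of the short suprathreshold trace, and
#' input resistance from the hyperpolarizing trace. Features that cannot be
#' computed are returned as `NA` and listed in the `missing` attribute.
#'
#' @param traces named list with `train`, `waveform`, `hyper` voltage traces
#'   (as from [gen_interneuron_cell()]).
#' @param protocols named list of matching `ng2_protocol`s.
#' @return an object of class `ng2_feature_set`: a named list of the 19
#'   parameters.
#' @export
extract_feature_set <- function(traces, protocols) {
  fs <- list(
    f_total = NA_real_, f_init = NA_real_, f_200 = NA_real_, f_final = NA_real_,
    early_accom = NA_real_, late_accom = NA_real_,
    threshold = NA_real_, a1 = NA_real_, a2 = NA_real_, amp_reduction = NA_real_,
    d1 = NA_real_, d2 = NA_real_, dur_increase = NA_real_,
    ahp = NA_real_, ahp_width = NA_real_, peak_to_ahp = NA_real_,
    depol_slope = NA_real_, hyperpol_slope = NA_real_, r_in = NA_real_
  )
  # frequencies from the long pulse
  st <- detect_spikes(traces$train, protocols$train)
  ff <- firing_frequencies(st, protocols$train)
  fs$f_total <- ff$f_total
  fs$f_init <- ff$f_init
  fs$f_200 <- ff$f_200
  fs$f_final <- ff$f_final
  if (ff$complete && ff$f_init > 0) {
    acc <- accommodation(ff$f_init, ff$f_200, ff$f_final)
    fs$early_accom <- acc$early
    fs$late_accom <- acc$late
  }
  # waveform features from the first two APs of the short pulse
  sw <- detect_spikes(traces$waveform, protocols$waveform)
  if (length(sw) >= 2) {
    s1 <- sw[1]; s2 <- sw[2]
    th <- try(spike_threshold(traces$waveform, s1), silent = TRUE)
    if (!inherits(th, "try-error")) {
      fs$threshold <- th
      fs$a1 <- spike_amplitude(traces$waveform, s1, th)
      d1 <- try(spike_duration(traces$waveform, s1, th), silent = TRUE)
      if (!inherits(d1, "try-error")) fs$d1 <- d1
      am <- ahp_metrics(traces$waveform, s1, th)
      if (!am$missing) {
        fs$ahp <- am$ahp
        fs$ahp_width <- am$ahp_width
        fs$peak_to_ahp <- am$peak_to_ahp
      }
      sl <- ap_slopes(traces$waveform, s1)
      fs$depol_slope <- sl$depol
      fs$hyperpol_slope <- sl$hyperpol
      th2 <- try(spike_threshold(traces$waveform, s2), silent = TRUE)
      if (!inherits(th2, "try-error")) {
        fs$a2 <- spike_amplitude(traces$waveform, s2, th2)
        d2 <- try(spike_duration(traces$waveform, s2, th2), silent = TRUE)
        if (!inherits(d2, "try-error")) fs$d2 <- d2
      }
      if (is.finite(fs$a1) && is.finite(fs$a2) && fs$a1 > 0) {
        fs$amp_reduction <- amplitude_reduction(fs$a1, fs$a2)
      }
      if (is.finite(fs$d1) && is.finite(fs$d2) && fs$d1 > 0) {
        fs$dur_increase <- duration_increase(fs$d1, fs$d2)
      }
    }
  }
  # input resistance
  if (!is.null(traces$hyper)) {
    fs$r_in <- input_resistance(traces$hyper, protocols$hyper)
  }
  miss <- names(fs)[!vapply(fs, function(x) is.finite(x), logical(1))]
  structure(fs, class = "ng2_feature_set", missing = miss)
}

#' @export
print.ng2_feature_set <- function(x, ...) {
  cat("<ng2_feature_set>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}
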