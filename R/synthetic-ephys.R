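# Synthetic current-clamp traces for interneuron phenotyping.
#
# Spikes are built from an analytic template, not a conductance model: the
# depolarized face is a Gaussian bump anchored at the spike threshold (so the
# FWHM-from-Gaussian-fit duration is an explicit template parameter), and the
# after-hyperpolarization is an asymmetric Gaussian lobe (fast fall to the
# trough, slow recovery) whose depth, FWHM and peak-to-trough latency are
# likewise explicit parameters. Every extracted waveform feature is therefore
# a known function of generator inputs, which gives the closed-loop ground
# truth the feature-extraction tests rely on.

#' Electrophysiological class parameters for an interneuron population
#'
#' Bundles the per-class population means and dispersions (between-cell SDs)
#' for the generator, plus fixed waveform-shape constants that are not drawn
#' per cell.
#'
#' @param label class label, `"FSI"` or `"NFSI"`.
#' @param means named numeric vector with elements `amp` (first spike
#'   amplitude, threshold to peak, mV), `dur` (first spike duration, FWHM,
#'   ms), `ahp` (AHP depth, trough minus threshold, mV, negative),
#'   `dur_increase` (spike-duration increase, %), `amp_reduction`
#'   (spike-amplitude reduction, %), `early_accom` (early accommodation, %),
#'   `r_in` (input resistance, MOhm), `rate` (firing rate at +200 pA, Hz).
#' @param disp named numeric vector of non-negative dispersions (SD) for the
#'   same elements.
#' @param shape list of fixed shape constants: `threshold` (mV), `ahp_width`
#'   (AHP FWHM, ms), `latency` (AP peak to AHP trough, ms), `late_accom`
#'   (late accommodation, %), `finit_factor` (F_init / F_total).
#' @return an object of class `ng2_ephys_params`.
#' @export
ephys_class_params <- function(label, means, disp, shape) {
  fields <- c("amp", "dur", "ahp", "dur_increase", "amp_reduction",
              "early_accom", "r_in", "rate")
  check_that(label %in% c("FSI", "NFSI"), "label must be 'FSI' or 'NFSI'")
  check_that(all(fields %in% names(means)), "means is missing required fields")
  check_that(all(fields %in% names(disp)), "disp is missing required fields")
  check_that(all(disp[fields] >= 0), "dispersions must be >= 0")
  check_that(means[["ahp"]] < 0, "AHP depth must be negative (trough below threshold)")
  check_that(means[["dur"]] > 0 && means[["amp"]] > 0, "amplitude and duration must be positive")
  structure(
    list(label = label, means = means[fields], disp = disp[fields], shape = shape),
    class = "ng2_ephys_params"
  )
}

#' Default fast-spiking interneuron parameters
#'
#' Population means follow the characterized FSI group (deep AHP, negligible
#' spike broadening and amplitude reduction during trains, low input
#' resistance). Dispersions of the three discriminative features (AHP depth,
#' duration increase, amplitude reduction) default to 35% of the
#' between-class gap so the two stated populations are marginally separable;
#' remaining dispersions are the population SDs implied by the reported
#' standard errors.
#'
#' @return an `ng2_ephys_params` object.
#' @export
fsi_params <- function() {
  ephys_class_params(
    "FSI",
    means = c(
      amp = 70.73, dur = 1.37, ahp = -15.89, dur_increase = 6.79,
      amp_reduction = -0.24, early_accom = 14.14, r_in = 208.22, rate = 28.32
    ),
    disp = c(
      amp = 2.33 * sqrt(27), dur = 0.10 * sqrt(27),
      ahp = 0.35 * abs(-15.89 - -8.43),
      dur_increase = 0.35 * abs(55.06 - 6.79),
      amp_reduction = 0.35 * abs(7.59 - -0.24),
      early_accom = 3.61 * sqrt(27), r_in = 17.97 * sqrt(27),
      rate = 2.73 * sqrt(27)
    ),
    shape = list(
      threshold = -35.68, ahp_width = 25.57, latency = 7.18,
      late_accom = 11.43, finit_factor = 37.12 / 28.32
    )
  )
}

#' Default non-fast-spiking interneuron parameters
#'
#' Broad spikes that widen and shrink during trains, shallow AHP, high input
#' resistance. See [fsi_params()] for the dispersion convention.
#'
#' @return an `ng2_ephys_params` object.
#' @export
nfsi_params <- function() {
  ephys_class_params(
    "NFSI",
    means = c(
      amp = 70.61, dur = 2.41, ahp = -8.43, dur_increase = 55.06,
      amp_reduction = 7.59, early_accom = 39.33, r_in = 399.96, rate = 24.18
    ),
    disp = c(
      amp = 1.09 * sqrt(105), dur = 0.10 * sqrt(105),
      ahp = 0.35 * abs(-15.89 - -8.43),
      dur_increase = 0.35 * abs(55.06 - 6.79),
      amp_reduction = 0.35 * abs(7.59 - -0.24),
      early_accom = 1.85 * sqrt(105), r_in = 19.75 * sqrt(105),
      rate = 0.93 * sqrt(105)
    ),
    shape = list(
      threshold = -36.31, ahp_width = 21.53, latency = 13.85,
      late_accom = 8.87, finit_factor = 45.29 / 24.18
    )
  )
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

# draw one cell's parameter values; clamps keep pathological tails out of
# the template's geometric validity range
draw_cell_params <- function(params) {
  z <- stats::rnorm(length(params$means))
  v <- params$means + params$disp * z
  v[["amp"]] <- max(v[["amp"]], 35)
  v[["dur"]] <- min(max(v[["dur"]], 0.5), 4.5)
  v[["ahp"]] <- min(v[["ahp"]], -1)
  v[["dur_increase"]] <- max(v[["dur_increase"]], 100 * (0.5 / v[["dur"]] - 1))
  v[["amp_reduction"]] <- min(v[["amp_reduction"]], 100 * (1 - 35 / v[["amp"]]))
  v[["r_in"]] <- max(v[["r_in"]], 50)
  v[["rate"]] <- min(max(v[["rate"]], 8), 60)
  v
}

# half-width per sigma at half maximum: FWHM of an asymmetric Gaussian with
# flank sigmas (sl, sr) is HALF_SIGMA * (sl + sr)
HALF_SIGMA <- sqrt(2 * log(2))

# slope of the linear "ignition" segment that launches each spike from the
# threshold level (mV/ms); must exceed twice the floored baseline derivative
# so the derivative-doubling rule localizes the spike onset
IGNITION_SLOPE <- 4

# distance from the peak (ms) at which the Gaussian face's own slope equals
# the ignition slope; the linear segment takes over beyond it
ignition_x1 <- function(amp, sigma) {
  f <- function(x) amp * (x / sigma^2) * exp(-x^2 / (2 * sigma^2)) - IGNITION_SLOPE
  stats::uniroot(f, c(sigma, 10 * sigma), tol = 1e-10)$root
}

# Assemble a voltage trace containing spikes at given peak times.
# peaks: spike peak times (ms); amp/dur: per-spike vectors. Each spike is a
# Gaussian depolarized face whose rising flank is replaced, below the point
# where its slope falls under IGNITION_SLOPE, by a straight ignition segment
# reaching exactly the threshold level; an asymmetric-Gaussian AHP lobe
# follows, reshaped after its half-recovery point so the trace is back at
# threshold when the next spike starts.
build_spike_trace <- function(peaks, amp, dur, v_thr, ahp, ahp_width, latency,
                              holding, onset, pulse_end, total_dur, dt) {
  t <- seq(0, total_dur, by = dt)
  n <- length(t)
  sig_l <- latency / 3.5
  sig_r <- max(ahp_width / HALF_SIGMA - sig_l, 1)
  # baseline: holding -> threshold plateau during the pulse -> holding
  v <- rep(holding, n)
  in_pulse <- t >= onset
  v[in_pulse] <- v_thr + (holding - v_thr) * exp(-(t[in_pulse] - onset) / 1)
  post <- t > pulse_end
  v[post] <- holding + (v_thr - holding) * exp(-(t[post] - pulse_end) / 10)

  k_n <- length(peaks)
  sigma <- dur / FWHM_SIGMA
  x1 <- vapply(seq_len(k_n), function(k) ignition_x1(amp[k], sigma[k]), numeric(1))
  g_x1 <- amp * exp(-x1^2 / (2 * sigma^2))
  x_on <- x1 + g_x1 / IGNITION_SLOPE
  onsets <- peaks - x_on
  for (k in seq_len(k_n)) {
    anchor <- if (k < k_n) onsets[k + 1] - 1 else t[n]
    seg <- t > onsets[k] & t <= anchor
    x <- t[seg]
    # depolarized face with ignition segment on the rising flank
    face <- amp[k] * exp(-(x - peaks[k])^2 / (2 * sigma[k]^2))
    ign <- x < peaks[k] - x1[k]
    face[ign] <- pmax(g_x1[k] - IGNITION_SLOPE * ((peaks[k] - x1[k]) - x[ign]), 0)
    # AHP lobe
    t_tr <- peaks[k] + latency
    t_half <- min(t_tr + HALF_SIGMA * sig_r, anchor)
    lobe <- ifelse(
      x <= t_tr,
      exp(-(x - t_tr)^2 / (2 * sig_l^2)),
      exp(-(x - t_tr)^2 / (2 * sig_r^2))
    )
    if (k < k_n && anchor > t_half) {
      tau_rec <- (anchor - t_half) / 4
      v_half <- exp(-(t_half - t_tr)^2 / (2 * sig_r^2))
      late <- x > t_half
      lobe[late] <- v_half * exp(-(x[late] - t_half) / tau_rec)
    }
    v[seg] <- v[seg] + face + ahp * lobe
  }
  trace(v, dt = dt, kind = "voltage")
}

# spike peak times for a long suprathreshold pulse: instantaneous rate decays
# exponentially from F_init to F_final, passing through F_200 at 200 ms
train_spike_times <- function(onset, duration, f_total, early_accom, late_accom,
                              finit_factor, min_isi = 18) {
  f_init <- f_total * finit_factor
  f_200 <- f_init * (1 - early_accom / 100)
  f_final <- f_200 - late_accom * f_init / 100
  f_final <- max(f_final, 2)
  f_200 <- max(f_200, f_final + 0.1)
  f_init <- max(f_init, f_200 + 0.1)
  tau <- 200 / log((f_init - f_final) / (f_200 - f_final))
  peaks <- onset + 12
  repeat {
    tk <- peaks[length(peaks)] - onset
    rate <- f_final + (f_init - f_final) * exp(-tk / tau)
    nxt <- peaks[length(peaks)] + max(1000 / rate, min_isi)
    if (nxt - onset > duration - 5) break
    peaks <- c(peaks, nxt)
  }
  peaks
}

#' Generate a synthetic interneuron current-clamp trace
#'
#' Three protocol regimes are recognised: a hyperpolarizing step (negative
#' amplitude) yields a passive RC response used for input resistance; a short
#' depolarizing step (duration <= 150 ms) yields the two-spike waveform
#' protocol used for spike-morphology features; a long depolarizing step
#' yields a full accommodating train used for the frequency features.
#'
#' @param params an `ng2_ephys_params` object (see [fsi_params()]).
#' @param protocol an `ng2_protocol`; its duration must be positive.
#' @param seed integer seed; same seed and parameters give a bit-identical
#'   trace.
#' @param dt sampling interval in ms (default 0.05, i.e. 20 kHz).
#' @param membrane_tau passive membrane time constant in ms for the RC
#'   regime.
#' @return a list with elements `trace` (an `ng2_trace`) and `truth`, a list
#'   recording the exact per-spike parameter values used (peak times,
#'   amplitudes, durations, threshold, AHP depth/width/latency, realized
#'   instantaneous frequencies, input resistance).
#' @export
gen_interneuron_trace <- function(params, protocol, seed = NULL, dt = 0.05,
                                  membrane_tau = 15) {
  check_that(inherits(params, "ng2_ephys_params"), "params must be ng2_ephys_params")
  check_that(inherits(protocol, "ng2_protocol"), "protocol must be ng2_protocol")
  check_that(protocol$duration > 0, "protocol step duration must be positive")
  check_that(dt <= 0.05, "sampling interval must be <= 0.05 ms")
  with_seed(seed, {
    v <- draw_cell_params(params)
    sh <- params$shape
    onset <- protocol$onset
    pulse_end <- onset + protocol$duration

    if (protocol$amplitude < 0) {
      # passive RC response to a hyperpolarizing step
      total <- pulse_end + 4 * membrane_tau + 100
      t <- seq(0, total, by = dt)
      dv <- v[["r_in"]] * protocol$amplitude * 1e-3 # MOhm * pA -> mV
      volt <- rep(protocol$holding, length(t))
      in_p <- t >= onset & t <= pulse_end
      volt[in_p] <- protocol$holding + dv * (1 - exp(-(t[in_p] - onset) / membrane_tau))
      post <- t > pulse_end
      v_end <- protocol$holding + dv * (1 - exp(-protocol$duration / membrane_tau))
      volt[post] <- protocol$holding +
        (v_end - protocol$holding) * exp(-(t[post] - pulse_end) / membrane_tau)
      return(list(
        trace = trace(volt, dt = dt, kind = "voltage"),
        truth = list(mode = "rc", r_in = v[["r_in"]], membrane_tau = membrane_tau,
                     params = v, label = params$label)
      ))
    }

    a1 <- v[["amp"]]
    a2 <- a1 * (1 - v[["amp_reduction"]] / 100)
    d1 <- v[["dur"]]
    d2 <- d1 * (1 + v[["dur_increase"]] / 100)

    if (protocol$duration <= 150) {
      # waveform protocol: two spikes, 50 ms apart
      peaks <- onset + c(20, 70)
      check_that(max(peaks) < pulse_end, "waveform protocol too short for two spikes")
      amp <- c(a1, a2)
      dur <- c(d1, d2)
    } else {
      peaks <- train_spike_times(
        onset, protocol$duration, v[["rate"]], v[["early_accom"]],
        sh$late_accom, sh$finit_factor, min_isi = sh$latency + 6
      )
      amp <- c(a1, rep(a2, length(peaks) - 1))
      dur <- c(d1, rep(d2, length(peaks) - 1))
    }
    # align peaks to the sample grid so ground truth is exact
    peaks <- round(peaks / dt) * dt
    total <- pulse_end + 150
    tr <- build_spike_trace(
      peaks, amp, dur, sh$threshold, v[["ahp"]], sh$ahp_width, sh$latency,
      protocol$holding, onset, pulse_end, total, dt
    )
    isi <- diff(peaks)
    truth <- list(
      mode = if (protocol$duration <= 150) "waveform" else "train",
      label = params$label,
      peaks = peaks, amp = amp, dur = dur,
      threshold = sh$threshold, ahp = v[["ahp"]],
      ahp_width = sh$ahp_width, latency = sh$latency,
      amp_reduction = 100 * (amp[1] - amp[2]) / amp[1],
      dur_increase = 100 * (dur[2] - dur[1]) / dur[1],
      f_total = 1000 * length(peaks) / protocol$duration,
      f_init = if (length(isi)) 1000 / isi[1] else NA_real_,
      f_final = if (length(isi)) 1000 / isi[length(isi)] else NA_real_,
      params = v
    )
    list(trace = tr, truth = truth)
  })
}

#' Standard protocol set for feature extraction
#'
#' The long 200 pA pulse drives the frequency/accommodation features, the
#' short 80 ms suprathreshold pulse drives the waveform features, and the
#' -200 pA hyperpolarizing pulse from -60 mV drives the input resistance.
#'
#' @return a named list of `ng2_protocol` objects (`train`, `waveform`,
#'   `hyper`).
#' @export
standard_protocols <- function() {
  list(
    train = pulse_protocol(holding = -70, amplitude = 200, onset = 100, duration = 1000),
    waveform = pulse_protocol(holding = -70, amplitude = 200, onset = 100, duration = 80),
    hyper = pulse_protocol(holding = -60, amplitude = -200, onset = 100, duration = 500)
  )
}

#' Generate the full three-protocol recording for one cell
#'
#' @param params an `ng2_ephys_params` object.
#' @param seed integer seed.
#' @return list with `traces` (named list of `ng2_trace`), `protocols`, and
#'   `truth` (ground truth of the train trace plus `r_in`).
#' @export
gen_interneuron_cell <- function(params, seed = NULL) {
  with_seed(seed, {
    pr <- standard_protocols()
    # independent sub-seeds drawn from the seeded stream
    s <- sample.int(2^31 - 2, 3)
    train <- gen_interneuron_trace(params, pr$train, seed = s[1])
    wave <- gen_interneuron_trace(params, pr$waveform, seed = s[1]) # same cell draw
    hyper <- gen_interneuron_trace(params, pr$hyper, seed = s[1])
    list(
      traces = list(train = train$trace, waveform = wave$trace, hyper = hyper$trace),
      protocols = pr,
      truth = list(
        label = params$label,
        train = train$truth, waveform = wave$truth, r_in = hyper$truth$r_in
      )
    )
  })
}
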