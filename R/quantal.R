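# Detection and quantal analysis of unitary postsynaptic currents in
# paired-recording sweeps: 2xSD event detection, connection summaries,
# kinetics fits, paired-pulse recovery, single- vs double-release-site
# classification, and benzodiazepine (DZP) modulation.

#' Baseline noise SD of a sweep
#'
#' @param sweep a sweep list with a current `trace` (as produced by
#'   [gen_paired_sweeps()]), or an `ng2_trace`.
#' @param baseline_window numeric length-2, window in ms over which to
#'   compute the SD; must lie inside the trace.
#' @return noise SD in pA.
#' @export
noise_sd <- function(sweep, baseline_window = c(0, 45)) {
  tr <- if (inherits(sweep, "ng2_trace")) sweep else sweep$trace
  t <- trace_times(tr)
  check_that(baseline_window[1] >= min(t) && baseline_window[2] <= max(t),
             "baseline window lies outside the trace")
  sel <- t >= baseline_window[1] & t <= baseline_window[2]
  check_that(sum(sel) >= 2, "baseline window too short")
  stats::sd(tr$samples[sel])
}

# peak (signed, most negative for inward events) of a lightly smoothed
# segment, measured relative to the local pre-window baseline (mean over the
# 2.5 ms just before `from_ms`); the local baseline removes the decay tail
# of any preceding event. Smoothing over ~0.5 ms tames single-sample noise
# excursions while the detection threshold stays on the raw-noise scale.
response_peak <- function(tr, from_ms, to_ms, smooth_ms = 0.5) {
  t <- trace_times(tr)
  sel <- which(t >= from_ms & t <= to_ms)
  check_that(length(sel) >= 3, "response window outside trace")
  sm <- smooth_boxcar(tr$samples, max(1L, round(smooth_ms / tr$dt)))
  pre <- which(t >= from_ms - 2.5 & t < from_ms - 0.25)
  base <- if (length(pre) >= 2) mean(tr$samples[pre]) else 0
  i <- sel[which.max(abs(sm[sel] - base))]
  list(amp = sm[i] - base, t = t[i], idx = i)
}

#' Detect the paired-pulse PSC events of one sweep
#'
#' For each stimulus, the response is the extremum of the (lightly smoothed)
#' current within the response window after the pulse; the event is a
#' failure when the extremum magnitude is below twice the raw baseline
#' noise SD. Failure amplitudes are recorded as 0.
#'
#' @param sweep a sweep list with `trace` and `stim_times`.
#' @param noise_sd baseline noise SD in pA; must be positive unless
#'   `zero_noise = TRUE`.
#' @param window response window after each stimulus, ms (default 1 to 20).
#' @param zero_noise set `TRUE` to allow a noiseless sweep (any non-zero
#'   response then counts as detected).
#' @return data.frame with one row per pulse: `pulse`, `amplitude` (pA,
#'   0 for failures), `peak_amplitude` (pre-thresholding extremum),
#'   `latency` (ms from stimulus), `is_failure`.
#' @export
detect_psc <- function(sweep, noise_sd, window = c(1, 20), zero_noise = FALSE) {
  check_that(zero_noise || noise_sd > 0,
             "noise_sd must be positive (or set zero_noise = TRUE)")
  thr <- 2 * noise_sd
  out <- lapply(seq_along(sweep$stim_times), function(k) {
    s <- sweep$stim_times[k]
    pk <- response_peak(sweep$trace, s + window[1], s + window[2])
    fail <- abs(pk$amp) < thr || (zero_noise && pk$amp == 0)
    data.frame(
      pulse = k,
      amplitude = if (fail) 0 else pk$amp,
      peak_amplitude = pk$amp,
      latency = pk$t - s,
      is_failure = fail
    )
  })
  do.call(rbind, out)
}

#' Detect events across all sweeps of a paired recording
#'
#' @param ps an `ng2_paired_sweeps` object with rendered traces.
#' @param baseline_window window for the per-recording noise estimate (ms).
#' @param window response window (ms after each stimulus).
#' @return data.frame with columns `sweep`, `pulse`, `amplitude`,
#'   `peak_amplitude`, `latency`, `is_failure`.
#' @export
detect_psc_all <- function(ps, baseline_window = c(0, 45), window = c(1, 20)) {
  check_that(!is.null(ps$sweeps), "paired sweeps were generated without rendered traces")
  sds <- vapply(ps$sweeps, noise_sd, numeric(1), baseline_window = baseline_window)
  sd0 <- stats::median(sds)
  rows <- lapply(seq_along(ps$sweeps), function(i) {
    ev <- detect_psc(ps$sweeps[[i]], sd0, window = window, zero_noise = sd0 == 0)
    ev$sweep <- i
    ev
  })
  out <- do.call(rbind, rows)
  attr(out, "noise_sd") <- sd0
  out[, c("sweep", "pulse", "amplitude", "peak_amplitude", "latency", "is_failure")]
}

#' Is a set of sweeps a unitary connection?
#'
#' A connection is accepted when the averaged sweep shows a PSC larger than
#' twice the SD of the averaged trace's baseline.
#'
#' @param sweeps list of sweep lists (each with `trace` and `stim_times`).
#' @param baseline_window baseline window (ms).
#' @param window response window after each stimulus (ms).
#' @return logical.
#' @export
is_unitary_connection <- function(sweeps, baseline_window = c(0, 45),
                                  window = c(1, 20)) {
  check_that(length(sweeps) > 0, "empty sweep list")
  mat <- vapply(sweeps, function(s) s$trace$samples,
                numeric(length(sweeps[[1]]$trace$samples)))
  avg <- trace(rowMeans(as.matrix(mat)), dt = sweeps[[1]]$trace$dt, kind = "current")
  sd_avg <- noise_sd(list(trace = avg), baseline_window)
  s1 <- sweeps[[1]]$stim_times[1]
  pk <- response_peak(avg, s1 + window[1], s1 + window[2])
  abs(pk$amp) > 2 * sd_avg
}

#' Summarize a detected paired-pulse connection
#'
#' Means with failures (failures count as 0 pA), means without failures,
#' coefficient of variation of non-failure PSC1 amplitudes, response
#' probabilities, and the paired-pulse ratio PPR = mean PSC2 / mean PSC1.
#' By default PPR uses with-failure means; set `ppr_failures = FALSE` for
#' the without-failure convention.
#'
#' @param events event table from [detect_psc_all()].
#' @param ppr_failures logical; use with-failure means for the PPR?
#' @return list of class `ng2_connection_summary`.
#' @export
summarize_connection <- function(events, ppr_failures = TRUE) {
  e1 <- events[events$pulse == 1, ]
  e2 <- events[events$pulse == 2, ]
  check_that(nrow(e1) > 0 && nrow(e2) > 0, "need events for both pulses")
  m1w <- mean(e1$amplitude)
  m2w <- mean(e2$amplitude)
  nf1 <- e1$amplitude[!e1$is_failure]
  nf2 <- e2$amplitude[!e2$is_failure]
  m1 <- if (length(nf1)) mean(nf1) else NA_real_
  m2 <- if (length(nf2)) mean(nf2) else NA_real_
  den1 <- if (ppr_failures) m1w else m1
  den2 <- if (ppr_failures) m2w else m2
  check_that(is.finite(den1) && den1 != 0, "mean PSC1 is zero: PPR undefined")
  structure(
    list(
      mean_with_failures = c(psc1 = m1w, psc2 = m2w),
      mean_without_failures = c(psc1 = m1, psc2 = m2),
      cv = if (length(nf1) > 1) stats::sd(nf1) / abs(mean(nf1)) else NA_real_,
      p1 = mean(!e1$is_failure),
      p2 = mean(!e2$is_failure),
      ppr = den2 / den1,
      n_sweeps = nrow(e1)
    ),
    class = "ng2_connection_summary"
  )
}

#' Rise time and decay time constant of a PSC waveform
#'
#' `t10_90` is the 10--90% rise time on the rising phase (linear
#' interpolation); the decay time constant is a single-exponential fit to
#' the segment starting where the decay falls to 90% of the peak
#' (log-linear least squares with nonlinear refinement).
#'
#' @param x numeric waveform starting at (or before) event onset; inward
#'   events are negative.
#' @param dt sampling interval (ms).
#' @param fit_ms length of the decay segment to fit (ms).
#' @return list with `t10_90` and `decay_tau` (ms).
#' @export
fit_kinetics <- function(x, dt, fit_ms = 50) {
  check_that(length(x) >= 8, "waveform too short for kinetics")
  ext <- x[which.max(abs(x))]
  check_that(ext != 0, "flat waveform")
  y <- if (ext < 0) -x else x # flip so the event is positive
  pk <- which.max(y)
  check_that(pk >= 3, "waveform shorter than its rising phase")
  t <- (seq_along(y) - 1) * dt
  a <- y[pk]
  # rising phase crossings
  up <- y[1:pk]
  i10 <- which(up >= 0.1 * a)[1]
  i90 <- which(up >= 0.9 * a)[1]
  check_that(!is.na(i10) && !is.na(i90) && i10 > 1,
             "rising phase not contained in waveform")
  t10 <- cross_time(t, up, i10 - 1, 0.1 * a)
  t90 <- cross_time(t, up, i90 - 1, 0.9 * a)
  # decay segment from 90% of peak
  post <- y[pk:length(y)]
  j <- which(post <= 0.9 * a)[1]
  check_that(!is.na(j), "decay phase not contained in waveform")
  j0 <- pk + j - 1
  j1 <- min(length(y), j0 + round(fit_ms / dt))
  seg <- j0:j1
  pos <- seg[y[seg] > 0.02 * a]
  check_that(length(pos) >= 5, "too few decay samples to fit")
  co <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))$coefficients
  tau0 <- -1 / co[2]
  amp0 <- exp(co[1])
  fit <- try(
    stats::nls(
      yy ~ A * exp(-tt / tau),
      data = list(yy = y[pos], tt = t[pos]),
      start = list(A = amp0, tau = tau0)
    ),
    silent = TRUE
  )
  tau <- if (inherits(fit, "try-error")) tau0 else stats::coef(fit)[["tau"]]
  check_that(is.finite(tau) && tau > 0, "decay fit did not converge")
  list(t10_90 = t90 - t10, decay_tau = tau)
}

#' Paired-pulse recovery curve across interstimulus intervals
#'
#' @param sweep_groups named list: one `ng2_paired_sweeps` (rendered) per
#'   interstimulus interval; names are the ISIs in ms.
#' @param ppr_failures passed to [summarize_connection()].
#' @return data.frame with `isi_ms`, `ppr`, `n`.
#' @export
recovery_curve <- function(sweep_groups, ppr_failures = TRUE) {
  check_that(length(sweep_groups) > 0, "no sweep groups")
  rows <- lapply(names(sweep_groups), function(nm) {
    ev <- detect_psc_all(sweep_groups[[nm]])
    sm <- summarize_connection(ev, ppr_failures = ppr_failures)
    data.frame(isi_ms = as.numeric(nm), ppr = sm$ppr, n = sm$n_sweeps)
  })
  out <- do.call(rbind, rows)
  out[order(out$isi_ms), ]
}

#' Classify a connection as single or double vesicular release
#'
#' Quantal reading of a paired-pulse experiment: failures excluded, the
#' PSC1 and PSC2 amplitude distributions are compared with a two-sample
#' Kolmogorov-Smirnov test and the response probabilities with a
#' two-proportion chi-square test (no continuity correction), both at
#' `alpha`. One release site is inferred when the amplitude distributions
#' are indistinguishable while PSC1 responds significantly more often; two
#' sites when both differ. Discordant patterns are returned as
#' `"indeterminate"`, never coerced. Requires at least `min_sweeps` sweeps.
#'
#' @param events event table from [detect_psc_all()].
#' @param alpha significance level for both tests.
#' @param min_sweeps minimum sweeps required (default 100).
#' @return list of class `ng2_quantal_result` with `n_sites` (1, 2 or NA),
#'   `verdict`, `ks_stat`, `ks_p`, `prob_p`, `quantal_size` (mean
#'   non-failure PSC amplitude under the 1-site reading, else NA),
#'   `mean_nf1`, `mean_nf2`, `p1`, `p2`, `n_sweeps`.
#' @export
classify_release_sites <- function(events, alpha = 0.05, min_sweeps = 100) {
  n_sweeps <- length(unique(events$sweep[events$pulse == 1]))
  check_that(
    n_sweeps >= min_sweeps,
    sprintf("quantal analysis requires >= %d sweeps, got %d", min_sweeps, n_sweeps)
  )
  e1 <- events[events$pulse == 1, ]
  e2 <- events[events$pulse == 2, ]
  nf1 <- e1$amplitude[!e1$is_failure]
  nf2 <- e2$amplitude[!e2$is_failure]
  check_that(length(nf1) >= 1 && length(nf2) >= 1,
             "need at least one non-failure response per pulse")
  ks <- suppressWarnings(stats::ks.test(nf1, nf2))
  tab <- rbind(
    c(sum(!e1$is_failure), sum(e1$is_failure)),
    c(sum(!e2$is_failure), sum(e2$is_failure))
  )
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  amps_differ <- ks$p.value < alpha
  probs_differ <- chi$p.value < alpha
  p1 <- mean(!e1$is_failure)
  p2 <- mean(!e2$is_failure)
  verdict <- if (!amps_differ && probs_differ && p1 > p2) "single"
    else if (amps_differ && probs_differ) "double"
    else "indeterminate"
  n_sites <- switch(verdict, single = 1L, double = 2L, NA_integer_)
  q <- if (identical(verdict, "single")) mean(c(nf1, nf2)) else NA_real_
  structure(
    list(
      n_sites = n_sites, verdict = verdict,
      ks_stat = unname(ks$statistic), ks_p = ks$p.value,
      prob_p = chi$p.value,
      quantal_size = q,
      mean_nf1 = mean(nf1), mean_nf2 = mean(nf2),
      p1 = p1, p2 = p2, n_sweeps = n_sweeps
    ),
    class = "ng2_quantal_result"
  )
}

#' Benzodiazepine (DZP) modulation of a connection
#'
#' Compares non-failure amplitudes between control and DZP conditions
#' (fold-change of means plus a Mann-Whitney test) and the paired-pulse
#' ratios (difference plus a seeded bootstrap test on the with-failure mean
#' ratio).
#'
#' @param control,dzp event tables from [detect_psc_all()].
#' @param n_boot bootstrap replicates for the PPR test.
#' @param seed seed for the bootstrap.
#' @return list with `amp_fold_change`, `amp_p`, `ppr_control`, `ppr_dzp`,
#'   `ppr_p`.
#' @export
dzp_effect <- function(control, dzp, n_boot = 2000, seed = 1) {
  check_that(nrow(control) > 0 && nrow(dzp) > 0, "empty condition")
  nf_c <- control$amplitude[control$pulse == 1 & !control$is_failure]
  nf_d <- dzp$amplitude[dzp$pulse == 1 & !dzp$is_failure]
  check_that(length(nf_c) >= 2 && length(nf_d) >= 2,
             "need non-failure PSC1 responses in both conditions")
  amp_p <- suppressWarnings(stats::wilcox.test(nf_c, nf_d))$p.value
  fold <- mean(nf_d) / mean(nf_c)
  ppr_of <- function(ev) summarize_connection(ev)$ppr
  ppr_c <- ppr_of(control)
  ppr_d <- ppr_of(dzp)
  sweep_amps <- function(ev, pulse) {
    e <- ev[ev$pulse == pulse, ]
    e$amplitude[order(e$sweep)]
  }
  c1 <- sweep_amps(control, 1); c2 <- sweep_amps(control, 2)
  d1 <- sweep_amps(dzp, 1); d2 <- sweep_amps(dzp, 2)
  boot_ppr <- function(a1, a2) {
    i <- sample.int(length(a1), replace = TRUE)
    mean(a2[i]) / mean(a1[i])
  }
  ppr_p <- with_seed(seed, {
    diffs <- replicate(n_boot, boot_ppr(d1, d2) - boot_ppr(c1, c2))
    # two-sided bootstrap p: does the interval exclude 0?
    2 * min(mean(diffs <= 0), mean(diffs >= 0))
  })
  list(
    amp_fold_change = fold, amp_p = amp_p,
    ppr_control = ppr_c, ppr_dzp = ppr_d, ppr_p = min(ppr_p, 1)
  )
}
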