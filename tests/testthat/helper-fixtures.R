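# Shared fixture builders; everything is generated in code at test time.

# zero-dispersion class parameters (population means exactly)
mean_params <- function(label = "FSI") {
  p <- if (label == "FSI") fsi_params() else nfsi_params()
  p$disp[] <- 0
  p
}

# a synthetic voltage trace with one Gaussian spike on a flat baseline
gaussian_spike_trace <- function(amp = 70, sigma = 0.6, baseline = -70,
                                 peak_t = 50, total = 100, dt = 0.05) {
  t <- seq(0, total, by = dt)
  trace(baseline + amp * exp(-(t - peak_t)^2 / (2 * sigma^2)), dt = dt,
        kind = "voltage")
}

# one noiseless rendered sweep with chosen clean amplitudes (pA, negative)
manual_sweep <- function(a1, a2, noise_sd = 0, dt = 0.05, seed = 1) {
  stim <- c(50, 100)
  tt <- seq(0, 200, by = dt)
  sig <- a1 * psc_kernel(tt - (stim[1] + 1.5)) + a2 * psc_kernel(tt - (stim[2] + 1.5))
  if (noise_sd > 0) {
    sig <- sig + with_seed_test(seed, stats::rnorm(length(tt), 0, noise_sd))
  }
  list(trace = trace(sig, dt = dt, kind = "current"), stim_times = stim)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# event table in the detect_psc_all format built directly from amplitudes
events_from_amps <- function(amp1, amp2, threshold = 0) {
  n <- length(amp1)
  rbind(
    data.frame(sweep = seq_len(n), pulse = 1, amplitude = amp1,
               peak_amplitude = amp1, latency = 3,
               is_failure = abs(amp1) <= threshold),
    data.frame(sweep = seq_len(n), pulse = 2, amplitude = amp2,
               peak_amplitude = amp2, latency = 3,
               is_failure = abs(amp2) <= threshold)
  )
}
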