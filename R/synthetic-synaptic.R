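# Paired-pulse postsynaptic current sweeps under a 1- or 2-site binomial
# vesicular release model.

#' Binomial release model parameters
#'
#' One or two release sites; each site releases independently with
#' probability `p1` on the first pulse and `p2 < p1` on the second
#' (paired-pulse depression). Each released vesicle contributes a fixed
#' quantal current `q` (negative, inward); recording noise is additive
#' Gaussian.
#'
#' @param n_sites number of release sites, 1 or 2.
#' @param p1,p2 per-site release probabilities for pulse 1 and pulse 2;
#'   `0 <= p2 < p1 <= 1`.
#' @param q quantal size in pA, negative.
#' @param noise_sd baseline current noise SD in pA.
#' @param rise_tau,decay_tau PSC kinetics in ms.
#' @param n_sweeps number of sweeps, at least 1.
#' @param interpulse paired-pulse interval in ms.
#' @param intersweep interval between sweeps in s (metadata only).
#' @return an object of class `ng2_release_params`.
#' @export
release_model_params <- function(n_sites = 1, p1 = 0.6, p2 = 0.35, q = -7.71,
                                 noise_sd = 1.5, rise_tau = 0.568,
                                 decay_tau = 12.7, n_sweeps = 200,
                                 interpulse = 50, intersweep = 8) {
  check_that(n_sites %in% c(1, 2), "n_sites must be 1 or 2")
  check_that(p1 >= 0 && p1 <= 1 && p2 >= 0 && p2 <= 1 && p2 < p1,
             "release probabilities must satisfy 0 <= p2 < p1 <= 1")
  check_that(q < 0, "quantal size q must be negative (inward current)")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  check_that(n_sweeps >= 1, "n_sweeps must be >= 1")
  check_that(interpulse > 0, "interpulse must be positive (ms)")
  structure(
    list(n_sites = n_sites, p1 = p1, p2 = p2, q = q, noise_sd = noise_sd,
         rise_tau = rise_tau, decay_tau = decay_tau, n_sweeps = n_sweeps,
         interpulse = interpulse, intersweep = intersweep),
    class = "ng2_release_params"
  )
}

#' Biexponential PSC kernel, normalized to unit peak
#'
#' `w(t) = (exp(-t/decay_tau) - exp(-t/rise_tau)) / w(t_peak)` for `t >= 0`.
#'
#' @param t time from event onset (ms), vector.
#' @param rise_tau,decay_tau time constants in ms, `rise_tau < decay_tau`.
#' @return kernel values (unit peak).
#' @export
psc_kernel <- function(t, rise_tau = 0.568, decay_tau = 12.7) {
  check_that(rise_tau > 0 && decay_tau > rise_tau,
             "need 0 < rise_tau < decay_tau")
  t_peak <- log(decay_tau / rise_tau) / (1 / rise_tau - 1 / decay_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / peak
  out
}

#' Generate paired-pulse sweeps under the binomial release model
#'
#' Per sweep and pulse, the number of released vesicles is a
#' `Binomial(n_sites, p_k)` draw and the clean PSC amplitude is that count
#' times `q`. With `render = TRUE` each sweep is also rendered as a
#' current trace: biexponential events at a fixed 1.5-ms synaptic latency
#' after each stimulus, plus white Gaussian noise of SD `noise_sd`. With
#' `render = FALSE` only the amplitude table is produced (amplitudes then
#' carry Gaussian measurement noise of SD `noise_sd` directly), which is
#' much cheaper for large Monte-Carlo runs.
#'
#' @param params an `ng2_release_params`.
#' @param seed integer seed.
#' @param render logical; render full current traces?
#' @param dt sampling interval (ms) for rendered traces.
#' @return a list of class `ng2_paired_sweeps` with elements `sweeps` (when
#'   rendered: list of per-sweep lists with `trace`, `stim_times`), `truth`
#'   (data.frame: sweep, vesicles1, vesicles2, amp1, amp2 clean amplitudes),
#'   `stim_times`, and `params`.
#' @export
gen_paired_sweeps <- function(params, seed = NULL, render = TRUE, dt = 0.05) {
  check_that(inherits(params, "ng2_release_params"), "params must be ng2_release_params")
  with_seed(seed, {
    n <- params$n_sweeps
    k1 <- stats::rbinom(n, params$n_sites, params$p1)
    k2 <- stats::rbinom(n, params$n_sites, params$p2)
    a1 <- k1 * params$q
    a2 <- k2 * params$q
    stim <- c(50, 50 + params$interpulse)
    latency <- 1.5
    truth <- data.frame(sweep = seq_len(n), vesicles1 = k1, vesicles2 = k2,
                        amp1 = a1, amp2 = a2)
    if (!render) {
      meas <- truth
      meas$amp1 <- meas$amp1 + stats::rnorm(n, 0, params$noise_sd)
      meas$amp2 <- meas$amp2 + stats::rnorm(n, 0, params$noise_sd)
      return(structure(
        list(sweeps = NULL, truth = truth, measured = meas,
             stim_times = stim, params = params),
        class = "ng2_paired_sweeps"
      ))
    }
    total <- stim[2] + 100
    tt <- seq(0, total, by = dt)
    kern1 <- psc_kernel(tt - (stim[1] + latency), params$rise_tau, params$decay_tau)
    kern2 <- psc_kernel(tt - (stim[2] + latency), params$rise_tau, params$decay_tau)
    sweeps <- vector("list", n)
    for (i in seq_len(n)) {
      sig <- a1[i] * kern1 + a2[i] * kern2
      if (params$noise_sd > 0) sig <- sig + stats::rnorm(length(tt), 0, params$noise_sd)
      sweeps[[i]] <- list(
        trace = trace(sig, dt = dt, kind = "current"),
        stim_times = stim
      )
    }
    structure(
      list(sweeps = sweeps, truth = truth, stim_times = stim, params = params),
      class = "ng2_paired_sweeps"
    )
  })
}
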