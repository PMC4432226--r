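test_that("noise_sd measures the baseline and validates its window", {
  sw <- manual_sweep(0, 0)
  expect_equal(noise_sd(sw), 0)
  sw2 <- manual_sweep(0, 0, noise_sd = 2, seed = 3)
  expect_equal(noise_sd(sw2), 2, tolerance = 0.2)
  expect_error(noise_sd(sw, baseline_window = c(-50, 10)), "outside")
})

test_that("detect_psc applies the 2xSD rule", {
  # injected event of 3x SD is detected; 1x SD is a failure
  big <- manual_sweep(-3, 0)
  ev <- detect_psc(big, noise_sd = 1)
  expect_false(ev$is_failure[1])
  expect_true(ev$is_failure[2])
  expect_equal(ev$amplitude[2], 0)
  small <- manual_sweep(-1, 0)
  ev2 <- detect_psc(small, noise_sd = 1)
  expect_true(ev2$is_failure[1])
  expect_error(detect_psc(big, noise_sd = 0), "positive")
})

test_that("detected failure fraction matches the generator within a binomial CI", {
  p1 <- 0.6
  ps <- gen_paired_sweeps(release_model_params(1, p1, 0.3, n_sweeps = 200), seed = 5)
  ev <- detect_psc_all(ps)
  f1 <- mean(ev$is_failure[ev$pulse == 1])
  ci <- stats::binom.test(sum(ev$is_failure[ev$pulse == 1]), 200)$conf.int
  expect_true((1 - p1) >= ci[1] && (1 - p1) <= ci[2])
  # labels agree with the ground-truth vesicle counts almost everywhere
  agree <- mean((ps$truth$vesicles1 == 0) == ev$is_failure[ev$pulse == 1])
  expect_gt(agree, 0.95)
})

test_that("failure labels are invariant to a common scale factor", {
  ps <- gen_paired_sweeps(release_model_params(1, 0.6, 0.35, n_sweeps = 30), seed = 6)
  sw <- ps$sweeps[[1]]
  sd0 <- noise_sd(sw)
  ev <- detect_psc(sw, sd0)
  for (fac in c(0.25, 4)) {
    sw2 <- sw
    sw2$trace$samples <- sw$trace$samples * fac
    ev2 <- detect_psc(sw2, sd0 * fac)
    expect_identical(ev2$is_failure, ev$is_failure)
  }
})

test_that("is_unitary_connection follows the averaged-trace criterion", {
  # deterministic -10 pA response over 1 pA noise: accepted
  sweeps <- lapply(1:20, function(i) manual_sweep(-10, -5, noise_sd = 1, seed = i))
  expect_true(is_unitary_connection(sweeps))
  expect_error(is_unitary_connection(list()), "empty")
  # pure noise: rejected in at least 95% of seeds
  fp <- 0
  for (s in 1:40) {
    noise <- lapply(1:10, function(i) manual_sweep(0, 0, noise_sd = 1.5, seed = 100 * s + i))
    fp <- fp + is_unitary_connection(noise)
  }
  expect_lte(fp / 40, 0.05)
})

test_that("summarize_connection computes PPR, CV and probabilities", {
  ev <- events_from_amps(rep(-10, 10), rep(-5, 10))
  sm <- summarize_connection(ev)
  expect_equal(sm$ppr, 0.5)
  expect_equal(sm$cv, 0)
  expect_equal(sm$p1, 1)
  # identical responses: PPR 1
  ev2 <- events_from_amps(rep(-8, 5), rep(-8, 5))
  expect_equal(summarize_connection(ev2)$ppr, 1)
  # all failures on pulse 1: undefined
  ev3 <- events_from_amps(rep(0, 5), rep(-8, 5))
  expect_error(summarize_connection(ev3), "PPR undefined")
  # with- vs without-failure conventions differ
  ev4 <- events_from_amps(c(-10, -10, 0, 0), c(-10, 0, 0, 0))
  expect_equal(summarize_connection(ev4, ppr_failures = TRUE)$ppr, 0.5)
  expect_equal(summarize_connection(ev4, ppr_failures = FALSE)$ppr, 1)
})

test_that("kinetics: analytic rise identity and decay recovery", {
  # pure saturating exponential rise: t10_90 = tau * ln 9
  dt <- 0.01
  tt <- seq(0, 60, by = dt)
  for (tau_r in c(0.3, 0.91)) {
    ramp <- -(1 - exp(-pmax(tt - 5, 0) / tau_r))
    # hold plateau then nothing: append a slow decay so a peak exists
    w <- ramp * exp(-pmax(tt - 25, 0) / 50)
    k <- fit_kinetics(w, dt)
    expect_equal(k$t10_90, tau_r * log(9), tolerance = 0.01)
  }
  # noiseless biexponential: decay tau recovered within 0.1 ms
  w2 <- -7.7 * psc_kernel(seq(0, 80, by = 0.05) - 5, 0.568, 12.7)
  k2 <- fit_kinetics(w2, 0.05)
  expect_lt(abs(k2$decay_tau - 12.7), 0.1)
  expect_equal(k2$t10_90, 0.91, tolerance = 0.02)
  # waveform shorter than its rise: error
  expect_error(fit_kinetics(c(0, -0.5, -1, -2, -4, -6, -7, -7.7), 0.05,
                            fit_ms = 1), "rising|decay|short")
})

test_that("recovery curve is flat for ISI-independent depression", {
  groups <- list()
  for (isi in c(50, 100, 250)) {
    groups[[as.character(isi)]] <- gen_paired_sweeps(
      release_model_params(1, 0.8, 0.32, n_sweeps = 120, interpulse = isi),
      seed = 40 + isi
    )
  }
  rc <- recovery_curve(groups)
  expect_equal(rc$isi_ms, c(50, 100, 250))
  expect_true(all(abs(rc$ppr - 0.4) < 0.12))
  one <- recovery_curve(groups["100"])
  expect_equal(nrow(one), 1)
})

test_that("classify_release_sites recovers 1- and 2-site generators and refuses small n", {
  ps1 <- gen_paired_sweeps(
    release_model_params(1, 0.6, 0.35, q = -7.71, n_sweeps = 200), seed = 71
  )
  r1 <- classify_release_sites(detect_psc_all(ps1))
  expect_identical(r1$verdict, "single")
  expect_equal(r1$n_sites, 1L)
  expect_lt(abs(r1$quantal_size - -7.71), 0.8)
  ps2 <- gen_paired_sweeps(
    release_model_params(2, 0.85, 0.4, q = -7.71, n_sweeps = 200), seed = 72
  )
  r2 <- classify_release_sites(detect_psc_all(ps2))
  expect_identical(r2$verdict, "double")
  # mean non-failure PSC1 of the double connection is roughly twice the
  # single-site quantal size
  expect_gt(abs(r2$mean_nf1 / r1$quantal_size), 1.5)
  # refusal below 100 sweeps, with an explicit message
  ps99 <- gen_paired_sweeps(release_model_params(1, 0.6, 0.35, n_sweeps = 99),
                            seed = 73)
  expect_error(classify_release_sites(detect_psc_all(ps99)), "99")
})

test_that("discordant quantal patterns are returned as indeterminate", {
  # amplitudes clearly differ but response probabilities are identical
  set.seed(77)
  a1 <- c(-7.7 + rnorm(130, 0, 0.3), rep(0, 20))
  a2 <- c(-15.4 + rnorm(130, 0, 0.3), rep(0, 20))
  ev <- events_from_amps(a1, a2)
  r <- classify_release_sites(ev)
  expect_identical(r$verdict, "indeterminate")
  expect_true(is.na(r$n_sites))
})

test_that("dzp_effect detects an amplitude increase with preserved PPR", {
  ctl <- gen_paired_sweeps(release_model_params(1, 0.65, 0.35, q = -7.7,
                                                n_sweeps = 120), seed = 80)
  dzp <- gen_paired_sweeps(release_model_params(1, 0.65, 0.35, q = -11.55,
                                                n_sweeps = 120), seed = 81)
  ev_c <- detect_psc_all(ctl)
  ev_d <- detect_psc_all(dzp)
  res <- dzp_effect(ev_c, ev_d, seed = 5)
  expect_gt(res$amp_fold_change, 1.25)
  expect_lt(res$amp_p, 0.01)
  expect_gt(res$ppr_p, 0.05)
  # identical samples: fold-change 1, nothing significant
  same <- dzp_effect(ev_c, ev_c, seed = 6)
  expect_equal(same$amp_fold_change, 1)
  expect_gt(same$amp_p, 0.99)
  expect_error(dzp_effect(ev_c[0, ], ev_d), "empty")
})
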