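test_that("connectivity fields honor the distance rules", {
  # NG2 rule: zero probability beyond 70 um, every seed
  for (s in 1:10) {
    fld <- gen_connectivity_field(
      field_params(n_interneurons = 200, target = "NG2", p_near = 0.8), seed = s
    )
    expect_false(any(fld$connected & fld$distance > 70))
  }
  # p_near = 0: no connections at all
  fld0 <- gen_connectivity_field(field_params(p_near = 0, n_interneurons = 100),
                                 seed = 1)
  expect_false(any(fld0$connected))
  # all positions inside the declared field radius
  expect_true(all(fld0$distance <= 100))
})

test_that("pyramidal fields are uniform: per-bin probabilities inside binomial CIs", {
  fld <- gen_connectivity_field(
    field_params(n_interneurons = 10000, target = "pyramidal", p_near = 0.3),
    seed = 7
  )
  edges <- seq(0, 100, by = 20)
  bin <- cut(fld$distance, edges)
  for (lv in levels(bin)) {
    sub <- fld[bin == lv, ]
    ci <- stats::binom.test(sum(sub$connected), nrow(sub))$conf.int
    expect_true(0.3 >= ci[1] && 0.3 <= ci[2])
  }
})

test_that("field probability function matches its stated form", {
  p <- field_params(p_near = 0.4, target = "NG2")
  expect_equal(field_probability(c(10, 50), p), c(0.4, 0.4))
  expect_equal(field_probability(60, p), 0.4 * 0.5)
  expect_equal(field_probability(c(70.001, 90), p), c(0, 0))
})

test_that("photostimulation trials: windows, evoked events, Poisson background", {
  # unconnected, zero rate: empty rasters
  ph0 <- gen_photostim_trials(FALSE, spontaneous_rate = 0, n_trials = 10, seed = 1)
  expect_true(all(lengths(ph0$trials) == 0))
  # connected, no failures: exactly one evoked event within 100 ms per trial
  ph1 <- gen_photostim_trials(TRUE, spontaneous_rate = 0, n_trials = 50, seed = 2)
  expect_true(all(lengths(ph1$trials) == 1))
  lat <- unlist(ph1$trials)
  expect_true(all(lat > 0 & lat <= 100))
  # background count matches the Poisson expectation: 0.2 Hz x 4 s = 0.8
  ph2 <- gen_photostim_trials(FALSE, spontaneous_rate = 0.2, n_trials = 1000,
                              seed = 3)
  expect_equal(mean(lengths(ph2$trials)), 0.8, tolerance = 0.08)
  # all events inside the declared window
  ev <- unlist(ph2$trials)
  expect_true(all(ev >= -2000 & ev <= 2000))
  # determinism
  ph2b <- gen_photostim_trials(FALSE, spontaneous_rate = 0.2, n_trials = 1000,
                               seed = 3)
  expect_identical(ph2$trials, ph2b$trials)
})

test_that("failure rate thins evoked events", {
  ph <- gen_photostim_trials(TRUE, spontaneous_rate = 0, n_trials = 1000,
                             seed = 4, failure_rate = 0.3)
  hit <- mean(lengths(ph$trials) == 1)
  # within 4 binomial SEs of the configured success rate
  expect_lt(abs(hit - 0.7), 4 * sqrt(0.7 * 0.3 / 1000))
})

test_that("timecourse generator honors probabilities and correlations", {
  tp <- timecourse_params()
  # perfect correlation, no noise floor interference
  tp1 <- timecourse_params(correlation = c(`8` = 0, `9` = 0, `10` = 1,
                                           `11` = 0, `12` = 0, `13` = 0))
  rec <- gen_timecourse(tp1, n_cells_per_day = 50, seed = 5)
  r10 <- with(rec[rec$day == 10, ], pearson_correlation(na_density, spont_freq))
  expect_gt(r10$r, 0.999)
  # PN10 connection probability near the configured 0.44 at n = 200:
  # +/- 0.07 is ~2 binomial SEs, so single seeds fail ~5% of the time;
  # the property is checked across seeds
  within <- vapply(1:15, function(s) {
    r2 <- gen_timecourse(tp, n_cells_per_day = 200, seed = 6 + s)
    abs(mean(r2$connected[r2$day == 10]) - 0.44) < 0.07
  }, logical(1))
  expect_gte(mean(within), 0.8)
  # zero correlation everywhere: per day, |r| < 0.2 in >= 90% of seeds
  # (P(|r| < 0.2) at n = 100 is ~0.95 per day, so the joint all-days event
  # only has probability ~0.95^6 ~ 0.74 and is not a usable bound)
  tp0 <- timecourse_params(correlation = stats::setNames(rep(0, 6), 8:13))
  rs <- sapply(1:20, function(s) {
    r <- gen_timecourse(tp0, n_cells_per_day = 100, seed = 100 + s)
    vapply(8:13, function(d) {
      with(r[r$day == d, ], pearson_correlation(na_density, spont_freq))$r
    }, numeric(1))
  })
  per_day_ok <- rowMeans(abs(rs) < 0.2)
  expect_true(all(per_day_ok >= 0.9))
  # invariant: the parameter set must peak at PN10
  expect_error(
    timecourse_params(connection_prob = c(`8` = 0.5, `9` = 0.3, `10` = 0.44,
                                          `11` = 0.36, `12` = 0.25, `13` = 0.12)),
    "peak at PN10"
  )
})

test_that("puncta clouds: channel structure, bounds, and distance ordering", {
  # PV-only absent
  cl0 <- gen_puncta_cloud(n_pv = 0, n_nonpv = 50, seed = 1)
  expect_true(all(cl0$puncta$channel == "PV-"))
  expect_error(gen_puncta_cloud(n_pv = -1), ">= 0")
  # all points inside stack bounds
  cl <- gen_puncta_cloud(300, 300, seed = 2, n_background = 60)
  with(cl$puncta, {
    expect_true(all(abs(x) <= cl$stack_bounds$xy))
    expect_true(all(abs(y) <= cl$stack_bounds$xy))
    expect_true(all(abs(z) <= cl$stack_bounds$z / 2))
  })
  # branches start on the soma surface
  for (b in cl$morphology$branches) {
    expect_equal(sqrt(sum((b[1, ] - cl$morphology$soma$center)^2)),
                 cl$morphology$soma$radius, tolerance = 1e-9)
  }
  # empirical mean distances: PV+ < PV- (n = 500 each)
  cl2 <- gen_puncta_cloud(500, 500, seed = 3)
  pv <- cl2$puncta[cl2$puncta$true_compartment == "branch", ]
  m <- tapply(pv$true_distance, pv$channel, mean)
  expect_lt(m[["PV+"]], m[["PV-"]])
})

test_that("equal scales give KS-indistinguishable distance distributions", {
  ns <- 0
  for (s in 1:20) {
    cl <- gen_puncta_cloud(200, 200, proximal_scale = 15, distal_scale = 15,
                           seed = 300 + s)
    pts <- cl$puncta[cl$puncta$true_compartment == "branch", ]
    ks <- suppressWarnings(stats::ks.test(
      pts$true_distance[pts$channel == "PV+"],
      pts$true_distance[pts$channel == "PV-"]
    ))
    ns <- ns + (ks$p.value >= 0.05)
  }
  expect_gte(ns / 20, 0.9)
})
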