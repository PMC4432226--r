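# Generators for the spatial/network parts of the study: photostimulation
# trials, distance-dependent connectivity fields, 3D puncta clouds with cell
# morphology, and the developmental time course.

#' Distance-dependent connectivity field parameters
#'
#' For NG2-cell targets the connection probability is `p_near` up to 50 um,
#' decays linearly to 0 at 70 um, and is exactly 0 beyond 70 um; for
#' pyramidal targets it is constant (`p_near`) within 100 um.
#'
#' @param radius field radius in um.
#' @param n_interneurons number of candidate presynaptic interneurons.
#' @param target `"NG2"` or `"pyramidal"`.
#' @param p_near plateau connection probability.
#' @return object of class `ng2_field_params`.
#' @export
field_params <- function(radius = 100, n_interneurons = 30,
                         target = c("NG2", "pyramidal"), p_near = 0.4) {
  target <- match.arg(target)
  check_that(p_near >= 0 && p_near <= 1, "p_near must be in [0,1]")
  check_that(radius > 0 && n_interneurons >= 0, "radius > 0 and counts >= 0 required")
  structure(
    list(radius = radius, n_interneurons = n_interneurons,
         target = target, p_near = p_near),
    class = "ng2_field_params"
  )
}

#' Connection probability at a given intersomatic distance
#'
#' @param d distance(s) in um.
#' @param params an `ng2_field_params`.
#' @return probability vector.
#' @export
field_probability <- function(d, params) {
  if (params$target == "NG2") {
    ifelse(d <= 50, params$p_near,
           ifelse(d <= 70, params$p_near * (70 - d) / 20, 0))
  } else {
    ifelse(d <= 100, params$p_near, 0)
  }
}

#' Generate a ground-truth connectivity field
#'
#' Interneuron positions are uniform in a sphere of the field radius around
#' the recorded cell; each is connected with the distance-rule probability.
#'
#' @param params an `ng2_field_params`.
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `z` (um, recorded cell at origin),
#'   `distance`, `connected` (logical); attribute `params`.
#' @export
gen_connectivity_field <- function(params, seed = NULL) {
  check_that(inherits(params, "ng2_field_params"), "params must be ng2_field_params")
  with_seed(seed, {
    n <- params$n_interneurons
    # uniform in ball: direction uniform, radius ~ R * U^(1/3)
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- params$radius * stats::runif(n)^(1 / 3)
    pos <- u * r
    d <- sqrt(rowSums(pos^2))
    p <- field_probability(d, params)
    out <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      distance = d,
      connected = stats::runif(n) < p
    )
    attr(out, "params") <- params
    out
  })
}

#' Generate photostimulation trials for one targeted interneuron
#'
#' Spontaneous PSCs occur as a homogeneous Poisson process over a window
#' spanning 2 s before to 2 s after the stimulus. If the pair is connected,
#' each trial additionally carries one evoked event (unless it fails with
#' probability `failure_rate`) at a latency drawn from a log-normal
#' truncated to (0, 100] ms, reflecting the delayed, jittered spiking of
#' photostimulated interneurons.
#'
#' @param connected logical: is the targeted interneuron connected?
#' @param spontaneous_rate background PSC rate in Hz.
#' @param n_trials number of photostimulation trials.
#' @param seed integer seed.
#' @param failure_rate per-trial probability that the evoked event fails.
#' @param latency_meanlog,latency_sdlog log-normal latency parameters
#'   (ms scale; defaults give a right-skewed distribution with mode near
#'   30 ms, bounded at 100 ms by truncation via resampling).
#' @param window half-width of the recording window around the stimulus (s).
#' @param pulse_ms laser pulse duration (3-8 ms).
#' @param spot spot position (um, length 3).
#' @param control `"none"`, `"displaced"` or `"longer_pulse"` flag carried on
#'   the trials.
#' @return object of class `ng2_photostim_trials`: list with `trials` (list
#'   of numeric event-time vectors, ms relative to the stimulus), `truth`
#'   (list with `connected`, per-trial evoked latency or NA), and metadata.
#' @export
gen_photostim_trials <- function(connected, spontaneous_rate = 0.2,
                                 n_trials = 20, seed = NULL,
                                 failure_rate = 0,
                                 latency_meanlog = log(35), latency_sdlog = 0.6,
                                 window = 2, pulse_ms = 3,
                                 spot = c(0, 0, 0), control = "none") {
  check_that(spontaneous_rate >= 0, "spontaneous_rate must be >= 0")
  check_that(n_trials >= 0, "n_trials must be >= 0")
  check_that(failure_rate >= 0 && failure_rate <= 1, "failure_rate in [0,1]")
  check_that(pulse_ms >= 3 && pulse_ms <= 8, "pulse duration must be 3-8 ms")
  with_seed(seed, {
    trials <- vector("list", n_trials)
    evoked <- rep(NA_real_, n_trials)
    span_ms <- 2 * window * 1000
    for (i in seq_len(n_trials)) {
      n_bg <- stats::rpois(1, spontaneous_rate * 2 * window)
      ev <- stats::runif(n_bg, -window * 1000, window * 1000)
      if (isTRUE(connected) && stats::runif(1) >= failure_rate) {
        lat <- stats::rlnorm(1, latency_meanlog, latency_sdlog)
        while (lat > 100) lat <- stats::rlnorm(1, latency_meanlog, latency_sdlog)
        evoked[i] <- lat
        ev <- c(ev, lat)
      }
      trials[[i]] <- sort(ev)
    }
    structure(
      list(
        trials = trials,
        truth = list(connected = isTRUE(connected), evoked_latency = evoked),
        spontaneous_rate = spontaneous_rate, window_s = window,
        pulse_ms = pulse_ms, spot = spot, control = control
      ),
      class = "ng2_photostim_trials"
    )
  })
}

#' Render one photostimulation trial as a current trace
#'
#' Convolves the trial's event times with the biexponential PSC kernel
#' (outward-positive at 0 mV holding) and adds Gaussian noise; used to feed
#' the averaged-trace criterion of the connection caller.
#'
#' @param event_times event times (ms, relative to stimulus).
#' @param amp event amplitude in pA (positive = outward).
#' @param noise_sd Gaussian noise SD (pA).
#' @param from_ms,to_ms rendered window (ms relative to stimulus).
#' @param dt sampling interval (ms).
#' @param seed integer seed for the noise.
#' @return an `ng2_trace` (current) with `t0 = from_ms`.
#' @export
render_trial_trace <- function(event_times, amp = 10, noise_sd = 1.5,
                               from_ms = -500, to_ms = 500, dt = 0.1,
                               seed = NULL) {
  with_seed(seed, {
    tt <- seq(from_ms, to_ms, by = dt)
    sig <- numeric(length(tt))
    for (ev in event_times) {
      if (ev > to_ms) next
      sig <- sig + amp * psc_kernel(tt - ev)
    }
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(tt), 0, noise_sd)
    tr <- trace(sig, dt = dt, kind = "current")
    tr$t0 <- from_ms
    tr
  })
}

#' Parameters of the developmental time course
#'
#' @param days integer postnatal days covered.
#' @param connection_prob per-day connection probability; the default peaks
#'   at PN10 with 44% connected pairs.
#' @param spont_freq per-day mean spontaneous PSC frequency (Hz).
#' @param na_density mean Na+ current density (pA/pF), common across days.
#' @param correlation per-day Pearson correlation between Na+ density and
#'   spontaneous frequency; by default nonzero only at PN10.
#' @return object of class `ng2_timecourse_params`.
#' @export
timecourse_params <- function(
    days = 8:13,
    connection_prob = c(`8` = 0.20, `9` = 0.30, `10` = 0.44, `11` = 0.36,
                        `12` = 0.25, `13` = 0.12),
    spont_freq = c(`8` = 0.12, `9` = 0.18, `10` = 0.24, `11` = 0.20,
                   `12` = 0.16, `13` = 0.12),
    na_density = 23.5,
    correlation = c(`8` = 0, `9` = 0, `10` = 0.7, `11` = 0, `12` = 0, `13` = 0)) {
  check_that(all(connection_prob >= 0 & connection_prob <= 1),
             "connection probabilities must be in [0,1]")
  check_that(all(abs(correlation) <= 1), "correlations must be in [-1,1]")
  peak <- names(connection_prob)[which.max(connection_prob)]
  check_that(identical(peak, "10"), "connection probability must peak at PN10")
  structure(
    list(days = days, connection_prob = connection_prob,
         spont_freq = spont_freq, na_density = na_density,
         correlation = correlation),
    class = "ng2_timecourse_params"
  )
}

#' Generate per-cell developmental records
#'
#' Per day, each recorded pair is connected with the day's probability; each
#' cell's Na+ current density and spontaneous PSC frequency are drawn from a
#' bivariate normal with the day's correlation (frequencies floored at a
#' small positive value).
#'
#' @param params an `ng2_timecourse_params`.
#' @param n_cells_per_day cells (pairs) per day.
#' @param seed integer seed.
#' @param density_sd,freq_cv dispersion of density (pA/pF) and the
#'   coefficient of variation of frequency.
#' @return data.frame with `day`, `connected`, `na_density`, `spont_freq`.
#' @export
gen_timecourse <- function(params, n_cells_per_day = 20, seed = NULL,
                           density_sd = 8, freq_cv = 0.35) {
  check_that(inherits(params, "ng2_timecourse_params"),
             "params must be ng2_timecourse_params")
  with_seed(seed, {
    rows <- lapply(params$days, function(d) {
      key <- as.character(d)
      n <- n_cells_per_day
      rho <- params$correlation[[key]]
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      dens <- params$na_density + density_sd * z1
      freq <- params$spont_freq[[key]] * (1 + freq_cv * z2)
      data.frame(
        day = d,
        connected = stats::runif(n) < params$connection_prob[[key]],
        na_density = pmax(dens, 1),
        spont_freq = pmax(freq, 0.01)
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate a 3D puncta cloud and the cell morphology it surrounds
#'
#' The cell is a spherical soma at the stack center with straight branches
#' radiating in random directions. Contacting puncta sit on the morphology:
#' PV+ (fast-spiking input) puncta at branch geodesic distances drawn from
#' a Gamma(shape 2) law with mean `proximal_scale`, PV- puncta with mean
#' `distal_scale`; a fraction of each group sits on the soma itself.
#' Non-contact background puncta are uniform in the stack. Each punctum
#' carries a fluorescence-profile overlap fraction with the cell membrane:
#' above 0.23 for contacts, below for background.
#'
#' @param n_pv,n_nonpv number of contacting PV+ and PV- puncta (>= 0).
#' @param proximal_scale,distal_scale mean branch distances in um (> 0).
#' @param stack_bounds list with `xy` (lateral half-extent from the center,
#'   um) and `z` (stack thickness, um).
#' @param seed integer seed.
#' @param soma_fraction_pv,soma_fraction_nonpv fraction of contacts on the
#'   soma (the PV+ input targets somata more).
#' @param n_background uniform non-contact puncta.
#' @param n_branches,branch_length,soma_radius morphology geometry (um).
#' @return list of class `ng2_puncta_cloud` with `puncta` (data.frame: x, y,
#'   z, channel `"PV+"`/`"PV-"`, `overlap`, plus ground-truth columns
#'   `true_compartment` and `true_distance`), `morphology` (list: `soma`
#'   center/radius, `branches` list of polyline matrices), `stack_bounds`.
#' @export
gen_puncta_cloud <- function(n_pv = 100, n_nonpv = 100,
                             proximal_scale = 12.8, distal_scale = 22.5,
                             stack_bounds = list(xy = 62.5, z = 19.2),
                             seed = NULL,
                             soma_fraction_pv = 0.45, soma_fraction_nonpv = 0.15,
                             n_background = 0,
                             n_branches = 6, branch_length = 55,
                             soma_radius = 5) {
  check_that(n_pv >= 0 && n_nonpv >= 0 && n_background >= 0, "counts must be >= 0")
  check_that(proximal_scale > 0 && distal_scale > 0, "scales must be > 0")
  check_that(stack_bounds$xy > 0 && stack_bounds$z > 0, "stack bounds must be positive")
  with_seed(seed, {
    center <- c(0, 0, 0)
    z_half <- stack_bounds$z / 2
    # branch directions: tilted mostly in-plane so branches stay in the stack
    dirs <- vapply(seq_len(n_branches), function(i) {
      ang <- 2 * pi * (i - 1) / n_branches + stats::runif(1, -0.2, 0.2)
      zc <- stats::runif(1, -0.15, 0.15)
      v <- c(cos(ang) * sqrt(1 - zc^2), sin(ang) * sqrt(1 - zc^2), zc)
      v / sqrt(sum(v^2))
    }, numeric(3))
    branches <- lapply(seq_len(n_branches), function(i) {
      d <- dirs[, i]
      start <- center + soma_radius * d
      rbind(start, start + branch_length * d)
    })
    place_group <- function(n, scale, soma_frac, channel) {
      if (n == 0) {
        return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          channel = character(0), overlap = numeric(0),
                          true_compartment = character(0),
                          true_distance = numeric(0)))
      }
      on_soma <- stats::runif(n) < soma_frac
      n_b <- sum(!on_soma)
      # geodesic distances from the soma surface: Gamma(shape 2) with the
      # requested mean (unimodal, little mass at zero), truncated to the
      # branch length
      dist <- stats::rgamma(n_b, shape = 2, rate = 2 / scale)
      dist <- pmin(dist, branch_length - 0.5)
      br <- sample.int(n_branches, n_b, replace = TRUE)
      pts <- matrix(0, n, 3)
      comp <- character(n)
      truedist <- numeric(n)
      # somatic puncta: random point on the soma surface
      if (any(on_soma)) {
        ns <- sum(on_soma)
        u <- matrix(stats::rnorm(3 * ns), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        pts[on_soma, ] <- rep(center, each = ns) + soma_radius * u
        comp[on_soma] <- "soma"
        truedist[on_soma] <- 0
      }
      if (n_b > 0) {
        bpos <- t(vapply(seq_len(n_b), function(j) {
          d <- dirs[, br[j]]
          center + (soma_radius + dist[j]) * d
        }, numeric(3)))
        # sub-resolution jitter transverse to the branch
        bpos <- bpos + matrix(stats::rnorm(3 * n_b, 0, 0.2), ncol = 3)
        pts[!on_soma, ] <- bpos
        comp[!on_soma] <- "branch"
        truedist[!on_soma] <- dist
      }
      # clip into the stack
      pts[, 1] <- pmin(pmax(pts[, 1], -stack_bounds$xy), stack_bounds$xy)
      pts[, 2] <- pmin(pmax(pts[, 2], -stack_bounds$xy), stack_bounds$xy)
      pts[, 3] <- pmin(pmax(pts[, 3], -z_half), z_half)
      data.frame(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        channel = channel,
        overlap = stats::runif(n, 0.30, 0.90),
        true_compartment = comp,
        true_distance = truedist
      )
    }
    pv <- place_group(n_pv, proximal_scale, soma_fraction_pv, "PV+")
    npv <- place_group(n_nonpv, distal_scale, soma_fraction_nonpv, "PV-")
    bg <- if (n_background > 0) {
      data.frame(
        x = stats::runif(n_background, -stack_bounds$xy, stack_bounds$xy),
        y = stats::runif(n_background, -stack_bounds$xy, stack_bounds$xy),
        z = stats::runif(n_background, -z_half, z_half),
        channel = sample(c("PV+", "PV-"), n_background, replace = TRUE),
        overlap = stats::runif(n_background, 0, 0.20),
        true_compartment = "none",
        true_distance = NA_real_
      )
    } else NULL
    structure(
      list(
        puncta = rbind(pv, npv, bg),
        morphology = list(
          soma = list(center = center, radius = soma_radius),
          branches = branches
        ),
        stack_bounds = stack_bounds
      ),
      class = "ng2_puncta_cloud"
    )
  })
}
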