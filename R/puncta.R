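# Spatial statistics of 3D synaptic puncta around a reconstructed cell:
# profile-overlap contact calls, subcellular assignment, distance
# distributions, and eccentric-shell density profiles with analytic
# clipped-sphere volumes.

#' Overlap fraction of two 1D fluorescence profiles
#'
#' The overlap is the shared area divided by the area of the first
#' (punctum) profile; the convention is therefore asymmetric unless both
#' profiles have equal area. Two profiles qualify as a contact when the
#' overlap exceeds 0.23.
#'
#' @param profile_a punctum profile: numeric vector of non-negative
#'   intensities on a common axis.
#' @param profile_b membrane profile on the same axis (same length).
#' @return overlap fraction in `[0, 1]`.
#' @export
profile_overlap <- function(profile_a, profile_b) {
  check_that(length(profile_a) == length(profile_b),
             "profiles must share a common axis (same length)")
  check_that(all(profile_a >= 0) && all(profile_b >= 0),
             "profiles must be non-negative")
  a <- sum(profile_a)
  check_that(a > 0, "punctum profile has zero area")
  sum(pmin(profile_a, profile_b)) / a
}

#' Contact threshold on the overlap fraction
#' @export
OVERLAP_CONTACT_THRESHOLD <- 0.23

# distance from a point to a polyline, plus the geodesic arc length from the
# polyline start to the closest point
point_to_polyline <- function(p, poly) {
  best <- list(dist = Inf, arc = NA_real_)
  cum <- 0
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]
    b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else min(max(sum((p - a) * ab) / len2, 0), 1)
    proj <- a + tt * ab
    d <- sqrt(sum((p - proj)^2))
    if (d < best$dist) best <- list(dist = d, arc = cum + tt * sqrt(len2))
    cum <- cum + sqrt(len2)
  }
  best
}

#' Assign a punctum to a subcellular compartment
#'
#' A punctum within the soma radius (plus tolerance) is somatic at distance
#' 0. Otherwise it is assigned to the nearest branch polyline, provided it
#' lies within `tolerance` of it; the distance from the soma is, by
#' default, the geodesic arc length along the branch from the soma surface
#' (`metric = "geodesic"`), or the Euclidean distance from the soma center
#' minus the soma radius (`metric = "euclidean"`).
#'
#' @param punctum numeric length-3 position (um).
#' @param morphology morphology list with `soma` (center, radius) and
#'   `branches` (list of polyline matrices), as from [gen_puncta_cloud()].
#' @param tolerance maximal distance to the morphology to count as a
#'   contact (um).
#' @param metric `"geodesic"` or `"euclidean"`.
#' @return list with `compartment` (`"soma"`, `"branch"` or
#'   `"non-contact"`), `distance` (um from the soma; NA for non-contacts)
#'   and `branch` (index or NA).
#' @export
assign_compartment <- function(punctum, morphology, tolerance = 1,
                               metric = c("geodesic", "euclidean")) {
  metric <- match.arg(metric)
  p <- as.numeric(punctum)
  soma <- morphology$soma
  r_c <- sqrt(sum((p - soma$center)^2))
  if (r_c <= soma$radius + tolerance) {
    return(list(compartment = "soma", distance = 0, branch = NA_integer_))
  }
  hits <- lapply(morphology$branches, point_to_polyline, p = p)
  dists <- vapply(hits, `[[`, numeric(1), "dist")
  j <- which.min(dists)
  if (dists[j] > tolerance) {
    return(list(compartment = "non-contact", distance = NA_real_,
                branch = NA_integer_))
  }
  d <- if (metric == "geodesic") hits[[j]]$arc else r_c - soma$radius
  list(compartment = "branch", distance = d, branch = j)
}

#' Classify all puncta of a cloud as PV+/PV- contacts or non-contacts
#'
#' A punctum is a contact when its fluorescence-profile overlap with the
#' cell membrane exceeds 0.23 (when overlap values are available) and it
#' lies within `tolerance` of the morphology.
#'
#' @param cloud an `ng2_puncta_cloud`.
#' @param tolerance contact tolerance in um.
#' @param metric distance convention, see [assign_compartment()].
#' @return data.frame: the cloud's puncta plus `contact` (logical),
#'   `compartment` and `distance`.
#' @export
classify_contacts <- function(cloud, tolerance = 1, metric = "geodesic") {
  pts <- cloud$puncta
  n <- nrow(pts)
  comp <- character(n)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    a <- assign_compartment(c(pts$x[i], pts$y[i], pts$z[i]), cloud$morphology,
                            tolerance = tolerance, metric = metric)
    comp[i] <- a$compartment
    dist[i] <- a$distance
  }
  overlap_ok <- if ("overlap" %in% names(pts)) {
    pts$overlap > OVERLAP_CONTACT_THRESHOLD
  } else TRUE
  pts$contact <- overlap_ok & comp != "non-contact"
  pts$compartment <- ifelse(pts$contact, comp, "non-contact")
  pts$distance <- ifelse(pts$contact, dist, NA_real_)
  pts
}

#' Distance distributions of PV+ vs PV- contacting puncta
#'
#' Branch distances only by default ("excluding puncta on the soma");
#' somatic puncta can be included at distance 0 with
#' `include_soma = TRUE`. Groups are compared with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param contacts data.frame from [classify_contacts()].
#' @param include_soma include somatic puncta at distance 0?
#' @return list with `pv_plus`, `pv_minus` (sorted distances), `mean_pv`,
#'   `mean_nonpv`, `ks` (htest).
#' @export
distance_distributions <- function(contacts, include_soma = FALSE) {
  sel <- contacts$contact &
    (contacts$compartment == "branch" |
       (include_soma & contacts$compartment == "soma"))
  d <- ifelse(contacts$compartment == "soma", 0, contacts$distance)
  dp <- d[sel & contacts$channel == "PV+"]
  dm <- d[sel & contacts$channel == "PV-"]
  check_that(length(dp) > 0 && length(dm) > 0,
             "need contacting puncta in both channel groups")
  ks <- suppressWarnings(stats::ks.test(dp, dm))
  list(
    pv_plus = sort(dp), pv_minus = sort(dm),
    mean_pv = mean(dp), mean_nonpv = mean(dm),
    ks = ks
  )
}

# volume of the spherical cap of height h on a sphere of radius r
cap_volume <- function(r, h) {
  h <- pmin(pmax(h, 0), 2 * r)
  pi * h^2 * (3 * r - h) / 3
}

#' Volume of a spherical shell clipped by the stack's z planes
#'
#' The ball of radius `r` centered at `center` loses the two caps cut off
#' by the stack's bottom and top z planes (analytic cap formula
#' `V = pi h^2 (3r - h) / 3`); the shell volume is the difference of the
#' two clipped balls. Lateral (x, y) bounds are not clipped here: shells
#' are only grown while they fit laterally (see
#' [shell_density_profile()]).
#'
#' @param r_inner,r_outer shell radii in um, `0 <= r_inner < r_outer`.
#' @param stack_bounds list with `xy` (lateral half-extent) and `z`
#'   (thickness) in um.
#' @param center sphere center; must lie inside the stack. The stack spans
#'   `[-z/2, z/2]` around the origin.
#' @return clipped shell volume in um^3.
#' @export
shell_volume <- function(r_inner, r_outer, stack_bounds, center = c(0, 0, 0)) {
  check_that(r_inner >= 0 && r_outer > r_inner, "need 0 <= r_inner < r_outer")
  z_half <- stack_bounds$z / 2
  check_that(abs(center[3]) <= z_half &&
               abs(center[1]) <= stack_bounds$xy &&
               abs(center[2]) <= stack_bounds$xy,
             "center lies outside the stack")
  clipped_ball <- function(r) {
    v <- 4 / 3 * pi * r^3
    # cap above the top plane and below the bottom plane
    h_top <- r - (z_half - center[3])
    h_bot <- r - (z_half + center[3])
    v - cap_volume(r, h_top) - cap_volume(r, h_bot)
  }
  clipped_ball(r_outer) - clipped_ball(r_inner)
}

#' Eccentric-shell puncta density profile
#'
#' Puncta are counted in concentric spherical shells of width `step`
#' around `center`; each count is divided by the shell volume clipped to
#' the stack's z planes. Shells are grown until the next shell would cross
#' the lateral (x, y) stack boundaries.
#'
#' @param cloud an `ng2_puncta_cloud`, or a data.frame of points with
#'   columns x, y, z (then `stack_bounds` is required).
#' @param step shell width in um.
#' @param center profile center (um).
#' @param stack_bounds stack bounds when `cloud` is a plain data.frame.
#' @param channel optional channel filter (e.g. `"PV+"`).
#' @return data.frame with `r_inner`, `r_outer`, `count`, `volume`,
#'   `density` (puncta / um^3).
#' @export
shell_density_profile <- function(cloud, step = 5, center = c(0, 0, 0),
                                  stack_bounds = NULL, channel = NULL) {
  if (inherits(cloud, "ng2_puncta_cloud")) {
    pts <- cloud$puncta
    stack_bounds <- cloud$stack_bounds
  } else {
    pts <- cloud
    check_that(!is.null(stack_bounds), "stack_bounds required for plain point tables")
  }
  if (!is.null(channel)) pts <- pts[pts$channel == channel, ]
  check_that(step > 0, "step must be positive")
  r_max_xy <- min(stack_bounds$xy - abs(center[1]),
                  stack_bounds$xy - abs(center[2]))
  check_that(r_max_xy >= step, "stack too small for a single shell")
  edges <- seq(0, r_max_xy, by = step)
  d <- sqrt((pts$x - center[1])^2 + (pts$y - center[2])^2 +
              (pts$z - center[3])^2)
  out <- data.frame(
    r_inner = edges[-length(edges)],
    r_outer = edges[-1]
  )
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    sum(d >= out$r_inner[i] & d < out$r_outer[i])
  }, numeric(1))
  out$volume <- vapply(seq_len(nrow(out)), function(i) {
    shell_volume(out$r_inner[i], out$r_outer[i], stack_bounds, center)
  }, numeric(1))
  out$density <- out$count / out$volume
  out
}
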