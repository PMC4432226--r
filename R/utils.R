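# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#'
#' All generators route their randomness through this helper so that a seed
#' argument gives bit-identical output without disturbing the caller's RNG
#' stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Half-up decimal rounding
#'
#' Rounds to `digits` decimal places with ties away from zero, matching how
#' values such as confidence-interval bounds are conventionally printed.
#' Base R's `round()` uses banker's rounding, which cannot reproduce those
#' printed values at ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.565, 2) # 0.57
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# argument check with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# linear interpolation of the time at which y crosses `level` between
# samples i and i+1
cross_time <- function(t, y, i, level) {
  if (y[i + 1] == y[i]) return(t[i])
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

# centered finite-difference derivative (one-sided at ends), per ms
deriv_dt <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# moving-average smoother with odd window (samples); pads by edge values
smooth_boxcar <- function(x, width) {
  if (width <= 1) return(x)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(h + 1):(h + length(x))]
}
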