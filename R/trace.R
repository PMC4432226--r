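# Trace and PulseProtocol containers plus their plain-text serialization.
# A Trace is the raw substrate of every waveform operation: a uniformly
# sampled signal with a sampling interval in ms and a declared signal kind.

#' Create a sampled electrophysiological trace
#'
#' @param samples numeric vector of samples (mV for voltage, pA for current).
#' @param dt sampling interval in ms (20 kHz digitization gives 0.05 ms).
#' @param kind `"voltage"` or `"current"`.
#' @param t0 time of the first sample in ms.
#' @return an object of class `ng2_trace`.
#' @export
trace <- function(samples, dt, kind = c("voltage", "current"), t0 = 0) {
  kind <- match.arg(kind)
  check_that(is.numeric(dt) && length(dt) == 1 && dt > 0, "dt must be a positive scalar (ms)")
  check_that(is.numeric(samples) && length(samples) > 0, "samples must be a non-empty numeric vector")
  check_that(all(is.finite(samples)), "samples must be finite")
  structure(
    list(samples = as.numeric(samples), dt = as.numeric(dt), kind = kind, t0 = as.numeric(t0)),
    class = "ng2_trace"
  )
}

#' @export
print.ng2_trace <- function(x, ...) {
  cat(sprintf(
    "<ng2_trace> %s, %d samples @ dt = %g ms (%.1f ms), t0 = %g ms\n",
    x$kind, length(x$samples), x$dt, length(x$samples) * x$dt, x$t0
  ))
  invisible(x)
}

#' Sample times of a trace (ms)
#' @param tr an `ng2_trace`.
#' @return numeric vector of times in ms.
#' @export
trace_times <- function(tr) {
  tr$t0 + (seq_along(tr$samples) - 1) * tr$dt
}

#' Current- or voltage-step protocol
#'
#' Describes one square current pulse delivered in current clamp (or the
#' voltage command mirrored as an action-current pulse in voltage clamp).
#'
#' @param holding holding level before/after the step (mV for current clamp).
#' @param amplitude step amplitude in pA (negative = hyperpolarizing).
#' @param onset step onset in ms.
#' @param duration step duration in ms; must be positive.
#' @return an object of class `ng2_protocol`.
#' @export
pulse_protocol <- function(holding = -70, amplitude = 200, onset = 100, duration = 1000) {
  check_that(duration > 0, "protocol duration must be positive")
  structure(
    list(
      holding = holding, amplitude = amplitude,
      onset = onset, duration = duration
    ),
    class = "ng2_protocol"
  )
}

#' Write a trace to a plain-text file
#'
#' Header lines start with `#` and carry `key: value` metadata; the body is
#' two whitespace-separated columns (time in ms, signal).
#'
#' @param tr an `ng2_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(tr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", tr$kind),
    sprintf("# dt_ms: %.17g", tr$dt),
    sprintf("# t0_ms: %.17g", tr$t0)
  ), con)
  utils::write.table(
    data.frame(time_ms = trace_times(tr), signal = tr$samples),
    con,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a trace written by [write_trace()]
#' @param path file path.
#' @return an `ng2_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    check_that(length(m) == 1, sprintf("trace header missing field '%s'", key))
    sub(sprintf("^# %s:\\s*", key), "", m)
  }
  body <- utils::read.table(text = lines[!grepl("^#", lines)])
  trace(
    samples = body[[2]],
    dt = as.numeric(get_field("dt_ms")),
    kind = get_field("kind"),
    t0 = as.numeric(get_field("t0_ms"))
  )
}
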