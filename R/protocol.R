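#' Stimulation protocol
#'
#' Describes one of the three study protocols: square current steps, current
#' ramps, or subthreshold voltage steps.
#'
#' @param mode `"current_step"`, `"current_ramp"` or `"voltage_step"`.
#' @param pre_ms,stim_ms,post_ms segment durations (ms), non-negative.
#' @param amplitudes numeric vector: step amplitudes in pA (current steps),
#'   ramp end currents in pA (ramps), or command voltages in mV (voltage
#'   steps). Must be non-empty.
#' @param ramp_start ramp starting current (pA), ramp mode only.
#' @param dt sample interval (ms), > 0.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(mode, pre_ms, stim_ms, post_ms, amplitudes,
                              ramp_start = NULL, dt = 0.025) {
  mode <- match.arg(mode, c("current_step", "current_ramp", "voltage_step"))
  stopifnot(dt > 0, pre_ms >= 0, stim_ms >= 0, post_ms >= 0,
            length(amplitudes) >= 1)
  if (mode == "current_ramp" && is.null(ramp_start))
    stop("ramp protocols need ramp_start")
  structure(list(mode = mode, pre_ms = pre_ms, stim_ms = stim_ms,
                 post_ms = post_ms, amplitudes = amplitudes,
                 ramp_start = ramp_start, dt = dt),
            class = "stimulus_protocol")
}

#' Canonical study protocols
#'
#' `protocol_steps()`: 1 s current steps (default -100 to 450 pA) with 200 ms
#' pre and 300 ms post. `protocol_ramp()`: 500 ms ramp from -50 pA to a
#' configurable peak. `protocol_iv()`: 500 ms subthreshold voltage steps,
#' -77 to -47 mV in 5 mV increments.
#'
#' @param amplitudes step amplitudes (pA).
#' @param dt sample interval (ms).
#' @name canonical_protocols
NULL

#' @rdname canonical_protocols
#' @export
protocol_steps <- function(amplitudes = c(-100, 50, 150, 250, 350, 450),
                           dt = 0.025) {
  stimulus_protocol("current_step", 200, 1000, 300, amplitudes, dt = dt)
}

#' @rdname canonical_protocols
#' @param ramp_end peak ramp current (pA): 200, 300, 500 or 700 in the study.
#' @export
protocol_ramp <- function(ramp_end = 300, dt = 0.025) {
  stimulus_protocol("current_ramp", 200, 500, 100, ramp_end,
                    ramp_start = -50, dt = dt)
}

#' @rdname canonical_protocols
#' @export
protocol_iv <- function(dt = 0.025) {
  stimulus_protocol("voltage_step", 100, 500, 100, seq(-77, -47, by = 5),
                    dt = dt)
}

protocol_total_ms <- function(protocol) {
  protocol$pre_ms + protocol$stim_ms + protocol$post_ms
}

#' Uniformly sampled voltage or current trace
#'
#' @param kind `"voltage"` or `"current"`.
#' @param samples numeric vector (mV or pA).
#' @param dt sample interval (ms).
#' @param protocol the generating [stimulus_protocol()] (or `NULL`).
#' @param amplitude the protocol amplitude this trace realizes.
#' @param cell_id,condition,subtype optional metadata.
#' @return an object of class `trace`.
#' @export
new_trace <- function(kind, samples, dt, protocol = NULL, amplitude = NA,
                      cell_id = NA_character_, condition = NA_character_,
                      subtype = NA_character_) {
  kind <- match.arg(kind, c("voltage", "current"))
  stopifnot(dt > 0, is.numeric(samples))
  if (!is.null(protocol)) {
    expected <- round(protocol_total_ms(protocol) / dt) + 1
    if (abs(length(samples) - expected) > 1)
      stop("sample count ", length(samples), " inconsistent with protocol (",
           expected, " expected)")
  }
  structure(list(kind = kind, samples = as.numeric(samples), dt = dt,
                 protocol = protocol, amplitude = amplitude,
                 meta = list(cell_id = cell_id, condition = condition,
                             subtype = subtype)),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s, %d samples @ dt %g ms (%.4g ms)%s\n", x$kind,
              length(x$samples), x$dt, (length(x$samples) - 1) * x$dt,
              if (!is.na(x$amplitude)) paste0(", amplitude ", x$amplitude) else ""))
  invisible(x)
}

#' Time axis of a trace
#' @param trace a [new_trace()] object.
#' @return numeric vector of sample times (ms), starting at 0.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) * trace$dt
}

# index range [i1, i2] covering times [t1, t2] (ms, inclusive)
window_idx <- function(trace, t1, t2) {
  n <- length(trace$samples)
  i1 <- max(1L, floor(t1 / trace$dt) + 1L)
  i2 <- min(n, round(t2 / trace$dt) + 1L)
  if (i2 < i1) stop("empty trace window [", t1, ", ", t2, "] ms")
  c(i1, i2)
}
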