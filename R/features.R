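#' Detect action potentials in a voltage trace
#'
#' A spike is a contiguous run of samples whose voltage slope dV/dt stays at
#' or above `dvdt_thresh` and whose subsequent voltage peak reaches
#' `min_peak` (the peak requirement guards against noise-triggered slope
#' crossings). The spike threshold voltage is the voltage at the first
#' sample of the run; the peak is the first local voltage maximum after the
#' run starts. dV/dt is computed by central differences (one-sided at the
#' edges). A new spike is only accepted once the voltage has fallen back
#' below the previous spike's threshold.
#'
#' @param trace a voltage [new_trace()] with at least 3 samples.
#' @param dvdt_thresh slope criterion (mV/ms), default 20.
#' @param min_peak minimum peak voltage (mV) to confirm a spike, default -20.
#' @return an object of class `spike_train`: list with `times` (ms),
#'   `threshold_v` (mV), `peak_v` (mV), `peak_times` (ms).
#' @export
detect_spikes <- function(trace, dvdt_thresh = 20, min_peak = -20) {
  stopifnot(inherits(trace, "trace"))
  if (trace$kind != "voltage") stop("detect_spikes needs a voltage trace")
  v <- trace$samples
  n <- length(v)
  if (n < 3) stop("trace too short for spike detection (< 3 samples)")
  dt <- trace$dt
  dvdt <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / dt

  up <- dvdt >= dvdt_thresh
  onset <- which(up & !c(FALSE, up[-n]))

  times <- thr <- pkv <- pkt <- numeric(0)
  last_thr <- Inf
  armed <- TRUE
  oi <- 1L
  for (k in onset) {
    if (!armed) {
      # re-arm once V has fallen below the previous spike threshold
      if (any(v[oi:k] < last_thr)) armed <- TRUE else next
    }
    # first local maximum at or after onset
    j <- k
    while (j < n && v[j + 1] >= v[j]) j <- j + 1
    if (v[j] < min_peak) next
    times <- c(times, (k - 1) * dt)
    thr <- c(thr, v[k])
    pkv <- c(pkv, v[j])
    pkt <- c(pkt, (j - 1) * dt)
    last_thr <- v[k]
    armed <- FALSE
    oi <- j
  }
  structure(list(times = times, threshold_v = thr, peak_v = pkv,
                 peak_times = pkt, dt = dt,
                 duration = (n - 1) * dt),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$times), "spikes over", x$duration, "ms\n")
  invisible(x)
}

#' Number of spikes in a train
#' @param train a [detect_spikes()] result.
#' @return integer count.
#' @export
n_spikes <- function(train) length(train$times)

#' Resting membrane potential
#'
#' Mean membrane potential over the first 100 ms of the recording (the
#' pre-stimulus baseline).
#'
#' @param trace a voltage [new_trace()] whose pre-stimulus segment is at
#'   least 100 ms.
#' @param window_ms baseline window (ms), default 100.
#' @return resting potential (mV).
#' @export
resting_vm <- function(trace, window_ms = 100) {
  stopifnot(inherits(trace, "trace"))
  pre <- if (!is.null(trace$protocol)) trace$protocol$pre_ms else
    (length(trace$samples) - 1) * trace$dt
  if (pre < window_ms)
    stop("pre-stimulus segment (", pre, " ms) shorter than the ", window_ms,
         " ms baseline window")
  idx <- window_idx(trace, 0, window_ms)
  mean(trace$samples[idx[1]:idx[2]])
}

#' Input resistance by Ohm's law
#'
#' @param delta_v voltage step (mV).
#' @param delta_i steady-state current response (pA), non-zero.
#' @return input resistance (MOhm); `delta_v/delta_i * 1000`.
#' @export
input_resistance <- function(delta_v, delta_i) {
  if (any(delta_i == 0)) stop("delta_i must be non-zero")
  delta_v / delta_i * 1000
}

#' Input resistance of a model from a -5 mV clamp step
#'
#' Runs the canonical voltage-clamp measurement: a -5 mV step from the
#' holding potential; Rin = -5 mV over the steady-state current deflection.
#'
#' @param model a [soma_model()].
#' @param step step size (mV), default -5.
#' @return input resistance (MOhm).
#' @export
measure_rin <- function(model, step = -5) {
  p <- stimulus_protocol("voltage_step", 100, 200, 50,
                         model$holding + step, dt = 0.025)
  tr <- simulate_vc(model, p)
  iss <- steady_state_current(tr, window_ms = 50)
  input_resistance(step, iss - holding_current(model))
}

#' Threshold of the first action potential
#' @param train a [detect_spikes()] result with at least one spike.
#' @return threshold voltage (mV), or `NA` (with a warning suppressed) when
#'   the train is empty — undefined features propagate as `NA`, never 0.
#' @export
ap_threshold <- function(train) {
  if (n_spikes(train) == 0) return(NA_real_)
  train$threshold_v[1]
}

#' Rheobase from a current-ramp trace
#'
#' The instantaneous injected current at the time the first spike crosses
#' threshold, obtained by mapping that time linearly onto the ramp.
#'
#' @param trace a voltage [new_trace()] generated under a `current_ramp`
#'   protocol.
#' @param train optional pre-computed [detect_spikes()] result.
#' @return rheobase (pA), or `NA` when no spike occurs during the ramp.
#' @export
rheobase <- function(trace, train = detect_spikes(trace)) {
  stopifnot(inherits(trace, "trace"))
  p <- trace$protocol
  if (is.null(p) || p$mode != "current_ramp")
    stop("rheobase needs a trace from a current_ramp protocol")
  t0 <- p$pre_ms
  t1 <- p$pre_ms + p$stim_ms
  tt <- train$times
  tt <- tt[tt >= t0 & tt <= t1]
  if (!length(tt)) return(NA_real_)
  frac <- (tt[1] - t0) / p$stim_ms
  p$ramp_start + frac * (trace$amplitude - p$ramp_start)
}

#' Action potential amplitude and half-width
#'
#' Measured on the first spike: amplitude is threshold to peak; half-width
#' is the time between the two crossings of the half-amplitude level
#' (threshold + amplitude/2), located by sub-sample linear interpolation.
#'
#' @param trace the voltage [new_trace()] the train came from.
#' @param train a [detect_spikes()] result.
#' @return list with `amplitude` (mV) and `half_width` (ms); both `NA` when
#'   the train is empty.
#' @export
ap_shape <- function(trace, train = detect_spikes(trace)) {
  if (n_spikes(train) == 0)
    return(list(amplitude = NA_real_, half_width = NA_real_))
  v <- trace$samples
  dt <- trace$dt
  i_thr <- round(train$times[1] / dt) + 1
  i_pk <- round(train$peak_times[1] / dt) + 1
  amp <- train$peak_v[1] - train$threshold_v[1]
  half <- train$threshold_v[1] + amp / 2

  cross_up <- NA_real_
  for (i in seq(max(i_thr - 1, 1), i_pk - 1)) {
    if (v[i] < half && v[i + 1] >= half) {
      cross_up <- (i - 1 + (half - v[i]) / (v[i + 1] - v[i])) * dt
      break
    }
  }
  cross_dn <- NA_real_
  for (i in seq(i_pk, length(v) - 1)) {
    if (v[i] >= half && v[i + 1] < half) {
      cross_dn <- (i - 1 + (v[i] - half) / (v[i] - v[i + 1])) * dt
      break
    }
  }
  list(amplitude = amp, half_width = cross_dn - cross_up)
}

# window bounds of the stimulus in a step trace, with amplitude check
check_step <- function(trace, amplitude = NULL) {
  p <- trace$protocol
  if (is.null(p) || p$mode != "current_step")
    stop("a current_step trace is required")
  if (!is.null(amplitude) && !isTRUE(all.equal(trace$amplitude, amplitude)))
    stop("trace amplitude is ", trace$amplitude, " pA; ", amplitude,
         " pA required")
  c(on = p$pre_ms, off = p$pre_ms + p$stim_ms)
}

#' Sag and steady-state hyperpolarization of a -100 pA step
#'
#' The steady state is the mean voltage over the last 50 ms of the step.
#' Sag is the magnitude of the difference between the voltage minimum during
#' the step and that steady state; hyperpolarization is the magnitude of the
#' difference between the resting potential and the steady state.
#'
#' @param trace a voltage trace of a -100 pA, >= 100 ms current step.
#' @param vm_rest resting potential (mV); default recomputed from the trace.
#' @return list with `sag` (mV) and `hyperpolarization` (mV), both >= 0.
#' @export
sag_and_hyperpolarization <- function(trace, vm_rest = resting_vm(trace)) {
  w <- check_step(trace, -100)
  if (trace$protocol$stim_ms < 100) stop("step too short (< 100 ms)")
  stim <- window_idx(trace, w["on"], w["off"])
  tail50 <- window_idx(trace, w["off"] - 50, w["off"])
  steady <- mean(trace$samples[tail50[1]:tail50[2]])
  vmin <- min(trace$samples[stim[1]:stim[2]])
  list(sag = abs(vmin - steady), hyperpolarization = abs(vm_rest - steady))
}

#' After-depolarization following a -100 pA step
#'
#' Magnitude of the difference between the resting potential and the maximum
#' membrane potential during the 200 ms after step offset. Rebound spikes
#' contaminate the window in some cells; spike samples (from each spike's
#' threshold crossing until the voltage falls back below that threshold) are
#' excised before taking the maximum.
#'
#' @inheritParams sag_and_hyperpolarization
#' @return ADP magnitude (mV).
#' @export
adp <- function(trace, vm_rest = resting_vm(trace)) {
  w <- check_step(trace, -100)
  if (trace$protocol$post_ms < 200)
    stop("need >= 200 ms recorded after step offset")
  idx <- window_idx(trace, w["off"], w["off"] + 200)
  seg <- trace$samples[idx[1]:idx[2]]
  tr2 <- new_trace("voltage", seg, trace$dt)
  train <- detect_spikes(tr2)
  keep <- rep(TRUE, length(seg))
  for (s in seq_len(n_spikes(train))) {
    i0 <- round(train$times[s] / trace$dt) + 1
    j <- i0
    while (j <= length(seg) && seg[j] >= train$threshold_v[s]) j <- j + 1
    keep[i0:min(j, length(seg))] <- FALSE
  }
  abs(max(seg[keep]) - vm_rest)
}

#' After-hyperpolarization following a +250 pA step
#'
#' Magnitude of the difference between the resting potential and the lowest
#' membrane potential during the 200 ms after step offset.
#'
#' @param trace a voltage trace of a +250 pA current step with >= 200 ms
#'   recorded after offset.
#' @param vm_rest resting potential (mV).
#' @return AHP magnitude (mV).
#' @export
ahp <- function(trace, vm_rest = resting_vm(trace)) {
  w <- check_step(trace, 250)
  if (trace$protocol$post_ms < 200)
    stop("need >= 200 ms recorded after step offset")
  idx <- window_idx(trace, w["off"], w["off"] + 200)
  abs(vm_rest - min(trace$samples[idx[1]:idx[2]]))
}

#' Firing frequency of a 1 s current step
#'
#' Spike count within the stimulus window of a 1 s step, reported as Hz
#' (count and rate coincide for the 1 s protocol; other durations are
#' rejected rather than rescaled).
#'
#' @param trace a voltage trace of a 1 s current step.
#' @param train optional pre-computed [detect_spikes()] result.
#' @return firing frequency (Hz).
#' @export
firing_frequency <- function(trace, train = detect_spikes(trace)) {
  w <- check_step(trace)
  if (!isTRUE(all.equal(trace$protocol$stim_ms, 1000)))
    stop("firing frequency is defined on the 1 s step protocol; got ",
         trace$protocol$stim_ms, " ms")
  sum(train$times >= w["on"] & train$times < w["off"])
}

#' Classify a layer-5 pyramidal neuron as type A or type B
#'
#' Type A (thick-tufted L5b) cells show pronounced sag, ADP and AHP; the
#' criterion is that the summed magnitude of the three features exceeds
#' 6.5 mV (strict inequality: exactly 6.5 classifies as B).
#'
#' @param sag,adp,ahp feature magnitudes (mV), all >= 0.
#' @return `"A"`, `"B"`, or `"unclassified"` when any input is missing.
#' @export
classify_subtype <- function(sag, adp, ahp) {
  if (anyNA(c(sag, adp, ahp))) return("unclassified")
  stopifnot(sag >= 0, adp >= 0, ahp >= 0)
  if (sag + adp + ahp > 6.5) "A" else "B"
}

#' Extract the full feature set of one cell
#'
#' Runs every feature measurement on a cell's trace collection: resting
#' potential and firing frequencies from the current steps, sag / ADP /
#' hyperpolarization from the -100 pA step, AHP from the +250 pA step,
#' threshold / amplitude / half-width / rheobase from the ramp, input
#' resistance from the -5 mV clamp step, then the subtype label.
#'
#' @param step_traces list of voltage traces from [protocol_steps()]
#'   (one per amplitude).
#' @param ramp_trace voltage trace from [protocol_ramp()], or `NULL`.
#' @param rin input resistance (MOhm) measured separately, or `NA`.
#' @return a one-row `data.frame` with columns `vm_rest`, `r_in`,
#'   `ap_threshold`, `rheobase`, `ap_amplitude`, `ap_half_width`, `sag`,
#'   `hyperpolarization`, `adp`, `ahp`, `freq_<pA>` per positive step, and
#'   `subtype`.
#' @export
extract_features <- function(step_traces, ramp_trace = NULL, rin = NA_real_) {
  if (inherits(step_traces, "trace")) step_traces <- list(step_traces)
  amps <- vapply(step_traces, `[[`, numeric(1), "amplitude")

  vm <- resting_vm(step_traces[[1]])
  out <- list(vm_rest = vm, r_in = rin, ap_threshold = NA_real_,
              rheobase = NA_real_, ap_amplitude = NA_real_,
              ap_half_width = NA_real_, sag = NA_real_,
              hyperpolarization = NA_real_, adp = NA_real_, ahp = NA_real_)

  if (-100 %in% amps) {
    tr <- step_traces[[match(-100, amps)]]
    sh <- sag_and_hyperpolarization(tr, vm)
    out$sag <- sh$sag
    out$hyperpolarization <- sh$hyperpolarization
    out$adp <- adp(tr, vm)
  }
  if (250 %in% amps) out$ahp <- ahp(step_traces[[match(250, amps)]], vm)

  if (!is.null(ramp_trace)) {
    train <- detect_spikes(ramp_trace)
    out$ap_threshold <- ap_threshold(train)
    out$rheobase <- rheobase(ramp_trace, train)
    shape <- ap_shape(ramp_trace, train)
    out$ap_amplitude <- shape$amplitude
    out$ap_half_width <- shape$half_width
  }

  for (i in seq_along(step_traces)) {
    if (amps[i] > 0)
      out[[paste0("freq_", amps[i])]] <- firing_frequency(step_traces[[i]])
  }
  out$subtype <- classify_subtype(out$sag, out$adp, out$ahp)
  as.data.frame(out, stringsAsFactors = FALSE)
}
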