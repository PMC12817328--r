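#' Holding current of a model at a voltage
#'
#' Total membrane current (pA, outward positive) with all gates and the
#' calcium pool at their steady state for the clamped voltage. This is the
#' current a perfect clamp must supply to hold the cell there, and the
#' injected bias applied throughout current-clamp simulations so that the
#' pre-stimulus baseline sits at the holding potential.
#'
#' @param model a [soma_model()].
#' @param v clamped voltage (mV); defaults to the model holding potential.
#' @return current in pA.
#' @export
holding_current <- function(model, v = model$holding) {
  .sim_membrane_current(flatten_model(model), v)
}

drive_vector <- function(protocol, amplitude, n) {
  tt <- (seq_len(n) - 1) * protocol$dt
  in_stim <- tt >= protocol$pre_ms & tt < protocol$pre_ms + protocol$stim_ms
  if (protocol$mode == "current_step") {
    drv <- numeric(n)
    drv[in_stim] <- amplitude
  } else if (protocol$mode == "current_ramp") {
    drv <- numeric(n)
    frac <- (tt[in_stim] - protocol$pre_ms) / protocol$stim_ms
    drv[in_stim] <- protocol$ramp_start + frac * (amplitude - protocol$ramp_start)
  } else {
    drv <- rep(NA_real_, n)
    drv[!in_stim] <- NA
    drv[in_stim] <- amplitude
  }
  drv
}

sim_one <- function(model, protocol, amplitude) {
  n <- round(protocol_total_ms(protocol) / protocol$dt) + 1
  fm <- flatten_model(model)
  if (protocol$mode == "voltage_step") {
    drv <- drive_vector(protocol, amplitude, n)
    drv[is.na(drv)] <- model$holding
    res <- .sim_run(fm, drv, protocol$dt, 1L, model$holding)
    kind <- "current"
  } else {
    i_hold <- .sim_membrane_current(fm, model$holding)
    drv <- i_hold + drive_vector(protocol, amplitude, n)
    res <- .sim_run(fm, drv, protocol$dt, 0L, model$holding)
    kind <- "voltage"
  }
  if (res$failed_at > 0)
    stop("integration failure (|V| > 200 mV) at step ", res$failed_at,
         " (t = ", signif(res$failed_at * protocol$dt, 5), " ms)",
         call. = FALSE)
  new_trace(kind, res$samples, protocol$dt, protocol, amplitude)
}

#' Simulate a current-clamp protocol
#'
#' Integrates the membrane equation \eqn{C \, dV/dt = -\sum I_{chan} +
#' I_{inj}} together with the calcium pool ODE, starting from the steady
#' state at the holding potential (a bias current holds the cell there, as
#' in the recordings). Deterministic: no noise is added.
#'
#' @param model a [soma_model()].
#' @param protocol a current-step or current-ramp [stimulus_protocol()].
#' @return a list of voltage [new_trace()]s, one per protocol amplitude
#'   (a single `trace` if the protocol has one amplitude).
#' @export
simulate_cc <- function(model, protocol) {
  stopifnot(inherits(model, "soma_model"),
            inherits(protocol, "stimulus_protocol"))
  if (!protocol$mode %in% c("current_step", "current_ramp"))
    stop("simulate_cc needs a current_step or current_ramp protocol")
  out <- lapply(protocol$amplitudes, function(a) sim_one(model, protocol, a))
  if (length(out) == 1) out[[1]] else out
}

#' Simulate an ideal voltage-clamp protocol
#'
#' The command voltage is imposed exactly (no series resistance, no
#' capacitive transient modelling); the returned trace is the total ionic
#' membrane current, outward positive, in pA. The calcium pool is still
#' integrated.
#'
#' @param model a [soma_model()].
#' @param protocol a voltage-step [stimulus_protocol()].
#' @return a list of current [new_trace()]s, one per command voltage
#'   (a single `trace` for one amplitude).
#' @export
simulate_vc <- function(model, protocol) {
  stopifnot(inherits(model, "soma_model"),
            inherits(protocol, "stimulus_protocol"))
  if (protocol$mode != "voltage_step")
    stop("simulate_vc needs a voltage_step protocol")
  out <- lapply(protocol$amplitudes, function(a) sim_one(model, protocol, a))
  if (length(out) == 1) out[[1]] else out
}
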