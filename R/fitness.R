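#' Fitness component weights
#'
#' Weights of the multi-component fitness used for model fitting, together
#' with the spike-region constants: samples within `spike_window` ms of a
#' reference spike peak receive `spike_region_weight` (default 10) times the
#' weight of other samples in the trace-error RMS; `presence_b` and
#' `count_c` are the spike-fidelity constants.
#'
#' @param w_trace,w_spike,w_timing,w_isi non-negative component weights.
#'   Defaults 1, 1, 1, 0.1.
#' @param spike_region_weight per-sample weight inside spike regions, >= 1.
#' @param spike_window half-width (ms) of a spike region, centred on each
#'   reference spike peak.
#' @param presence_b penalty for a presence/absence mismatch.
#' @param count_c penalty per unit spike-count deviation.
#' @param normalize logical; `TRUE` (default) divides the weighted RMS by
#'   the sum of weights (the 10x weight re-balances rather than inflates the
#'   scale); `FALSE` divides by the sample count.
#' @param current_scale fitness units per pA for current (voltage-clamp)
#'   references: their plain RMS is multiplied by this so that 10 pA of
#'   clamp-current error weighs like 1 mV of voltage error (default 0.1).
#' @return an object of class `fitness_weights`.
#' @export
fitness_weights <- function(w_trace = 1, w_spike = 1, w_timing = 1,
                            w_isi = 0.1, spike_region_weight = 10,
                            spike_window = 5, presence_b = 5, count_c = 1,
                            normalize = TRUE, current_scale = 0.1) {
  stopifnot(w_trace >= 0, w_spike >= 0, w_timing >= 0, w_isi >= 0,
            spike_region_weight >= 1, spike_window >= 0,
            presence_b >= 0, count_c >= 0, current_scale >= 0)
  structure(list(w_trace = w_trace, w_spike = w_spike, w_timing = w_timing,
                 w_isi = w_isi, spike_region_weight = spike_region_weight,
                 spike_window = spike_window, presence_b = presence_b,
                 count_c = count_c, normalize = normalize,
                 current_scale = current_scale),
            class = "fitness_weights")
}

#' Spike-weighted RMS trace error
#'
#' Root-mean-square of the pointwise voltage difference, with per-sample
#' weights equal to `spike_region_weight` within `spike_window` ms of any
#' reference spike peak and 1 elsewhere. Weights are normalized (divide by
#' their sum) so identical traces score 0 and a uniform 1 mV offset scores
#' 1 regardless of spike content.
#'
#' @param sim,ref voltage [new_trace()]s of equal length and dt.
#' @param weights a [fitness_weights()].
#' @param ref_train optional pre-computed [detect_spikes()] of `ref`.
#' @return non-negative scalar (mV scale).
#' @export
weighted_trace_error <- function(sim, ref, weights = fitness_weights(),
                                 ref_train = detect_spikes(ref)) {
  if (length(sim$samples) != length(ref$samples))
    stop("trace length mismatch: ", length(sim$samples), " vs ",
         length(ref$samples))
  if (!isTRUE(all.equal(sim$dt, ref$dt))) stop("trace dt mismatch")
  n <- length(ref$samples)
  w <- rep(1, n)
  for (pt in ref_train$peak_times) {
    i1 <- max(1L, ceiling((pt - weights$spike_window) / ref$dt - 1e-9) + 1L)
    i2 <- min(n, floor((pt + weights$spike_window) / ref$dt + 1e-9) + 1L)
    if (i2 >= i1) w[i1:i2] <- weights$spike_region_weight
  }
  d2 <- (sim$samples - ref$samples)^2
  denom <- if (weights$normalize) sum(w) else length(w)
  sqrt(sum(w * d2) / denom)
}

#' Spike presence and count penalty
#'
#' `presence_b * [presence differs] + count_c * |count(sim) - count(ref)|`;
#' zero exactly when both trains agree in presence and count.
#'
#' @param sim_train,ref_train [detect_spikes()] results.
#' @param weights a [fitness_weights()].
#' @return non-negative scalar.
#' @export
spike_fidelity_penalty <- function(sim_train, ref_train,
                                   weights = fitness_weights()) {
  ns <- n_spikes(sim_train)
  nr <- n_spikes(ref_train)
  weights$presence_b * as.numeric((ns > 0) != (nr > 0)) +
    weights$count_c * abs(ns - nr)
}

#' First/last spike timing penalty
#'
#' Sum of the absolute first-spike and last-spike time differences,
#' normalized by the trace duration. Zero when either train is empty (the
#' spike-fidelity component carries that penalty).
#'
#' @param sim_train,ref_train [detect_spikes()] results.
#' @param duration trace duration (ms) used for normalization; defaults to
#'   the reference train's duration.
#' @return non-negative scalar.
#' @export
timing_penalty <- function(sim_train, ref_train,
                           duration = ref_train$duration) {
  if (n_spikes(sim_train) == 0 || n_spikes(ref_train) == 0) return(0)
  (abs(sim_train$times[1] - ref_train$times[1]) +
     abs(sim_train$times[length(sim_train$times)] -
           ref_train$times[length(ref_train$times)])) / duration
}

#' 1-D Wasserstein distance between ISI distributions
#'
#' Order-1 Wasserstein (earth mover) distance between the empirical
#' distributions of two inter-spike-interval samples, computed as the
#' integral of the absolute difference of the empirical CDFs. For samples
#' of equal size this equals the mean absolute difference of the sorted
#' values. Both sets empty gives 0; exactly one empty gives `empty_penalty`.
#'
#' @param isi_sim,isi_ref numeric vectors of non-negative ISIs (ms).
#' @param empty_penalty value when exactly one set is empty; keeps the
#'   optimization finite instead of undefined.
#' @return distance in ms.
#' @export
isi_wasserstein <- function(isi_sim, isi_ref, empty_penalty = 1000) {
  if (any(isi_sim < 0) || any(isi_ref < 0)) stop("negative ISI")
  n <- length(isi_sim)
  m <- length(isi_ref)
  if (n == 0 && m == 0) return(0)
  if (n == 0 || m == 0) return(empty_penalty)
  x <- sort(isi_sim)
  y <- sort(isi_ref)
  all_v <- sort(unique(c(x, y)))
  if (length(all_v) == 1) return(0)
  # CDF difference integrated over the union grid
  Fx <- findInterval(all_v, x) / n
  Fy <- findInterval(all_v, y) / m
  k <- length(all_v)
  sum(abs(Fx[-k] - Fy[-k]) * diff(all_v))
}

# ISIs of a spike train
isi_of <- function(train) diff(train$times)

#' Multi-component fitness of a simulated trace against a reference
#'
#' Weighted sum of the four components: spike-weighted RMS trace error,
#' spike presence/count penalty, first/last spike timing penalty, and the
#' Wasserstein distance between ISI distributions. Lower is better; 0 is
#' attained only by an identical trace. When `sim` and `ref` are lists of
#' traces (several protocol amplitudes per cell), the total is the mean of
#' per-trace totals. Current (voltage-clamp) references contribute a plain
#' RMS scaled by `current_scale` through the trace component only — the
#' spike-based components do not apply to clamp currents; mixing
#' subthreshold clamp steps into the reference set anchors the
#' conductances that shape subthreshold currents.
#'
#' @param sim,ref voltage [new_trace()]s, or equal-length lists of them.
#' @param weights a [fitness_weights()].
#' @param ref_trains optional list of pre-computed [detect_spikes()]
#'   results for `ref` (an optimization for repeated evaluation against
#'   fixed references).
#' @return an object of class `fitness_report`: list with `total` and a
#'   named `components` vector (for multi-trace input, components are
#'   means across traces).
#' @export
total_fitness <- function(sim, ref, weights = fitness_weights(),
                          ref_trains = NULL) {
  if (inherits(sim, "trace")) sim <- list(sim)
  if (inherits(ref, "trace")) ref <- list(ref)
  stopifnot(length(sim) == length(ref))
  comp <- sapply(seq_along(sim), function(i) {
    if (ref[[i]]$kind == "current") {
      if (sim[[i]]$kind != "current") stop("trace kind mismatch")
      if (length(sim[[i]]$samples) != length(ref[[i]]$samples))
        stop("trace length mismatch")
      rms <- sqrt(mean((sim[[i]]$samples - ref[[i]]$samples)^2))
      return(c(trace = weights$current_scale * rms, spike = 0, timing = 0,
               isi = 0))
    }
    rt <- if (is.null(ref_trains)) detect_spikes(ref[[i]]) else ref_trains[[i]]
    st <- detect_spikes(sim[[i]])
    c(trace = weighted_trace_error(sim[[i]], ref[[i]], weights, rt),
      spike = spike_fidelity_penalty(st, rt, weights),
      timing = timing_penalty(st, rt),
      isi = isi_wasserstein(isi_of(st), isi_of(rt)))
  })
  comps <- rowMeans(comp)
  total <- weights$w_trace * comps["trace"] + weights$w_spike * comps["spike"] +
    weights$w_timing * comps["timing"] + weights$w_isi * comps["isi"]
  structure(list(total = unname(total), components = comps),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("<fitness_report> total", signif(x$total, 5), "|",
      paste(names(x$components), signif(x$components, 4), collapse = ", "),
      "\n")
  invisible(x)
}
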