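#' Built-in condition effects
#'
#' The three study conditions as conductance-multiplier effects on the base
#' model: `aCSF` is the identity; `sevo` potentiates the persistent
#' potassium conductance (KP x 1.5, the Kv1.2 proxy) and SK (x 1.3);
#' `sevo_tstx` models the Kv1.2 pore block attenuating the KP potentiation
#' (KP x 1.1) while leaving the SK effect (x 1.3). The multipliers are
#' synthetic defaults chosen for the recovery experiment, not estimates of
#' the biology: the experimental statistics they emulate establish
#' direction and significance only.
#'
#' @param name `"aCSF"`, `"sevo"` or `"sevo_tstx"`.
#' @return a [condition_effect()].
#' @export
study_condition <- function(name = c("aCSF", "sevo", "sevo_tstx")) {
  name <- match.arg(name)
  switch(name,
    aCSF = condition_effect("aCSF"),
    sevo = condition_effect("sevo", c(KP = 1.5, SK = 1.3)),
    sevo_tstx = condition_effect("sevo_tstx", c(KP = 1.1, SK = 1.3)))
}

#' Synthetic cohort recipe
#'
#' @param n_cells named integer vector: cells per condition; names must
#'   match `conditions`.
#' @param base_model the base [soma_model()].
#' @param conditions named list of [condition_effect()]s.
#' @param cv lognormal coefficient of variation of the inter-cell
#'   conductance variability (truncated-normal for `gamma` and
#'   `tau_decay`).
#' @param noise_sd additive white Gaussian recording noise, in mV for
#'   voltage traces and pA for current traces.
#' @param protocols named list of [stimulus_protocol()]s rendered per cell.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells, base_model = default_soma_model(),
                        conditions = lapply(
                          c(aCSF = "aCSF", sevo = "sevo",
                            sevo_tstx = "sevo_tstx"), study_condition),
                        cv = 0.2, noise_sd = 0.3,
                        protocols = list(steps = protocol_steps(),
                                         ramp = protocol_ramp(),
                                         iv = protocol_iv())) {
  stopifnot(all(n_cells >= 1), cv >= 0, noise_sd >= 0,
            !is.null(names(n_cells)),
            all(names(n_cells) %in% names(conditions)))
  structure(list(n_cells = n_cells, base_model = base_model,
                 conditions = conditions[names(n_cells)], cv = cv,
                 noise_sd = noise_sd, protocols = protocols),
            class = "cohort_spec")
}

#' The shipped study-scale cohort specification
#'
#' Group sizes mirror the type A cohort of the study (aCSF n = 21, sevo
#' n = 9, sevo + TsTX n = 8), with the built-in condition effects
#' ([study_condition()]), 20 percent inter-cell conductance variability and
#' 0.3 mV recording noise.
#'
#' @inheritParams cohort_spec
#' @return a [cohort_spec()].
#' @export
default_study_spec <- function(protocols = list(steps = protocol_steps(),
                                                ramp = protocol_ramp(),
                                                iv = protocol_iv())) {
  cohort_spec(n_cells = c(aCSF = 21, sevo = 9, sevo_tstx = 8),
              protocols = protocols)
}

draw_cell_params <- function(base, cv, bounds_lo = base / 10) {
  if (cv == 0) return(base)
  s <- sqrt(log(1 + cv^2))
  out <- base
  for (nm in names(base)) {
    if (nm %in% c("gamma", "tau_decay")) {
      # truncated normal, strictly positive
      repeat {
        x <- rnorm(1, base[[nm]], cv * base[[nm]])
        if (x > bounds_lo[[nm]] && (nm != "gamma" || x <= 1)) break
      }
      out[[nm]] <- x
    } else {
      out[[nm]] <- base[[nm]] * exp(rnorm(1, -s^2 / 2, s))  # mean-1 factor
    }
  }
  out
}

#' Generate a synthetic ground-truth cohort
#'
#' Per cell: draw true parameters around the base model (lognormal
#' multiplicative variability with unit mean for conductances,
#' truncated-normal for the calcium parameters), apply the cell's condition
#' effect, simulate every protocol, and add i.i.d. Gaussian recording
#' noise. Cells whose simulation fails are redrawn (at most 5 attempts,
#' counted in the result). Deterministic under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return list with `cells` (list of per-cell records: `cell_id`,
#'   `condition`, `params`, `traces` -- a named list following
#'   `spec$protocols`, each a list of traces per amplitude) and
#'   `ground_truth` (data.frame: `cell_id`, `condition`, `parameter`,
#'   `true_value`) and `redraws`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  base <- get_params(spec$base_model)
  cells <- list()
  gt <- list()
  redraws <- 0L
  for (cond in names(spec$n_cells)) {
    eff <- spec$conditions[[cond]]
    for (ci in seq_len(spec$n_cells[[cond]])) {
      cell_id <- sprintf("%s_%02d", cond, ci)
      for (attempt in 1:5) {
        par_drawn <- draw_cell_params(base, spec$cv)
        m <- set_params(spec$base_model, par_drawn)
        m <- apply_condition(m, eff)
        traces <- tryCatch(
          lapply(spec$protocols, function(p) {
            trs <- if (p$mode == "voltage_step") simulate_vc(m, p)
                   else simulate_cc(m, p)
            if (inherits(trs, "trace")) trs <- list(trs)
            lapply(trs, function(tr) {
              if (spec$noise_sd > 0)
                tr$samples <- tr$samples +
                  rnorm(length(tr$samples), 0, spec$noise_sd)
              tr$meta$cell_id <- cell_id
              tr$meta$condition <- cond
              tr
            })
          }),
          error = function(e) NULL)
        if (!is.null(traces)) break
        redraws <- redraws + 1L
      }
      if (is.null(traces))
        stop("cell ", cell_id, " failed to simulate after 5 redraws")
      true_par <- get_params(apply_condition(set_params(spec$base_model,
                                                        par_drawn), eff))
      cells[[cell_id]] <- list(cell_id = cell_id, condition = cond,
                               params = true_par, traces = traces)
      gt[[cell_id]] <- data.frame(cell_id = cell_id, condition = cond,
                                  parameter = names(true_par),
                                  true_value = unname(true_par),
                                  stringsAsFactors = FALSE)
    }
  }
  list(cells = cells, ground_truth = do.call(rbind, c(gt, make.row.names = FALSE)),
       redraws = redraws)
}

# ---- analytic feature fixtures ---------------------------------------------

# piecewise-linear sampler: breakpoints (t, v), linear in between
piecewise_trace <- function(bp_t, bp_v, dt, protocol = NULL, amplitude = NA) {
  tt <- seq(0, bp_t[length(bp_t)], by = dt)
  v <- approx(bp_t, bp_v, xout = tt)$y
  new_trace("voltage", v, dt, protocol, amplitude)
}

#' Analytic current-step fixture with prescribed features
#'
#' Builds piecewise-linear voltage traces whose extracted features equal
#' the requested targets up to sub-sample interpolation error: a -100 pA
#' step trace realizing the requested sag, ADP and hyperpolarization, and a
#' +250 pA step trace realizing the requested AHP.
#'
#' @param sag,adp_mv,ahp_mv target magnitudes (mV), >= 0.
#' @param rest resting potential (mV).
#' @param hyperpolarization target steady-state hyperpolarization (mV),
#'   must be >= sag (the minimum lies below the steady state).
#' @param dt sample interval (ms).
#' @return list with `step_m100` and `step_p250` voltage traces (protocol
#'   annotated, 200/1000/300 ms pre/stim/post).
#' @export
make_feature_fixture <- function(sag = 4, adp_mv = 3, ahp_mv = 3,
                                 rest = -65, hyperpolarization = 11,
                                 dt = 0.025) {
  stopifnot(sag >= 0, adp_mv >= 0, ahp_mv >= 0, hyperpolarization >= 0)
  steady <- rest - hyperpolarization
  vmin <- steady - sag
  p_m100 <- stimulus_protocol("current_step", 200, 1000, 300, -100, dt = dt)
  tr1 <- piecewise_trace(
    c(0, 200, 250, 350, 1200, 1250, 1300, 1500),
    c(rest, rest, vmin, steady, steady, rest + adp_mv, rest, rest),
    dt, p_m100, -100)

  p_p250 <- stimulus_protocol("current_step", 200, 1000, 300, 250, dt = dt)
  top <- rest + 10
  tr2 <- piecewise_trace(
    c(0, 200, 210, 1200, 1250, 1300, 1500),
    c(rest, rest, top, top, rest - ahp_mv, rest, rest),
    dt, p_p250, 250)
  list(step_m100 = tr1, step_p250 = tr2)
}

#' Triangular action-potential fixture
#'
#' A baseline trace carrying `n` triangular spikes with prescribed
#' threshold, peak, rise and fall times. The approach from baseline to
#' threshold is a slow ramp (below the slope criterion), so spike detection
#' locates the threshold exactly at the triangle corner.
#'
#' @param n number of spikes.
#' @param times spike (threshold-corner) times (ms).
#' @param threshold,peak corner and apex voltages (mV).
#' @param rise_ms,fall_ms rise and fall durations (ms).
#' @param baseline resting level (mV).
#' @param total_ms trace duration (ms).
#' @param dt sample interval (ms); breakpoints snap to the sample grid.
#' @param protocol optional protocol annotation.
#' @param amplitude optional amplitude annotation.
#' @return a voltage [new_trace()].
#' @export
make_spike_fixture <- function(n = 5, times = seq(100, by = 100, length.out = n),
                               threshold = -40, peak = 20, rise_ms = 0.5,
                               fall_ms = 1, baseline = -65, total_ms = NULL,
                               dt = 0.025, protocol = NULL, amplitude = NA) {
  stopifnot(length(times) == n, peak > threshold, rise_ms > 0, fall_ms > 0)
  if (is.null(total_ms)) total_ms <- max(times) + 50
  approach <- 5  # ms of slow sub-criterion ramp up to threshold
  bp_t <- 0
  bp_v <- baseline
  for (tk in times) {
    # rise threshold -> peak over rise_ms, fall peak -> threshold over
    # fall_ms (so rise/fall slopes are amplitude/rise and amplitude/fall),
    # then a brief return to baseline
    bp_t <- c(bp_t, tk - approach, tk, tk + rise_ms, tk + rise_ms + fall_ms,
              tk + rise_ms + fall_ms + 2)
    bp_v <- c(bp_v, baseline, threshold, peak, threshold, baseline)
  }
  bp_t <- c(bp_t, total_ms)
  bp_v <- c(bp_v, baseline)
  if (is.unsorted(bp_t, strictly = TRUE))
    stop("spikes too close together for the fixture construction")
  piecewise_trace(bp_t, bp_v, dt, protocol, amplitude)
}
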