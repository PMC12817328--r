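#' Voltage- or calcium-dependent gating variable
#'
#' A gate contributes `x^power` to its channel's open fraction. Voltage gates
#' follow a Boltzmann steady state
#' \deqn{x_\infty(V) = 1 / (1 + \exp((V_{1/2} + \Delta V - V)/k))}
#' where `slope` \eqn{k > 0} encodes activation and \eqn{k < 0} inactivation,
#' and `v_shift` \eqn{\Delta V} is an additive shift of the voltage
#' dependence (used for the built-in -3 mV leftward shift of persistent-K
#' activation). Calcium-sensing gates (`sensor = "ca"`) use a Hill function
#' of intracellular calcium, with `v_half` read as the half-activating
#' concentration in mM and `slope` as the Hill exponent.
#'
#' @param power non-negative integer exponent.
#' @param v_half half-activation voltage (mV), or half-activation calcium
#'   concentration (mM) for calcium-sensing gates.
#' @param slope Boltzmann slope factor (mV); sign selects activation vs
#'   inactivation. Hill exponent for calcium gates.
#' @param tau_family one of `"constant"`, `"bell"`, `"sigmoid"`.
#' @param tau_constants numeric vector of time-constant parameters (ms scale):
#'   `constant` uses `c(tau)`; `bell` uses `c(base, amp, v_mid, k_left,
#'   k_right)` for `base + amp/(exp((v-v_mid)/k_left)+exp(-(v-v_mid)/k_right))`;
#'   `sigmoid` uses `c(base, amp, v_mid, k)` for
#'   `base + amp/(1+exp((v-v_mid)/k))`.
#' @param v_shift additive shift (mV) on the voltage dependence; default 0.
#' @param sensor `"v"` (default) or `"ca"`.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(power, v_half, slope, tau_family = "constant",
                      tau_constants = 1, v_shift = 0, sensor = "v") {
  stopifnot(length(power) == 1, power >= 0, power == round(power))
  if (slope == 0) stop("gate slope must be non-zero")
  tau_family <- match.arg(tau_family, c("constant", "bell", "sigmoid"))
  sensor <- match.arg(sensor, c("v", "ca"))
  need <- c(constant = 1, bell = 5, sigmoid = 4)[[tau_family]]
  if (length(tau_constants) < need)
    stop("tau_family '", tau_family, "' needs ", need, " constants")
  structure(list(power = as.integer(power), v_half = v_half, slope = slope,
                 tau_family = tau_family, tau_constants = tau_constants,
                 v_shift = v_shift, sensor = sensor),
            class = "gate_spec")
}

#' Gate steady-state open fraction
#'
#' @param gate a [gate_spec()].
#' @param v membrane potential (mV); must be finite.
#' @param ca intracellular calcium (mM), needed for calcium-sensing gates.
#' @return steady-state fraction in \[0, 1\].
#' @export
gate_steady_state <- function(gate, v, ca = 1e-4) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!all(is.finite(v))) stop("non-finite voltage")
  if (gate$sensor == "ca") {
    return(1 / (1 + (gate$v_half / pmax(ca, 1e-12))^gate$slope))
  }
  1 / (1 + exp((gate$v_half + gate$v_shift - v) / gate$slope))
}

#' Gate time constant at a voltage
#' @inheritParams gate_steady_state
#' @return time constant (ms).
#' @export
gate_tau <- function(gate, v) {
  tc <- gate$tau_constants
  switch(gate$tau_family,
    constant = rep_len(tc[1], length(v)),
    bell = tc[1] + tc[2] / (exp((v - tc[3]) / tc[4]) + exp(-(v - tc[3]) / tc[5])),
    sigmoid = tc[1] + tc[2] / (1 + exp((v - tc[3]) / tc[4]))
  )
}

#' Membrane conductance specification
#'
#' @param id channel identifier; one of `NaT`, `NaP`, `KT`, `KP`, `SKv3_1`,
#'   `SK`, `Ca_HVA`, `Ca_LVA`, `leak`.
#' @param gbar maximal conductance density (S/cm2), non-negative.
#' @param erev fixed reversal potential (mV); ignored when
#'   `reversal_mode = "nernst_ca"`.
#' @param gates list of [gate_spec()] objects (empty for leak).
#' @param reversal_mode `"fixed"` or `"nernst_ca"` (instantaneous calcium
#'   Nernst potential; calcium channels only).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(id, gbar, erev = 0, gates = list(),
                         reversal_mode = c("fixed", "nernst_ca")) {
  id <- match.arg(id, c("NaT", "NaP", "KT", "KP", "SKv3_1", "SK",
                        "Ca_HVA", "Ca_LVA", "leak"))
  reversal_mode <- match.arg(reversal_mode)
  if (gbar < 0) stop("gbar must be >= 0")
  if (reversal_mode == "nernst_ca" && !id %in% c("Ca_HVA", "Ca_LVA"))
    stop("Nernst-from-calcium reversal is only valid for calcium channels")
  stopifnot(all(vapply(gates, inherits, logical(1), "gate_spec")))
  structure(list(id = id, gbar = gbar, erev = erev, gates = gates,
                 reversal_mode = reversal_mode),
            class = "channel_spec")
}

#' Intracellular calcium pool dynamics
#'
#' A single submembrane shell: influx through calcium channels scaled by the
#' free-calcium fraction `gamma`, first-order decay back to `ca_rest`.
#'
#' @param gamma free (unbuffered) calcium fraction, in (0, 1].
#' @param tau_decay decay time constant (ms), > 0.
#' @param ca_rest resting calcium concentration (mM), > 0.
#' @param shell_depth submembrane shell depth (um).
#' @return an object of class `calcium_dynamics`.
#' @export
calcium_dynamics <- function(gamma = 0.05, tau_decay = 80, ca_rest = 1e-4,
                             shell_depth = 1) {
  stopifnot(gamma > 0, gamma <= 1, tau_decay > 0, ca_rest > 0,
            shell_depth > 0)
  structure(list(gamma = gamma, tau_decay = tau_decay, ca_rest = ca_rest,
                 shell_depth = shell_depth),
            class = "calcium_dynamics")
}

#' Single-compartment somatic neuron model
#'
#' @param area somatic membrane area (um2).
#' @param cm specific capacitance (uF/cm2).
#' @param channels list of [channel_spec()]; must contain exactly one leak.
#' @param calcium a [calcium_dynamics()].
#' @param e_na,e_k fixed sodium / potassium reversal potentials (mV).
#' @param ca_out extracellular calcium (mM), for the Nernst reversal.
#' @param temperature recording temperature (deg C); kinetics are defined at
#'   this temperature, no Q10 scaling is applied.
#' @param holding holding potential (mV) defining the clamped resting state.
#' @return an object of class `soma_model`.
#' @export
soma_model <- function(area, cm, channels, calcium = calcium_dynamics(),
                       e_na = 50, e_k = -85, ca_out = 2,
                       temperature = 25, holding = -67) {
  stopifnot(area > 0, cm > 0, inherits(calcium, "calcium_dynamics"))
  ids <- vapply(channels, `[[`, character(1), "id")
  if (sum(ids == "leak") != 1) stop("model needs exactly one leak channel")
  if (anyDuplicated(ids)) stop("duplicate channel ids")
  names(channels) <- ids
  structure(list(area = area, cm = cm, channels = channels,
                 calcium = calcium, e_na = e_na, e_k = e_k, ca_out = ca_out,
                 temperature = temperature, holding = holding),
            class = "soma_model")
}

#' @export
print.soma_model <- function(x, ...) {
  cat("<soma_model> area", x$area, "um2, cm", x$cm, "uF/cm2, holding",
      x$holding, "mV\n")
  for (ch in x$channels)
    cat(sprintf("  %-7s gbar %.5g S/cm2 (%d gate%s)\n", ch$id, ch$gbar,
                length(ch$gates), if (length(ch$gates) == 1) "" else "s"))
  invisible(x)
}

# flatten an S3 soma_model into the plain list the C++ integrator reads
flatten_model <- function(model) {
  chans <- lapply(model$channels, function(ch) {
    erev <- ch$erev
    if (ch$id %in% c("NaT", "NaP")) erev <- model$e_na
    if (ch$id %in% c("KT", "KP", "SKv3_1", "SK")) erev <- model$e_k
    gates <- lapply(ch$gates, function(g) {
      list(power = g$power, v_half = g$v_half, slope = g$slope,
           v_shift = g$v_shift,
           tau_family = match(g$tau_family,
                              c("constant", "bell", "sigmoid")) - 1L,
           tau_constants = as.numeric(g$tau_constants),
           ca_sensor = identical(g$sensor, "ca"))
    })
    list(gbar = ch$gbar, rev_mode = if (ch$reversal_mode == "nernst_ca") 1L else 0L,
         erev = erev, gates = unname(gates))
  })
  list(area_cm2 = model$area * 1e-8, cm = model$cm,
       ca_gamma = model$calcium$gamma, ca_tau = model$calcium$tau_decay,
       ca_rest = model$calcium$ca_rest, ca_depth = model$calcium$shell_depth,
       ca_out = model$ca_out, channels = unname(chans))
}

#' Default thick-tufted L5b somatic model
#'
#' The shipped baseline parameter table: a point-soma reduction with
#' transient and persistent sodium (NaT, NaP), transient and persistent
#' potassium (KT, KP), delayed rectifier (SKv3_1), calcium-activated
#' potassium (SK), high- and low-voltage-activated calcium channels and a
#' fixed leak. Kinetics are Boltzmann steady states with bell/sigmoid time
#' constants in the spirit of published thick-tufted L5b somatic mechanisms;
#' the exact constants are this package's own documented defaults. The
#' persistent-K activation curve carries a built-in -3 mV leftward shift
#' (present in every condition), reflecting anesthetic-sensitive Kv1.2
#' steady-state gating.
#'
#' @param gbar named numeric vector overriding default conductance densities
#'   (S/cm2) for any of the tunable channels.
#' @return a [soma_model()].
#' @export
default_soma_model <- function(gbar = NULL) {
  g <- c(NaT = 1.5, NaP = 2e-4, KT = 0.1, KP = 0.35, SKv3_1 = 0.6,
         SK = 0.01, Ca_HVA = 3e-4, Ca_LVA = 1e-3)
  if (!is.null(gbar)) {
    bad <- setdiff(names(gbar), names(g))
    if (length(bad)) stop("unknown channel id: ", paste(bad, collapse = ", "))
    g[names(gbar)] <- gbar
  }
  ch <- list(
    channel_spec("NaT", g[["NaT"]], gates = list(
      gate_spec(3, -35, 6, "bell", c(0.15, 0.3, -38, 10, 10)),
      gate_spec(1, -66, -6, "bell", c(0.25, 1.5, -66, 10, 10)))),
    channel_spec("NaP", g[["NaP"]], gates = list(
      gate_spec(3, -52.6, 4.6, "constant", 1),
      gate_spec(1, -48.8, -10, "constant", 1000))),
    channel_spec("KT", g[["KT"]], gates = list(
      gate_spec(4, -25, 12, "bell", c(0.5, 3, -30, 20, 20)),
      gate_spec(1, -76, -10, "constant", 20))),
    channel_spec("KP", g[["KP"]], gates = list(
      gate_spec(2, -11, 10, "bell", c(2, 30, -40, 25, 25), v_shift = -3),
      gate_spec(1, -64, -11, "constant", 2000))),
    channel_spec("SKv3_1", g[["SKv3_1"]], gates = list(
      gate_spec(2, 18.7, 9.7, "bell", c(0.5, 3, -20, 30, 30)))),
    channel_spec("SK", g[["SK"]], gates = list(
      gate_spec(1, 4.3e-4, 4.8, "constant", 1, sensor = "ca"))),
    channel_spec("Ca_HVA", g[["Ca_HVA"]], reversal_mode = "nernst_ca", gates = list(
      gate_spec(2, -27, 6, "bell", c(0.5, 1.5, -27, 12, 12)),
      gate_spec(1, -49, -9, "constant", 400))),
    channel_spec("Ca_LVA", g[["Ca_LVA"]], reversal_mode = "nernst_ca", gates = list(
      gate_spec(2, -40, 6, "sigmoid", c(5, 20, -35, 5)),
      gate_spec(1, -90, -6.4, "sigmoid", c(20, 50, -50, 7)))),
    channel_spec("leak", 3e-5, erev = -60)
  )
  soma_model(area = 10000, cm = 1,
             channels = ch,
             calcium = calcium_dynamics(gamma = 0.05, tau_decay = 80,
                                        ca_rest = 1e-4, shell_depth = 1))
}

#' Names of the tunable somatic parameters
#'
#' The free parameters of the model-fitting problem: all channel conductance
#' densities except leak (which is fixed), plus the calcium free fraction
#' `gamma` and decay time constant `tau_decay`.
#' @return character vector of parameter names.
#' @export
tunable_params <- function() {
  c("NaT", "NaP", "KT", "KP", "SKv3_1", "SK", "Ca_HVA", "Ca_LVA",
    "gamma", "tau_decay")
}

#' Read tunable parameter values from a model
#' @param model a [soma_model()].
#' @return named numeric vector in [tunable_params()] order.
#' @export
get_params <- function(model) {
  p <- vapply(tunable_params(), function(nm) {
    switch(nm,
      gamma = model$calcium$gamma,
      tau_decay = model$calcium$tau_decay,
      model$channels[[nm]]$gbar)
  }, numeric(1))
  p
}

#' Build a model from a tunable parameter vector
#' @param template a [soma_model()] supplying everything non-tunable.
#' @param theta named (or [tunable_params()]-ordered) numeric vector.
#' @return a new [soma_model()].
#' @export
set_params <- function(template, theta) {
  if (is.null(names(theta))) names(theta) <- tunable_params()
  m <- template
  for (nm in names(theta)) {
    if (nm == "gamma") m$calcium$gamma <- theta[[nm]]
    else if (nm == "tau_decay") m$calcium$tau_decay <- theta[[nm]]
    else if (nm %in% names(m$channels)) m$channels[[nm]]$gbar <- theta[[nm]]
    else stop("unknown tunable parameter: ", nm)
  }
  m
}

#' Experimental condition effect on a model
#'
#' A condition multiplies selected channel conductance densities and may add
#' extra gate voltage shifts. The built-in -3 mV persistent-K activation
#' shift belongs to the base model (all conditions), not to effects.
#'
#' @param name condition label.
#' @param multipliers named non-negative numeric vector of gbar multipliers
#'   per channel id.
#' @param gate_shifts named numeric vector of additional activation-gate
#'   voltage shifts (mV) per channel id.
#' @return an object of class `condition_effect`.
#' @export
condition_effect <- function(name = "custom", multipliers = numeric(),
                             gate_shifts = numeric()) {
  if (length(multipliers) && (is.null(names(multipliers)) ||
                              any(!nzchar(names(multipliers)))))
    stop("multipliers must be named by channel id")
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  if (any(!is.finite(gate_shifts))) stop("gate shifts must be finite")
  structure(list(name = name, multipliers = multipliers,
                 gate_shifts = gate_shifts),
            class = "condition_effect")
}

#' Apply a condition effect to a model
#'
#' @param model a [soma_model()]; left unchanged.
#' @param effect a [condition_effect()].
#' @return a new [soma_model()] with multipliers and shifts applied.
#' @export
apply_condition <- function(model, effect) {
  stopifnot(inherits(model, "soma_model"), inherits(effect, "condition_effect"))
  known <- names(model$channels)
  bad <- setdiff(c(names(effect$multipliers), names(effect$gate_shifts)), known)
  if (length(bad)) stop("unknown channel id in effect: ", paste(bad, collapse = ", "))
  m <- model
  for (nm in names(effect$multipliers))
    m$channels[[nm]]$gbar <- m$channels[[nm]]$gbar * effect$multipliers[[nm]]
  for (nm in names(effect$gate_shifts)) {
    # shift applies to activation gates (positive slope / ca gates excluded)
    gs <- m$channels[[nm]]$gates
    for (j in seq_along(gs)) {
      if (gs[[j]]$sensor == "v" && gs[[j]]$slope > 0)
        gs[[j]]$v_shift <- gs[[j]]$v_shift + effect$gate_shifts[[nm]]
    }
    m$channels[[nm]]$gates <- gs
  }
  m
}
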