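test_that("gate steady state is a Boltzmann with shift and saturation", {
  g <- gate_spec(1, v_half = -40, slope = 6)
  expect_equal(gate_steady_state(g, -40), 0.5)
  expect_equal(gate_steady_state(g, 200), 1, tolerance = 1e-10)
  expect_equal(gate_steady_state(g, -300), 0, tolerance = 1e-10)
  # monotone in v for positive slope
  vs <- seq(-100, 50, by = 5)
  expect_true(all(diff(gate_steady_state(g, vs)) > 0))
  expect_error(gate_steady_state(g, NaN), "non-finite")

  # the persistent-K activation gate carries the built-in -3 mV left shift:
  # half-activation sits 3 mV hyperpolarized from its nominal v_half
  kp <- default_soma_model()$channels$KP$gates[[1]]
  expect_equal(kp$v_shift, -3)
  expect_equal(gate_steady_state(kp, kp$v_half - 3), 0.5)
})

test_that("passive step responses match the analytic RC solution", {
  m <- passive_model(g_nS = 5, c_pF = 100, e_leak = -70)
  p <- stimulus_protocol("current_step", 100, 500, 200, -100, dt = 0.025)
  tr <- simulate_cc(m, p)
  tt <- trace_times(tr)
  tau <- 100 / 5                                  # C/g = 20 ms
  dV <- -100 * 200 * 1e-3                         # I*R = -20 mV
  v_ref <- rep(-70, length(tt))
  in_stim <- tt >= 100 & tt <= 600
  v_ref[in_stim] <- -70 + dV * (1 - exp(-(tt[in_stim] - 100) / tau))
  post <- tt > 600
  v_end <- -70 + dV * (1 - exp(-500 / tau))
  v_ref[post] <- -70 + (v_end + 70) * exp(-(tt[post] - 600) / tau)
  expect_lt(max(abs(tr$samples - v_ref)), 0.1)
  # relaxes towards -90 mV
  expect_equal(min(tr$samples), -90, tolerance = 0.01)
})

test_that("zero-amplitude step preserves the clamped resting state", {
  m <- default_model_cached()
  tr <- simulate_cc(m, stimulus_protocol("current_step", 100, 500, 100, 0))
  expect_lt(max(abs(tr$samples - m$holding)), 0.05)
})

test_that("ideal voltage clamp obeys Ohm's law and reversal identities", {
  # leak-only, e_leak = holding = -67: a -67 -> -62 step draws +25 pA
  m <- passive_model(g_nS = 5, e_leak = -67, holding = -67)
  tr <- simulate_vc(m, stimulus_protocol("voltage_step", 50, 200, 50, -62))
  expect_equal(steady_state_current(tr), 25, tolerance = 1e-6)

  # K-channels plus leak all reversing at e_k: zero current when clamped there
  mk <- default_soma_model(c(NaT = 0, NaP = 0, Ca_HVA = 0, Ca_LVA = 0))
  mk$channels$leak$erev <- mk$e_k
  trk <- simulate_vc(mk, stimulus_protocol("voltage_step", 50, 200, 50, mk$e_k))
  expect_lt(abs(steady_state_current(trk)), 1e-6)
})

test_that("clamp current at holding equals the current-clamp bias current", {
  m <- default_model_cached()
  tr <- simulate_vc(m, stimulus_protocol("voltage_step", 50, 300, 50,
                                         m$holding))
  expect_equal(steady_state_current(tr), holding_current(m),
               tolerance = 1e-6)
})

test_that("simulation is deterministic", {
  m <- default_model_cached()
  p <- stimulus_protocol("current_step", 100, 300, 100, 250)
  expect_identical(simulate_cc(m, p)$samples, simulate_cc(m, p)$samples)
})

test_that("halving the step size preserves the spike count and converges", {
  m <- default_model_cached()
  count_at <- function(dt) {
    tr <- simulate_cc(m, stimulus_protocol("current_step", 200, 1000, 300,
                                           250, dt = dt))
    n_spikes(detect_spikes(tr))
  }
  expect_identical(count_at(0.025), count_at(0.0125))

  times_at <- function(dt) {
    tr <- simulate_cc(m, stimulus_protocol("current_step", 200, 500, 100,
                                           250, dt = dt))
    detect_spikes(tr)$times
  }
  t1 <- times_at(0.00625)
  t2 <- times_at(0.003125)
  expect_identical(length(t1), length(t2))
  expect_lt(max(abs(t1 - t2)), 0.5)
})

test_that("condition effects multiply conductances without touching inputs", {
  m <- default_model_cached()
  expect_equal(apply_condition(m, condition_effect("aCSF")), m)

  eff <- condition_effect("x", c(KP = 1.5))
  m2 <- apply_condition(m, eff)
  expect_equal(m2$channels$KP$gbar, 1.5 * m$channels$KP$gbar)
  m2$channels$KP$gbar <- m$channels$KP$gbar
  expect_equal(m2, m)                             # nothing else changed

  m3 <- apply_condition(apply_condition(m, eff),
                        condition_effect("inv", c(KP = 2 / 3)))
  expect_equal(m3$channels$KP$gbar, m$channels$KP$gbar)

  expect_error(apply_condition(m, condition_effect("bad", c(HCN = 2))),
               "unknown channel")
  expect_error(condition_effect("bad", c(KP = -1)), ">= 0")
})

test_that("gate shifts in condition effects move activation curves", {
  m <- default_model_cached()
  eff <- condition_effect("shift", gate_shifts = c(KP = -5))
  m2 <- apply_condition(m, eff)
  g0 <- m$channels$KP$gates[[1]]
  g2 <- m2$channels$KP$gates[[1]]
  expect_equal(g2$v_shift, g0$v_shift - 5)
  # inactivation gate (negative slope) untouched
  expect_equal(m2$channels$KP$gates[[2]], m$channels$KP$gates[[2]])
})

test_that("model constructors enforce their invariants", {
  expect_error(gate_spec(1, -40, 0), "non-zero")
  expect_error(channel_spec("KP", -1), ">= 0")
  expect_error(channel_spec("KP", 0.1, reversal_mode = "nernst_ca"),
               "calcium")
  expect_error(calcium_dynamics(gamma = 0))
  expect_error(soma_model(100, 1, list(channel_spec("KP", 0.1))),
               "leak")
  expect_error(default_soma_model(c(HCN = 1)), "unknown channel")
  expect_error(stimulus_protocol("current_ramp", 100, 500, 100, 300),
               "ramp_start")
})
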