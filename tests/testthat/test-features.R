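test_that("spike detection finds constructed spikes and rejects flat traces", {
  flat <- new_trace("voltage", rep(-65, 4000), 0.025)
  expect_identical(n_spikes(detect_spikes(flat)), 0L)

  times <- c(100, 180, 260, 340, 420)
  fx <- make_spike_fixture(5, times = times)
  train <- detect_spikes(fx)
  expect_identical(n_spikes(train), 5L)
  expect_true(all(abs(train$times - times) <= fx$dt))
  expect_equal(train$threshold_v, rep(-40, 5), tolerance = 1e-6)
  expect_equal(train$peak_v, rep(20, 5), tolerance = 1e-6)

  expect_error(detect_spikes(new_trace("voltage", c(-65, -65), 0.025)),
               "short")
  expect_error(detect_spikes(new_trace("current", rep(0, 10), 0.025)),
               "voltage")
})

test_that("spike detection agrees with a local-maximum oracle on simulations", {
  m <- default_model_cached()
  for (amp in c(150, 250, 350)) {
    tr <- simulate_cc(m, stimulus_protocol("current_step", 200, 1000, 300,
                                           amp))
    expect_identical(n_spikes(detect_spikes(tr)), oracle_spike_count(tr),
                     info = paste(amp, "pA"))
  }
})

test_that("resting potential averages the first 100 ms only", {
  flat <- new_trace("voltage", rep(-65, 8001), 0.025)
  expect_equal(resting_vm(flat), -65)

  set.seed(42)
  noisy <- new_trace("voltage", rep(-65, 8001) + rnorm(8001, 0, 0.5), 0.025)
  expect_equal(resting_vm(noisy), -65, tolerance = 0.05)

  tt <- seq(0, 200, by = 0.05)
  seg <- new_trace("voltage", ifelse(tt <= 100, -60, -70), 0.05)
  expect_equal(resting_vm(seg), -60, tolerance = 0.01)

  p_short <- stimulus_protocol("current_step", 50, 100, 100, 0, dt = 0.025)
  short <- new_trace("voltage", rep(-65, round(250 / 0.025) + 1), 0.025,
                     protocol = p_short)
  expect_error(resting_vm(short), "100 ms")
})

test_that("input resistance follows Ohm's law", {
  expect_equal(input_resistance(-5, -25), 200)
  expect_equal(input_resistance(-5, -50), 100)
  expect_error(input_resistance(-5, 0), "non-zero")

  m <- passive_model(g_nS = 5, e_leak = -67, holding = -67)
  expect_equal(measure_rin(m), 200, tolerance = 1)
})

test_that("threshold is read from the first spike only", {
  fx <- make_spike_fixture(3, times = c(100, 200, 300), threshold = -40)
  train <- detect_spikes(fx)
  expect_equal(ap_threshold(train), -40, tolerance = 1e-6)
  # truncate to the first spike: unchanged
  fx1 <- make_spike_fixture(1, times = 100, threshold = -40)
  expect_equal(ap_threshold(detect_spikes(fx1)), ap_threshold(train))
  # empty train: undefined, not zero
  expect_true(is.na(ap_threshold(detect_spikes(
    new_trace("voltage", rep(-65, 100), 0.025)))))
})

test_that("rheobase interpolates the ramp at the first threshold crossing", {
  p <- stimulus_protocol("current_ramp", 200, 500, 100, 450,
                         ramp_start = -50, dt = 0.025)
  mk_ramp <- function(spike_at_ms) {
    make_spike_fixture(1, times = spike_at_ms, total_ms = 800, dt = 0.025,
                       protocol = p, amplitude = 450)
  }
  # crossing at 300 ms into the ramp: -50 + 0.6 * 500 = 250 pA
  expect_equal(rheobase(mk_ramp(500)), 250, tolerance = 0.5)
  # boundary: crossing at ramp onset -> ramp_start
  expect_equal(rheobase(mk_ramp(200)), -50, tolerance = 0.5)
  # boundary: crossing at ramp end -> peak current
  expect_equal(rheobase(mk_ramp(700)), 450, tolerance = 0.5)
  # no spike -> undefined
  quiet <- new_trace("voltage", rep(-65, round(800 / 0.025) + 1), 0.025, p,
                     450)
  expect_true(is.na(rheobase(quiet)))
  expect_error(rheobase(make_spike_fixture(1)), "ramp")
})

test_that("AP amplitude and half-width follow the crossing algebra", {
  fx <- make_spike_fixture(1, threshold = -40, peak = 20, rise_ms = 0.5,
                           fall_ms = 1)
  s <- ap_shape(fx, detect_spikes(fx))
  expect_equal(s$amplitude, 60, tolerance = 1e-6)
  expect_equal(s$half_width, 0.75, tolerance = 0.025)

  sym <- make_spike_fixture(1, rise_ms = 1, fall_ms = 1)
  expect_equal(ap_shape(sym, detect_spikes(sym))$half_width, 1,
               tolerance = 0.025)

  slow_fall <- make_spike_fixture(1, rise_ms = 0.5, fall_ms = 2)
  expect_equal(ap_shape(slow_fall, detect_spikes(slow_fall))$half_width,
               1.25, tolerance = 0.025)

  empty <- detect_spikes(new_trace("voltage", rep(-65, 100), 0.025))
  expect_true(is.na(ap_shape(new_trace("voltage", rep(-65, 100), 0.025),
                             empty)$amplitude))
})

test_that("sag, hyperpolarization, ADP and AHP recover fixture targets", {
  fx <- make_feature_fixture(sag = 4, adp_mv = 3, ahp_mv = 3, rest = -65,
                             hyperpolarization = 11)
  sh <- sag_and_hyperpolarization(fx$step_m100)
  expect_equal(sh$sag, 4, tolerance = 0.01)
  expect_equal(sh$hyperpolarization, 11, tolerance = 0.01)
  expect_equal(adp(fx$step_m100), 3, tolerance = 0.01)
  expect_equal(ahp(fx$step_p250), 3, tolerance = 0.01)

  # passive response (min equals steady state): zero sag
  fx0 <- make_feature_fixture(sag = 0, adp_mv = 0, ahp_mv = 0)
  expect_equal(sag_and_hyperpolarization(fx0$step_m100)$sag, 0,
               tolerance = 1e-9)
  expect_equal(adp(fx0$step_m100), 0, tolerance = 0.01)
  expect_equal(ahp(fx0$step_p250), 0, tolerance = 0.01)

  # deepening the AHP trough by 1 mV raises AHP by exactly 1 mV
  fx1 <- make_feature_fixture(ahp_mv = 4)
  expect_equal(ahp(fx1$step_p250) - ahp(fx$step_p250), 1, tolerance = 0.01)

  # wrong amplitude rejected
  expect_error(sag_and_hyperpolarization(fx$step_p250), "-100")
  expect_error(ahp(fx$step_m100), "250")
})

test_that("additive voltage offsets shift rest/threshold but not magnitudes", {
  fx <- make_feature_fixture(sag = 4, adp_mv = 3, ahp_mv = 3)
  off <- 2
  sh0 <- sag_and_hyperpolarization(fx$step_m100)
  tr_off <- fx$step_m100
  tr_off$samples <- tr_off$samples + off
  sh1 <- sag_and_hyperpolarization(tr_off)
  expect_equal(sh1$sag, sh0$sag, tolerance = 1e-9)
  expect_equal(sh1$hyperpolarization, sh0$hyperpolarization,
               tolerance = 1e-9)
  expect_equal(adp(tr_off), adp(fx$step_m100), tolerance = 1e-9)
  expect_equal(resting_vm(tr_off), resting_vm(fx$step_m100) + off)

  sp <- make_spike_fixture(2, times = c(100, 200))
  sp_off <- sp
  sp_off$samples <- sp$samples + off
  s0 <- ap_shape(sp, detect_spikes(sp))
  s1 <- ap_shape(sp_off, detect_spikes(sp_off))
  expect_equal(s1$amplitude, s0$amplitude, tolerance = 1e-6)
  expect_equal(s1$half_width, s0$half_width, tolerance = 1e-6)
  expect_equal(ap_threshold(detect_spikes(sp_off)),
               ap_threshold(detect_spikes(sp)) + off, tolerance = 1e-6)
})

test_that("ADP excises rebound spikes before taking the window maximum", {
  fx <- make_feature_fixture(sag = 4, adp_mv = 3, rest = -65)
  tr <- fx$step_m100
  # inject a low-threshold rebound AP rising out of the ADP envelope inside
  # the 200 ms post window; threshold-to-threshold excision removes it
  spike <- make_spike_fixture(1, times = 1260, threshold = -62, peak = 20,
                              baseline = -65, total_ms = 1500, dt = tr$dt)
  tr$samples <- pmax(tr$samples, spike$samples)
  expect_equal(adp(tr), 3, tolerance = 0.05)
})

test_that("firing frequency counts spikes inside the 1 s stimulus window", {
  p <- stimulus_protocol("current_step", 200, 1000, 300, 250, dt = 0.025)
  fx <- make_spike_fixture(14, times = seq(250, 1150, length.out = 14),
                           total_ms = 1500, dt = 0.025, protocol = p,
                           amplitude = 250)
  expect_equal(firing_frequency(fx), 14)

  sub <- new_trace("voltage", rep(-60, round(1500 / 0.025) + 1), 0.025, p,
                   250)
  expect_equal(firing_frequency(sub), 0)

  # a rebound spike after stimulus offset does not count
  fx2 <- make_spike_fixture(15, times = c(seq(250, 1150, length.out = 14),
                                          1300),
                            total_ms = 1500, dt = 0.025, protocol = p,
                            amplitude = 250)
  expect_equal(firing_frequency(fx2), 14)

  p2 <- stimulus_protocol("current_step", 200, 500, 300, 250, dt = 0.025)
  short <- new_trace("voltage", rep(-60, round(1000 / 0.025) + 1), 0.025,
                     p2, 250)
  expect_error(firing_frequency(short), "1 s")
})

test_that("subtype classification applies the 6.5 mV sum criterion", {
  expect_identical(classify_subtype(3.56, 3.58, 4.02), "A")
  expect_identical(classify_subtype(1.18, 0.99, 1.12), "B")
  expect_identical(classify_subtype(6.5, 0, 0), "B")       # strict >
  expect_identical(classify_subtype(NA, 1, 1), "unclassified")

  # monotone: increasing any input never flips A to B
  set.seed(7)
  for (i in 1:50) {
    x <- runif(3, 0, 4)
    a <- classify_subtype(x[1], x[2], x[3])
    if (a == "A") {
      j <- sample(3, 1)
      x[j] <- x[j] + runif(1, 0, 3)
      expect_identical(classify_subtype(x[1], x[2], x[3]), "A")
    }
  }
})

test_that("extract_features assembles the full per-cell vector", {
  m <- default_model_cached()
  steps <- simulate_cc(m, protocol_steps(c(-100, 250)))
  ramp <- simulate_cc(m, protocol_ramp(300))
  ft <- extract_features(steps, ramp, rin = measure_rin(m))
  expect_equal(ft$vm_rest, m$holding, tolerance = 0.1)
  expect_gt(ft$r_in, 0)
  expect_true(ft$freq_250 > 0)
  expect_true(ft$subtype %in% c("A", "B"))
  expect_false(anyNA(ft[c("ap_threshold", "rheobase", "ap_amplitude",
                          "ap_half_width", "sag", "adp", "ahp")]))
})
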