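test_that("steady-state current averages the final window", {
  p <- stimulus_protocol("voltage_step", 100, 500, 100, -62, dt = 0.05)
  n <- round(700 / 0.05) + 1
  const <- new_trace("current", rep(25, n), 0.05, p, -62)
  expect_equal(steady_state_current(const), 25)
  expect_equal(steady_state_current(const, window_ms = 500), 25)

  # exponential settling to 25 pA with tau = 10 ms: analytic tail average
  tt <- (seq_len(n) - 1) * 0.05
  settle <- ifelse(tt < 100, 0, 25 * (1 - exp(-(tt - 100) / 10)))
  tr <- new_trace("current", settle, 0.05, p, -62)
  expect_equal(steady_state_current(tr), 25, tolerance = 0.1)

  expect_error(steady_state_current(const, window_ms = 600), "exceeds")
})

test_that("reversal potential interpolates the zero crossing", {
  cv <- function(v, i) data.frame(v = v, i = i)
  expect_equal(reversal_potential(cv(c(-60, -50), c(-20, 20))), -55)
  expect_equal(reversal_potential(cv(c(-70, -60, -50), c(-10, 0, 30))), -60)
  expect_true(is.na(reversal_potential(cv(c(-70, -60), c(5, 10)))))

  # pure ohmic cell sampled at the 7 protocol voltages: exact recovery
  g <- 3.2; e <- -63.7
  vs <- seq(-77, -47, by = 5)
  expect_equal(reversal_potential(cv(vs, g * (vs - e))), e,
               tolerance = 1e-10)
})

test_that("segment slopes match the closed-form OLS oracle", {
  cv <- function(v, i) data.frame(v = v, i = i)
  vs <- seq(-77, -62, by = 5)
  expect_equal(segment_slope(cv(vs, 2 * vs + 7), c(-77, -62)), 2,
               tolerance = 1e-10)
  # invariant to shifting the voltage axis origin of the currents
  expect_equal(segment_slope(cv(vs, 2 * (vs + 30) + 7), c(-77, -62)), 2,
               tolerance = 1e-10)
  set.seed(11)
  x <- seq(-62, -47, by = 5)
  y <- rnorm(4, 0, 10)
  oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(segment_slope(cv(x, y), c(-62, -47)), oracle,
               tolerance = 1e-10)
  expect_error(segment_slope(cv(-77, 1), c(-77, -62)), ">= 2")
})

test_that("BH adjustment reproduces the hand-computed example", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.80)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.80), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  p <- c(0.001, 0.2, 0.03)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

# synthetic multi-cell I-V data: per-cell random intercept + residual noise
make_iv_data <- function(n_cells, conditions, shift = 0, cell_sd = 3,
                         noise_sd = 2, seed = 1) {
  set.seed(seed)
  vs <- seq(-77, -47, by = 5)
  rows <- list()
  for (cond in names(conditions)) {
    for (c_i in seq_len(n_cells)) {
      id <- paste0(cond, "_", c_i)
      b <- rnorm(1, 0, cell_sd)
      i <- 3 * (vs + 65) + b + conditions[[cond]] +
        rnorm(length(vs), 0, noise_sd)
      rows[[id]] <- data.frame(v = vs, i = i, cell_id = id,
                               condition = cond)
    }
  }
  do.call(rbind, rows)
}

test_that("bin_and_compare finds a uniform shift and spares the null", {
  # canonical 7-step protocol yields 6 bins
  dat <- make_iv_data(10, list(aCSF = 0, sevo = -20), seed = 21)
  res <- bin_and_compare(dat, reference = "aCSF")
  expect_identical(sort(unique(res$bin)), 1:6)
  expect_true(all(res$p_fdr < 0.05))
  expect_true(all(res$estimate < 0))

  null <- bin_and_compare(make_iv_data(10, list(a = 0, b = 0), seed = 22),
                          reference = "a")
  expect_true(all(null$p_fdr > 0.05))
  expect_lt(max(abs(null$z)), 3)
})

test_that("trace subtraction is exact and reversible", {
  p <- stimulus_protocol("voltage_step", 10, 50, 10, -62, dt = 0.1)
  n <- round(70 / 0.1) + 1
  a <- new_trace("current", rep(30, n), 0.1, p, -62)
  b <- new_trace("current", rep(25, n), 0.1, p, -62)
  expect_true(all(subtract_traces(a, a)$samples == 0))
  expect_true(all(subtract_traces(a, b)$samples == 5))
  back <- subtract_traces(a, b)$samples + b$samples
  expect_identical(back, a$samples)
  bad <- new_trace("current", rep(1, 10), 0.1)
  expect_error(subtract_traces(a, bad), "length")
})

test_that("Henderson junction potential behaves like the closed forms", {
  # identical solutions: no junction
  s <- solution_composition(K = 150, Cl = 150)
  expect_equal(liquid_junction_potential(s, s), 0)

  # binary KCl dilution: near zero because u_K is close to u_Cl
  s2 <- solution_composition(K = 15, Cl = 15)
  expect_lt(abs(liquid_junction_potential(s, s2)), 1.5)

  # antisymmetric under swapping the two sides
  internal <- pipette_internal_solution()
  external <- standard_acsf_solution()
  expect_equal(liquid_junction_potential(internal, external),
               -liquid_junction_potential(external, internal),
               tolerance = 1e-10)

  expect_error(
    liquid_junction_potential(solution_composition(Xenon = 5), external),
    "Xenon")
})

test_that("ANOVA sample size search matches the noncentral-F power curve", {
  r <- anova_min_sample_size(6, 0.8, alpha = 0.05, target_power = 0.80)
  expect_equal(r$n, 5)
  expect_equal(r$N, 30)
  expect_gte(r$power, 0.80)
  expect_lt(anova_power(6, 4, 0.8), 0.80)

  # a larger effect never needs more samples
  small_f <- anova_min_sample_size(6, 0.5)$n
  big_f <- anova_min_sample_size(6, 1.0)$n
  expect_lte(big_f, small_f)
  expect_error(anova_min_sample_size(6, 1e-4, n_max = 50), "attainable")
})

test_that("conductance comparison normalizes to the reference median", {
  set.seed(31)
  fits <- rbind(
    data.frame(condition = "aCSF", parameter = "KP",
               value = rlnorm(20, log(0.35), 0.2)),
    data.frame(condition = "sevo", parameter = "KP",
               value = rlnorm(20, log(0.35 * 1.5), 0.2)))
  res <- compare_conductances(fits, reference = "aCSF")
  ref_norm <- res$normalized$norm_value[res$normalized$condition == "aCSF"]
  expect_equal(median(ref_norm), 1, tolerance = 1e-10)
  expect_lt(res$tests$p[1], 0.05)
})
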