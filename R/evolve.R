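#' Parameter bounds for model fitting
#'
#' The tunable parameters (see [tunable_params()]) with per-parameter
#' `[lo, hi]` search bounds. Conductance densities are searched in log
#' space (they span orders of magnitude); the calcium parameters `gamma`
#' and `tau_decay` in linear space. The leak conductance is fixed and never
#' appears here.
#'
#' @param template a [soma_model()] whose parameter values centre the
#'   default bounds.
#' @param lo_frac,hi_frac multiplicative bounds around the template values
#'   (defaults 1/3 and 3), the package's physiologically-plausible search
#'   range.
#' @return a `data.frame` with columns `name`, `lo`, `hi`, `log`.
#' @export
param_bounds <- function(template = default_soma_model(), lo_frac = 1 / 3,
                         hi_frac = 3) {
  stopifnot(lo_frac > 0, hi_frac > lo_frac)
  base <- get_params(template)
  data.frame(name = names(base), lo = base * lo_frac,
             hi = pmin(base * hi_frac, ifelse(names(base) == "gamma", 1, Inf)),
             log = !(names(base) %in% c("gamma", "tau_decay")),
             row.names = NULL, stringsAsFactors = FALSE)
}

check_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("name", "lo", "hi", "log") %in% names(bounds)))
  if (any(bounds$lo >= bounds$hi)) stop("bounds need lo < hi")
  if (any(bounds$log & bounds$lo <= 0)) stop("log-scale bounds need lo > 0")
  if ("leak" %in% bounds$name) stop("leak conductance is not tunable")
  invisible(bounds)
}

# forward/backward transform between parameter space and search space
to_search <- function(theta, bounds) ifelse(bounds$log, log(theta), theta)
from_search <- function(u, bounds) ifelse(bounds$log, exp(u), u)

search_box <- function(bounds, expand = 0) {
  lo <- to_search(bounds$lo, bounds)
  hi <- to_search(bounds$hi, bounds)
  span <- hi - lo
  cbind(lo = lo - expand * span, hi = hi + expand * span)
}

#' Evolutionary-strategy configuration
#'
#' @param pop_size population size (default 800, the full-scale setting;
#'   reduce for desk-scale runs).
#' @param max_gen maximum number of generations (default 35).
#' @param tournament_frac adaptive tournament size range as fractions of
#'   the population, default `c(0.04, 0.10)`; the fraction grows linearly
#'   across generations (selection pressure increases as the search
#'   narrows).
#' @param blx_alpha BLX-alpha blending parameter (default 0.5).
#' @param elite_frac fraction of the population preserved unchanged each
#'   generation (default 0.10).
#' @param bound_expand fractional widening of the search-space bounds
#'   applied to crossover/mutation output (default 0.10 of the span on each
#'   side), the "expanded bounds" promoting diversity.
#' @param diversity_threshold relative fitness spread
#'   (`sd(fitness)/best_fitness`) below which fresh Latin-hypercube
#'   individuals are injected into the tournament pools (default 0.01).
#' @param early_stop_tol,early_stop_gens stop when the relative improvement
#'   of the best fitness stays below `early_stop_tol` (default 0.001) for
#'   `early_stop_gens` (default 5) consecutive generations.
#' @param sigma0 initial mutation scale as a fraction of each parameter's
#'   search-space span (default 0.1); the scale cools as `sigma0/generation`.
#' @param mutation_rate,crossover_rate per-generation probability ranges
#'   `c(max_at_gen1, min_at_max_gen)`; defaults `c(0.4, 0.1)` and
#'   `c(0.9, 0.6)`.
#' @param seed integer RNG seed making the run reproducible.
#' @return an object of class `ea_config`.
#' @export
ea_config <- function(pop_size = 800, max_gen = 35,
                      tournament_frac = c(0.04, 0.10), blx_alpha = 0.5,
                      elite_frac = 0.10, bound_expand = 0.10,
                      diversity_threshold = 0.01, early_stop_tol = 0.001,
                      early_stop_gens = 5, sigma0 = 0.1,
                      mutation_rate = c(0.4, 0.1),
                      crossover_rate = c(0.9, 0.6), seed = 1L) {
  stopifnot(pop_size >= 2, max_gen >= 1, elite_frac > 0, elite_frac < 1,
            all(tournament_frac > 0), all(tournament_frac < 1),
            blx_alpha >= 0, sigma0 >= 0)
  structure(list(pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
                 tournament_frac = tournament_frac, blx_alpha = blx_alpha,
                 elite_frac = elite_frac, bound_expand = bound_expand,
                 diversity_threshold = diversity_threshold,
                 early_stop_tol = early_stop_tol,
                 early_stop_gens = as.integer(early_stop_gens),
                 sigma0 = sigma0, mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate, seed = as.integer(seed)),
            class = "ea_config")
}

#' Latin hypercube population initialization
#'
#' Stratified sampling: for each parameter, the `n` samples occupy `n`
#' distinct equal-width strata of the search interval (log-spaced strata
#' for log-scale parameters). Reproducible under a fixed seed.
#'
#' @param bounds a [param_bounds()] table.
#' @param n number of individuals, >= 1.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return an `n x d` matrix of parameter values, columns named by
#'   `bounds$name`.
#' @export
lhs_init <- function(bounds, n, seed = NULL) {
  check_bounds(bounds)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(bounds)
  u01 <- lhs::randomLHS(n, d)
  box <- search_box(bounds, expand = 0)
  theta <- sapply(seq_len(d), function(j)
    box[j, "lo"] + u01[, j] * (box[j, "hi"] - box[j, "lo"]))
  theta <- matrix(theta, nrow = n)
  for (j in seq_len(d)) if (bounds$log[j]) theta[, j] <- exp(theta[, j])
  colnames(theta) <- bounds$name
  theta
}

#' Tournament selection
#'
#' Returns the index of the fittest (lowest-fitness) member of a uniformly
#' drawn subset of `round(frac * n)` individuals (minimum 2).
#'
#' @param fitness numeric vector of evaluated fitness values (no NA).
#' @param frac tournament size as a fraction of the population; the
#'   adaptive schedule keeps it within the 4-10 percent range, but any
#'   fraction up to 1 (whole-population tournament, i.e. deterministic
#'   best) is accepted.
#' @param pool optional candidate index pool (defaults to everyone);
#'   fresh diversity-injection individuals enter here.
#' @return the winning index.
#' @export
tournament_select <- function(fitness, frac, pool = seq_along(fitness)) {
  if (anyNA(fitness)) stop("population must be fully evaluated")
  stopifnot(frac > 0, frac <= 1)
  k <- max(2L, round(frac * length(fitness)))
  cand <- pool[sample.int(length(pool), min(k, length(pool)))]
  cand[which.min(fitness[cand])]
}

#' BLX-alpha blend crossover
#'
#' Each offspring coordinate is drawn uniformly from the parental interval
#' expanded by `alpha` times its width, `[min - alpha*d, max + alpha*d]`,
#' then clipped to the expanded search bounds. Operates in search space
#' (log space for conductances).
#'
#' @param p1,p2 parent parameter vectors (named, in-bounds).
#' @param bounds a [param_bounds()] table.
#' @param alpha blending parameter (default 0.5).
#' @param bound_expand fractional bound widening (default 0.10).
#' @return offspring parameter vector.
#' @export
blx_crossover <- function(p1, p2, bounds, alpha = 0.5, bound_expand = 0.10) {
  u1 <- to_search(unname(p1), bounds)
  u2 <- to_search(unname(p2), bounds)
  lo <- pmin(u1, u2) - alpha * abs(u1 - u2)
  hi <- pmax(u1, u2) + alpha * abs(u1 - u2)
  u <- runif(length(u1), lo, hi)
  box <- search_box(bounds, expand = bound_expand)
  u <- pmin(pmax(u, box[, "lo"]), box[, "hi"])
  setNames(from_search(u, bounds), bounds$name)
}

#' Cooled Gaussian mutation
#'
#' Each coordinate is independently perturbed with probability `rate` by a
#' Gaussian of standard deviation `sigma0/gen` times the parameter's
#' search-space span (the cooling schedule: scale proportional to
#' 1/generation), then clipped to the expanded bounds.
#'
#' @param theta parameter vector.
#' @param gen current generation, >= 1.
#' @param rate per-coordinate mutation probability.
#' @param bounds a [param_bounds()] table.
#' @param sigma0 initial scale fraction (default 0.1).
#' @param bound_expand fractional bound widening (default 0.10).
#' @return mutated parameter vector.
#' @export
gaussian_mutate <- function(theta, gen, rate, bounds, sigma0 = 0.1,
                            bound_expand = 0.10) {
  stopifnot(gen >= 1)
  u <- to_search(unname(theta), bounds)
  box0 <- search_box(bounds, expand = 0)
  span <- box0[, "hi"] - box0[, "lo"]
  hit <- runif(length(u)) < rate
  u[hit] <- u[hit] + rnorm(sum(hit), 0, sigma0 * span[hit] / gen)
  box <- search_box(bounds, expand = bound_expand)
  u <- pmin(pmax(u, box[, "lo"]), box[, "hi"])
  setNames(from_search(u, bounds), bounds$name)
}

#' Per-generation mutation and crossover rates
#'
#' Both rates decrease linearly from their configured maximum at
#' generation 1 to their minimum at `max_gen`: exploration early,
#' exploitation late.
#'
#' @param gen generation, in `[1, max_gen]`.
#' @param config an [ea_config()].
#' @return named vector with `mutation` and `crossover` rates.
#' @export
schedule_rates <- function(gen, config) {
  stopifnot(gen >= 1, gen <= config$max_gen)
  f <- if (config$max_gen == 1) 0 else (gen - 1) / (config$max_gen - 1)
  c(mutation = config$mutation_rate[1] +
      f * (config$mutation_rate[2] - config$mutation_rate[1]),
    crossover = config$crossover_rate[1] +
      f * (config$crossover_rate[2] - config$crossover_rate[1]))
}

tournament_frac_at <- function(gen, config) {
  f <- if (config$max_gen == 1) 0 else (gen - 1) / (config$max_gen - 1)
  config$tournament_frac[1] +
    f * (config$tournament_frac[2] - config$tournament_frac[1])
}

WORST_FITNESS <- 1e9

#' Run the adaptive elitist evolutionary strategy
#'
#' Minimizes `objective(theta)` over the bounded parameter space. Each
#' generation: evaluate, preserve the elite fraction unchanged, fill the
#' rest by tournament selection plus BLX-alpha crossover and cooled
#' Gaussian mutation. When the population fitness spread
#' (`sd(fitness)/best`) falls below the diversity threshold, fresh
#' Latin-hypercube individuals are evaluated and injected into the
#' tournament candidate pools. Terminates at `max_gen` or when the relative
#' best-fitness improvement stays below `early_stop_tol` for
#' `early_stop_gens` consecutive generations. Objective failures (errors or
#' non-finite values) score a worst-possible fitness and are counted, never
#' fatal.
#'
#' @param objective function of a named parameter vector returning a
#'   non-negative scalar fitness (lower is better).
#' @param bounds a [param_bounds()] table.
#' @param config an [ea_config()].
#' @return list with `best` (list `theta`, `fitness`), `history` (one row
#'   per generation: best / mean fitness, diversity, failures,
#'   injections), `population` and `fitness` at the final generation.
#' @export
run_ea <- function(objective, bounds, config = ea_config()) {
  check_bounds(bounds)
  set.seed(config$seed)
  n <- config$pop_size
  n_elite <- max(1L, round(config$elite_frac * n))

  evaluate <- function(theta_mat) {
    vapply(seq_len(nrow(theta_mat)), function(i) {
      f <- tryCatch(objective(theta_mat[i, ]), error = function(e) WORST_FITNESS)
      if (!is.finite(f)) WORST_FITNESS else f
    }, numeric(1))
  }

  pop <- lhs_init(bounds, n)
  fit <- evaluate(pop)
  n_fail <- sum(fit >= WORST_FITNESS)

  hist_rows <- list()
  best_prev <- Inf
  stall <- 0L

  for (gen in seq_len(config$max_gen)) {
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]
    fit <- fit[ord]
    best <- fit[1]
    diversity <- if (best > 0) sd(fit[fit < WORST_FITNESS]) / best else 0
    if (!is.finite(diversity)) diversity <- 0

    injected <- 0L
    pool_pop <- pop
    pool_fit <- fit
    if (diversity < config$diversity_threshold) {
      fresh <- lhs_init(bounds, max(2L, ceiling(0.1 * n)))
      ffit <- evaluate(fresh)
      n_fail <- n_fail + sum(ffit >= WORST_FITNESS)
      pool_pop <- rbind(pop, fresh)
      pool_fit <- c(fit, ffit)
      injected <- nrow(fresh)
    }

    improvement <- if (is.finite(best_prev) && best_prev > 0)
      (best_prev - best) / best_prev else Inf
    stall <- if (improvement < config$early_stop_tol) stall + 1L else 0L

    hist_rows[[gen]] <- data.frame(gen = gen, best = best,
                                   mean = mean(fit[fit < WORST_FITNESS]),
                                   diversity = diversity,
                                   failures = n_fail, injections = injected)
    best_prev <- best
    if (stall >= config$early_stop_gens || gen == config$max_gen) break

    rates <- schedule_rates(gen, config)
    tfrac <- tournament_frac_at(gen, config)
    pool_idx <- seq_len(nrow(pool_pop))

    children <- matrix(NA_real_, n - n_elite, ncol(pop),
                       dimnames = list(NULL, colnames(pop)))
    for (i in seq_len(n - n_elite)) {
      i1 <- tournament_select(pool_fit, tfrac, pool_idx)
      child <- if (runif(1) < rates["crossover"]) {
        i2 <- tournament_select(pool_fit, tfrac, pool_idx)
        blx_crossover(pool_pop[i1, ], pool_pop[i2, ], bounds,
                      alpha = config$blx_alpha,
                      bound_expand = config$bound_expand)
      } else pool_pop[i1, ]
      children[i, ] <- gaussian_mutate(child, gen, rates["mutation"], bounds,
                                       sigma0 = config$sigma0,
                                       bound_expand = config$bound_expand)
    }
    cfit <- evaluate(children)
    n_fail <- n_fail + sum(cfit >= WORST_FITNESS)
    pop <- rbind(pop[seq_len(n_elite), , drop = FALSE], children)
    fit <- c(fit[seq_len(n_elite)], cfit)   # elites keep cached fitness
  }

  ord <- order(fit)
  list(best = list(theta = pop[ord[1], ], fitness = fit[ord[1]]),
       history = do.call(rbind, hist_rows),
       population = pop[ord, , drop = FALSE], fitness = fit[ord])
}

#' Fit somatic model parameters to reference voltage traces
#'
#' Builds the objective -- simulate the template model under the reference
#' protocols with candidate parameters, score with [total_fitness()] -- and
#' runs [run_ea()].
#'
#' @param ref_traces list of reference voltage [new_trace()]s, each carrying
#'   its generating protocol and amplitude.
#' @param template a [soma_model()] providing all non-tunable structure.
#' @param bounds a [param_bounds()] table (default centred on the template).
#' @param config an [ea_config()].
#' @param weights a [fitness_weights()].
#' @return as [run_ea()], with `best$model` set to the fitted [soma_model()].
#' @export
fit_cell <- function(ref_traces, template, bounds = param_bounds(template),
                     config = ea_config(), weights = fitness_weights()) {
  if (inherits(ref_traces, "trace")) ref_traces <- list(ref_traces)
  # precompute per-reference stimulus vectors and spike trains; the
  # objective flattens each candidate model once and reuses it across
  # protocols (current-clamp and voltage-clamp references both supported)
  ref_trains <- lapply(ref_traces, function(tr)
    if (tr$kind == "voltage") detect_spikes(tr) else NULL)
  holding <- template$holding
  stims <- lapply(ref_traces, function(tr) {
    p <- tr$protocol
    n <- round(protocol_total_ms(p) / p$dt) + 1
    drv <- drive_vector(p, tr$amplitude, n)
    vc <- p$mode == "voltage_step"
    if (vc) drv[is.na(drv)] <- holding
    list(drive = drv, dt = p$dt, vc = vc)
  })
  objective <- function(theta) {
    fm <- flatten_model(set_params(template, theta))
    ih <- .sim_membrane_current(fm, holding)
    sims <- lapply(seq_along(stims), function(i) {
      s <- stims[[i]]
      res <- if (s$vc) .sim_run(fm, s$drive, s$dt, 1L, holding)
             else .sim_run(fm, ih + s$drive, s$dt, 0L, holding)
      if (res$failed_at > 0) stop("integration failure")
      new_trace(if (s$vc) "current" else "voltage", res$samples, s$dt,
                ref_traces[[i]]$protocol, ref_traces[[i]]$amplitude)
    })
    total_fitness(sims, ref_traces, weights, ref_trains = ref_trains)$total
  }
  res <- run_ea(objective, bounds, config)
  res$best$model <- set_params(template, res$best$theta)
  res
}
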