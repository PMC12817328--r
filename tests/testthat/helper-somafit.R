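# shared fixtures and independent oracles

# single-compartment passive membrane: leak only, given total conductance
# (nS), capacitance (pF) and reversal; all active conductances zero
passive_model <- function(g_nS = 5, c_pF = 100, e_leak = -70,
                          holding = e_leak) {
  area_um2 <- 10000                      # 1e-4 cm2
  m <- default_soma_model(c(NaT = 0, NaP = 0, KT = 0, KP = 0, SKv3_1 = 0,
                            SK = 0, Ca_HVA = 0, Ca_LVA = 0))
  m$area <- area_um2
  m$cm <- c_pF / (area_um2 * 1e-8) * 1e-6          # pF -> uF/cm2
  m$channels$leak$gbar <- g_nS * 1e-9 / (area_um2 * 1e-8)
  m$channels$leak$erev <- e_leak
  m$holding <- holding
  m
}

# independent spike-count oracle: local voltage maxima above 0 mV,
# separated by at least 1 ms
oracle_spike_count <- function(trace, min_sep_ms = 1) {
  v <- trace$samples
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[v[pk] > 0]
  if (length(pk) < 2) return(length(pk))
  keep <- c(TRUE, diff(pk) * trace$dt >= min_sep_ms)
  sum(keep)
}

# brute-force 1-D Wasserstein for equal-size samples: mean absolute
# difference of the sorted values (optimal transport pairs order statistics)
oracle_w1_equal <- function(x, y) {
  stopifnot(length(x) == length(y))
  mean(abs(sort(x) - sort(y)))
}

# default model, cached across tests (deterministic)
default_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_soma_model()
    m
  }
})
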