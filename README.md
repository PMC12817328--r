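# somafit

Conductance-based somatic modelling, patch-clamp feature extraction and
evolutionary model fitting for layer-5 pyramidal neurons.

Volatile anesthetics such as sevoflurane suppress the firing of neocortical
layer-5 pyramidal neurons, plausibly by potentiating low-threshold Kv1.2
potassium channels — represented in somatic conductance-based models by the
persistent potassium conductance (KP). `somafit` packages the complete
computational workflow needed to test that hypothesis in silico, end to
end:

* **Point-soma Hodgkin–Huxley model** of a thick-tufted L5b pyramidal
  neuron — transient/persistent Na (NaT, NaP), transient/persistent K
  (KT, KP), delayed rectifier (SKv3.1), calcium-activated K (SK), high- and
  low-voltage-activated Ca channels, fixed leak, and a calcium pool
  (free fraction γ = 0.05). The KP activation curve carries a built-in
  −3 mV leftward shift in every condition, the steady-state signature of
  anesthetic action on Kv1.2. Current clamp integrates
  C dV/dt = −Σ ḡᵢ mᵢ^p hᵢ (V − Eᵢ) + I/A with a stable staggered
  exponential scheme; voltage clamp is ideal and reports outward-positive
  current.
* **Current-clamp feature set**: resting potential, input resistance (−5 mV
  step, Ohm's law), spike detection at dV/dt ≥ 20 mV/ms, ramp rheobase,
  AP amplitude and half-width, sag, steady-state hyperpolarization, ADP,
  AHP, firing frequency — and the layer-5 subtype rule
  (type A ⇔ sag + ADP + AHP > 6.5 mV).
* **Evolutionary model fitting**: Latin-hypercube initialization,
  tournament selection with adaptive 4–10 % tournaments, BLX-α crossover
  (α = 0.5) on 10 %-expanded bounds, Gaussian mutation cooled as σ ∝ 1/gen,
  10 % elitism, diversity injection, and early stop after five generations
  of < 0.1 % improvement. Fitness = spike-weighted RMS trace error (10×
  weight near reference spikes) + spike presence/count penalties +
  normalized first/last-spike timing error + the 1-D Wasserstein distance
  between inter-spike-interval distributions.
* **Subthreshold I–V statistics**: steady-state currents, reversal
  potentials, OLS segment slopes (−77/−62, −62/−47 mV), per-5-mV-bin
  mixed-effects condition comparisons (cell as random intercept) with
  Benjamini–Hochberg FDR, digital trace subtraction, Henderson
  liquid-junction potentials, and noncentral-F ANOVA sample-size
  computation.
* **Synthetic cohorts with ground truth** emulating the aCSF /
  sevoflurane / sevoflurane + TsTX-Kα conditions (KP×1.5 + SK×1.3 and
  KP×1.1 + SK×1.3 multipliers, lognormal 20 % cell-to-cell variability,
  0.3 mV recording noise), so every stage is testable by parameter
  recovery.

## Worked example

```r
library(somafit)

model <- default_soma_model()
steps <- simulate_cc(model, protocol_steps(c(-100, 250)))
ramp  <- simulate_cc(model, protocol_ramp(300))
extract_features(steps, ramp, rin = measure_rin(model))
#>   vm_rest    r_in ap_threshold rheobase ap_amplitude ap_half_width ...
#> 1     -67 200.075     -42.9607  60.7925      68.6122      0.359856 ...
#>   sag hyperpolarization    adp     ahp freq_250 subtype
#>   ~0            23.592  0.297 13.8374       23       A
```

The default cell rests at the −67 mV holding potential, has ~200 MΩ input
resistance, fires 23 spikes during a 1 s +250 pA step, and classifies as
type A (AHP-dominated sum 14.1 mV > 6.5 mV).

```r
# Henderson junction potential of the study's solutions
liquid_junction_potential(pipette_internal_solution(),
                          standard_acsf_solution())
#> [1] -14.21512

# ANOVA sample size: 6 groups, f = 0.8, alpha = 0.05, power = 0.80
anova_min_sample_size(6, 0.8)
#> $n [1] 5   $N [1] 30   $power [1] 0.8741261

# self-recovery of the persistent-K conductance
ref <- simulate_cc(model, stimulus_protocol("current_step",
                                            200, 1000, 300, 250))
fit <- fit_cell(ref, model,
                config = ea_config(pop_size = 100, max_gen = 15, seed = 1))
fit$best$theta[["KP"]] / get_params(model)[["KP"]]
```

A shell entry point wrapping the same functions ships in `inst/cli/somafit`
(subcommands `simulate`, `extract-features`, `classify`, `make-cohort`,
`iv`, `jp`, `power`).

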