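---
title: "Conductance-based somatic modelling and evolutionary fitting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-based somatic modelling and evolutionary fitting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somafit)
```

## The problem

Volatile anesthetics such as sevoflurane silence neocortical layer-5
pyramidal neurons, and a leading mechanistic hypothesis is potentiation of
low-threshold voltage-gated potassium channels (Kv1.2), which in somatic
conductance-based models is proxied by the persistent potassium
conductance (KP). `somafit` provides the complete computational tool chain
needed to study that hypothesis *in silico*:

1. a single-compartment (point-soma) conductance-based model of a
   thick-tufted L5b pyramidal neuron with the canonical somatic channel
   set (NaT, NaP, KT, KP, SKv3.1, SK, Ca_HVA, Ca_LVA, leak) and a calcium
   pool;
2. extraction of the standard current-clamp feature set and the type A /
   type B layer-5 subtype classification;
3. a real-valued, adaptive, elitist evolutionary strategy that fits the
   somatic conductance densities to reference voltage traces under a
   multi-component fitness;
4. subthreshold current-voltage statistics (segment regressions, voltage-bin
   mixed-effects comparisons with FDR control, reversal potentials,
   Henderson liquid-junction potentials, ANOVA power);
5. a synthetic-cohort generator that emulates three experimental
   conditions - control aCSF, sevoflurane (KP x 1.5, SK x 1.3) and
   sevoflurane plus the Kv1.2 pore blocker tityustoxin-K&alpha;
   (KP x 1.1, SK x 1.3) - with known ground truth, so that every stage of
   the pipeline can be validated by parameter recovery.

## The somatic model

The membrane equation is
$$C_m \frac{dV}{dt} = -\sum_i \bar g_i \, m_i^{p_i} h_i \,(V - E_i) + I_{inj}/A,$$
with Boltzmann steady-state gating
$x_\infty(V) = 1/(1+\exp((V_{1/2} + \Delta V - V)/k))$ and per-gate time
constants drawn from constant, bell-shaped, or sigmoid families. SK carries
a Hill gate of intracellular calcium instead of voltage gates
(half-activation 0.43 uM, exponent 4.8). The calcium pool follows
$$\frac{d[\mathrm{Ca}]}{dt} = -\frac{\gamma \, I_{Ca}}{2 F d}
 - \frac{[\mathrm{Ca}] - [\mathrm{Ca}]_{rest}}{\tau_{decay}},$$
with free-calcium fraction $\gamma = 0.05$, decay constant
$\tau_{decay} = 80$ ms, shell depth $d = 1$ um and resting level 0.1 uM.
Calcium-channel reversal potentials follow the instantaneous Nernst
potential; sodium and potassium reversals are fixed (+50 / -85 mV). The
leak conductance is fixed (not tunable): every other channel density plus
$\gamma$ and $\tau_{decay}$ are free parameters of the fitting problem.

The persistent-potassium activation curve carries a built-in **-3 mV
leftward shift** in all conditions, reflecting the steady-state effect of
anesthetic binding on Kv1.2 gating; condition effects on top of that are
pure conductance multipliers.

The exact kinetic constants shipped in `default_soma_model()` are this
package's own documented defaults, written in the spirit of the published
thick-tufted L5b somatic mechanisms but tuned as a self-consistent point
soma: with the -14 mV junction-potential-corrected holding at -67 mV the
default cell rests quietly (holding bias of a few pA), has an input
resistance near 200 MOhm, a ramp rheobase near 100 pA, and fires roughly
13 / 18 / 22 / 25 spikes at 150 / 250 / 350 / 450 pA - the firing range
reported for type A cells. All validation in this package is by
*self-consistent recovery* (fit the simulator's own output), so the
absolute constants matter less than their identifiability.

### Numerics

Integration uses fixed-step staggered integration in the NEURON style:
gates advance a full step by exponential (exact-relaxation) updates with
rates evaluated at the current voltage, so gate states effectively live on
the half-step grid, and the voltage then advances by the exact exponential
solution of the frozen-conductance membrane equation. The scheme is
unconditionally stable, which matters because the evolutionary search
visits extreme conductance combinations; any candidate whose voltage still
escapes +-200 mV is scored with the worst possible fitness rather than
crashing the run.

The default step is `dt = 0.025` ms. Halving `dt` never changes spike
counts on the default model, and late-spike *timing* converges at second
order: at the default step, accumulated spike-time drift over a one-second
tonic train is of order 2 ms (a fraction of an inter-spike interval), and
falls below 0.5 ms for `dt` at or under 0.00625 ms. The tests assert spike
count invariance at the default step and sub-0.5 ms timing convergence at
the fine step; fitting runs use coarser steps (0.05-0.1 ms, stated with
each experiment) because the fitness compares reference and candidate
traces computed with the *same* integrator.

Ideal voltage clamp imposes the command potential exactly (no series
resistance or capacitance-transient modelling; the experiments compensated
access resistance but the model needs none), and reports total ionic
current, outward positive. The "steady state" of a step is the mean over
its final 50 ms, ending one sample before the step offset.

## Feature extraction

All definitions act on annotated traces and propagate undefined features
as `NA`, never zero:

* **resting potential**: mean over the first 100 ms (pre-stimulus);
* **input resistance**: Ohm's law on the steady-state current response to a
  -5 mV clamp step;
* **spikes**: contiguous runs of dV/dt >= 20 mV/ms (central differences)
  whose ensuing voltage peak exceeds -20 mV - the peak criterion guards
  against noise-triggered slope events; the threshold voltage is the
  voltage at the run's first sample;
* **rheobase**: injected current at the first threshold crossing of a
  ramp, by the linear time-to-current map;
* **amplitude / half-width**: threshold-to-peak, and the time between the
  two sub-sample-interpolated crossings of threshold + amplitude/2;
* **sag / hyperpolarization** (-100 pA step): |minimum - steady state| and
  |rest - steady state|, steady state = mean of the step's last 50 ms;
* **ADP / AHP**: |extremum in the 200 ms after step offset - rest| for the
  -100 / +250 pA steps; rebound spikes inside the ADP window are excised
  threshold-to-threshold before taking the maximum;
* **firing frequency**: spike count inside the 1 s stimulus window (count
  and Hz coincide by construction; other durations are rejected);
* **subtype**: type A if sag + ADP + AHP > 6.5 mV (strictly), else type B.
  All three magnitudes are reported non-negative.

## The fitness function

A candidate trace is scored against a reference by
$$F = w_t \cdot \mathrm{RMS}_w + w_s \cdot (b\,[\mathrm{presence\ differs}] +
c\,|\Delta \mathrm{count}|) + w_m \cdot \frac{|\Delta t_{first}| +
|\Delta t_{last}|}{T} + w_i \cdot W_1(\mathrm{ISI}_{sim},
\mathrm{ISI}_{ref}),$$
with shipped weights $w_t = w_s = w_m = 1$, $w_i = 0.1$ per ms, $b = 5$,
$c = 1$. The trace term is a weighted RMS with 10x per-sample weight
within +-5 ms of each reference spike peak, normalized by the summed
weights so that the spike emphasis re-balances rather than inflates the
scale (identical traces score 0; a uniform 1 mV offset scores exactly 1).
$W_1$ is the order-1 Wasserstein distance between the empirical
inter-spike-interval distributions, computed by integrating the absolute
CDF difference (equal-size samples reduce to the mean absolute difference
of sorted values); two empty ISI sets score 0, and exactly one empty set
scores a large fixed constant (1000 ms) to keep the optimization finite.
Multi-trace references are scored by the mean of per-trace totals.

Reference sets may also include subthreshold voltage-clamp steps: a
current trace contributes a plain (unweighted) RMS through the trace
component, scaled at 0.1 fitness units per pA so that 10 pA of clamp
current weighs like 1 mV of voltage, and the spike-based components do
not apply. This matters for identifiability: the outward clamp current at
the top of the subthreshold range (about -52 to -47 mV) is carried almost
entirely by the persistent potassium conductance, so including the
voltage-step protocol in the reference set anchors KP directly, where
current-clamp spike trains alone leave it free to trade against the other
potassium conductances.

## The evolutionary strategy

Populations (default 800 at full scale; experiments in this package run
desk-scale populations stated per experiment) are initialized by Latin
hypercube sampling over the search box; conductance densities are searched
in log space (they span orders of magnitude, and stratification then
happens per decade), the calcium parameters linearly. Each generation:

1. the top 10% (elites) survive unchanged with cached fitness;
2. the remainder is produced by tournament selection (adaptive tournament
   size growing from 4% to 10% of the population across generations),
   BLX-&alpha; blend crossover ($\alpha = 0.5$) applied with a probability
   that anneals from 0.9 to 0.6, and cooled Gaussian mutation
   ($\sigma(g) = \sigma_0/g$ of each parameter's span, $\sigma_0 = 0.1$,
   per-coordinate rate annealing 0.4 to 0.1);
3. offspring are clipped to bounds expanded by 10% of the span on each
   side ("expanded bounds" promoting diversity at the edges);
4. when the population fitness spread, `sd(fitness)/best`, falls below 1%,
   fresh Latin-hypercube individuals are evaluated and injected into the
   tournament candidate pools (they compete for parenthood without
   displacing the population);
5. the run stops at 35 generations or when the relative best-fitness
   improvement stays under 0.1% for 5 consecutive generations.

Design points that the method leaves open and this package fixes: the
diversity metric is the relative fitness spread (a parameter-space spread
is selectable); "expanded bounds" widen each side by 10% of the span;
elites are cached, not re-evaluated (references are fixed, not noisy
resamples); the search bounds default to 1/3x-3x of the template values,
a generous physiological range around the baseline; improvement for early
stopping is measured against the previous generation's best.

## Synthetic cohorts and what recovery does (and does not) show

`generate_cohort()` draws per-cell conductance multipliers from a
unit-mean lognormal with CV 0.2 (calcium parameters: truncated normal),
applies the condition effect, renders the study protocols (1 s current
steps -100 to 450 pA; 500 ms ramps from -50 pA; 500 ms voltage steps -77
to -47 mV in 5 mV increments) and adds 0.3 mV white recording noise. Group
sizes default to the study's type-A cohort (21 / 9 / 8). The condition
multipliers (KP x 1.5 and SK x 1.3 for sevoflurane; KP x 1.1 and SK x 1.3
for the toxin co-application) are *synthetic effect sizes chosen so the
recovery experiment has statistical power at these group sizes*; the
underlying study reports only direction and significance of the
conductance shifts, not calibrated magnitudes.

The generator emulates lognormal cell-to-cell variability and white
measurement noise only: no electrode drift, seal loss, line hum, washout
dynamics, or dendritic filtering. Passing recovery tests therefore
demonstrates that the pipeline is *internally consistent and statistically
powered under its stated noise model* - not that the biological effect
sizes are as simulated.

A practical caveat established during development: the fitness landscape
over the 10-dimensional parameter space is rugged (a +-33% change of any
single conductance from a perfect fit raises the fitness by roughly 20
units, predominantly through the spike-pattern terms), and many
compensated parameter combinations reach moderately low fitness. From
current-clamp spike trains alone, the persistent-potassium density is
reliably identified only when the optimization is driven well below that
compensated shelf — populations of about 100 for 15+ generations per cell
when the target sits near the centre of the search box, and substantially
more for arbitrary cohort cells. Adding the subthreshold voltage-step
protocol to the reference set resolves this: the clamp currents pin KP
directly and desk-scale runs (population 100, about 12 generations, on a
0.4-2.5x search box around the template) then recover cohort-cell KP to
within roughly 10-20%. The recovery experiments in the shipped tests use
exactly that design; each test states its population, generation count,
group sizes and integration steps.

## Statistics

Voltage-bin comparisons fit, per 5 mV bin, a linear mixed-effects model
`current ~ condition + (1 | cell)` (random intercept per cell, delegated
to `lme4`), report Wald z-scores and two-sided normal p-values, and adjust
across bins with Benjamini-Hochberg (`stats::p.adjust`); the -log10
thresholds 1.3 and 2 (p = 0.05 / 0.01) are annotated in the result.
Reversal potentials are linear interpolations of the I-V zero crossing;
segment slopes are OLS on the -77/-62 and -62/-47 mV intervals (pA/mV =
nS). Fitted conductances are normalized to the control median per
parameter before unpaired Mann-Whitney comparisons.

The Henderson liquid-junction potential uses a shipped table of standard
limiting equivalent conductivities (including gluconate, HEPES, phosphate
species, and EGTA carried at its dominant 2- charge state near pH 7.2);
HEPES enters by its anionic fraction at the stated pH (pKa 7.48), with
matching counter-cations from the titrant, and Mg-ATP/GTP are omitted
(both choices affect the result by under 1 mV). The sign convention is
pipette-referenced: about -14 mV for the study's K-gluconate internal
against bicarbonate-buffered aCSF. ANOVA sample sizes come from the
noncentral-F power function with noncentrality $f^2 k n$ evaluated
directly; with k = 6 groups, f = 0.8, alpha = 0.05 and 80% power the
smallest group size is n = 5 (30 cells total), and n = 4 is confirmed
underpowered.

## Worked example

```{r example, eval = FALSE}
model <- default_soma_model()
steps <- simulate_cc(model, protocol_steps(c(-100, 250)))
ramp  <- simulate_cc(model, protocol_ramp(300))
extract_features(steps, ramp, rin = measure_rin(model))

# fit the model back to its own trace (self-recovery)
ref <- simulate_cc(model, stimulus_protocol("current_step",
                                            200, 1000, 300, 250))
fit <- fit_cell(ref, model,
                config = ea_config(pop_size = 100, max_gen = 15, seed = 1))
fit$best$theta["KP"] / get_params(model)["KP"]
```

## Known limitations

* Point soma only: no dendritic or axonal compartments, no synapses, and
  a single fixed temperature (25 deg C, no Q10 scaling).
* No hyperpolarization-activated (HCN) conductance is included in the
  channel set, so the default model produces essentially no sag; sag
  extraction is validated on analytic fixtures instead.
* The default kinetic constants are self-consistent surrogates, not a
  reproduction of any published parameter file.
* Recovery of parameters other than the well-identified potassium
  conductances is poor at desk scale (sloppy directions of the model);
  conclusions should rest on the parameters the recovery tests actually
  validate.
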