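Package: somafit
Title: Conductance-Based Somatic Modelling, Patch-Clamp Feature Extraction
    and Evolutionary Model Fitting for Layer 5 Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the somatic compartment of thick-tufted layer 5b
    pyramidal neurons with Hodgkin-Huxley style sodium, potassium and
    calcium conductances and a calcium pool, extracts the standard
    current-clamp feature set (resting potential, input resistance, spike
    threshold, rheobase, sag, after-depolarization, after-hyperpolarization,
    firing frequency) and classifies cells into the type A / type B layer-5
    subtypes. Fits model conductances to reference voltage traces with a
    real-valued adaptive elitist evolutionary strategy (Latin hypercube
    initialisation, tournament selection, BLX-alpha crossover, cooled
    Gaussian mutation) driven by a multi-component fitness combining
    spike-weighted RMS trace error, spike-count fidelity, spike-timing error
    and the Wasserstein distance between inter-spike-interval distributions.
    Includes subthreshold current-voltage analysis (segment regressions,
    voltage-bin mixed-effects comparisons with Benjamini-Hochberg
    correction, reversal potentials), Henderson liquid-junction-potential
    calculation, noncentral-F ANOVA sample-size computation, and a
    synthetic-cohort generator emulating anesthetic modulation of
    persistent-potassium and SK conductances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    lme4,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
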