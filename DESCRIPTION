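Package: somnopk
Title: Simulation and Analysis of Crossover Pharmacokinetic-Sleep Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for randomized crossover studies of hypnotic drugs that combine
    plasma pharmacokinetics with polysomnography. Implements noncompartmental
    pharmacokinetic analysis (Cmax, tmax, terminal slope, half-life, trapezoidal
    and extrapolated AUC), hypnogram-derived sleep variables on 30-s epochs
    (sleep latency by the three-consecutive-epoch rule, REM latency, stage
    minutes, WASO, sleep efficiency), the quantitative-EEG slow-wave-energy
    pipeline (zero-phase filtering, downsampling to 128 Hz, Welch averaged
    modified periodograms with 4-s Hann windows, 0.75-4.0 Hz delta power,
    per-half-night slow-wave energy over artifact-free N2/N3 epochs),
    orthostatic (Schellong) and endocrine summaries, and within-subject paired
    contrasts with sign-flip permutation tests, bootstrap confidence intervals
    and Benjamini-Hochberg correction. A synthetic-study generator produces
    complete crossover data sets (Bateman-shaped plasma curves with lognormal
    between-subject variability and quantification-limit censoring, hypnograms
    with configurable condition effects, stage-dependent EEG with 1/f
    background and artifacts, cardiovascular and hormone tables) so every
    analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
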