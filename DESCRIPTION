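Package: earpipe
Title: Ear-EEG Auditory Evoked Response Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating ear-centered EEG acquisition with auditory
    paradigms. Generates amplitude-modulated and gated auditory stimuli and
    oddball event schedules; simulates multichannel ear-EEG recordings with
    1/f background, alpha and power-line components, steady-state and
    event-related responses, and blink/muscle artifacts; implements an
    auditory steady-state response (ASSR) detection chain (zero-phase FIR
    filtering, sweep averaging, FFT power spectra, neighbor-bin SNR) and a
    P300 oddball ERP chain (filtering, resampling, epoching, baseline
    correction, joint-probability and kurtosis epoch rejection, ICA blink
    removal, grand averages and difference waves); and scores bipolar
    comfort questionnaires with noninferiority/nonsuperiority t-tests and a
    tie-corrected Friedman rank sum test. Outputs are tibbles with broom-style
    tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
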