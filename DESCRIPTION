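Package: gapekit
Title: Valve-Gape Valvometry Analysis for Noise and Predator Exposure Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing bivalve valve-gape (valvometry) time series
    from controlled exposure experiments combining sound playback and live
    predator cues. Converts raw electromagnetic-sensor records to normalized
    fraction-open traces, detects sudden strong valve-closing events with a
    robust moving-average threshold, computes short- and long-term epoch
    responses and closing-event rate changes, turns scored predator
    state-transition logs into ethogram time budgets, builds and characterizes
    playback stimuli (looping with linear crossfades, band-pass filtering,
    Welch power spectral density, band rms sound pressure levels), and fits
    Gaussian and Poisson generalized linear models with all-subsets AICc
    selection and Tukey pairwise contrasts. Includes a synthetic-trial
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
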