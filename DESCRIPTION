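Package: vpref
Title: Satiety-Weighted Preference Models for Ventral Pallidum Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured single-unit recordings
    collected while an animal's preference between two liquid rewards
    (sucrose versus water) shifts within a session as thirst is quenched.
    Provides a plain-text session format with validation, event-aligned
    spike-count extraction, smoothed behavioral preference curves,
    peri-stimulus time histograms with causal half-normal smoothing and
    baseline z-scoring, Poisson generalized linear models classifying
    neurons with outcome-by-time interactions, and a family of Poisson
    spike-count models (unmodulated, satiety, preference, mixed, licks)
    fitted by constrained multi-start maximum likelihood and compared by
    cross-validated likelihood. Fitted mixed models yield per-neuron
    estimates of behavioral preference and indifference points that can be
    compared against a logistic fit to the animal's choices. A synthetic
    session generator with known ground truth supports end-to-end testing
    and calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
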