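Package: swrtools
Title: Sharp-Wave Ripple Detection and Reactivation-Driven Plasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking hippocampal sharp-wave-ripple (SWR)
    associated reactivation of CA3/CA1 place cells to the induction of
    long-term potentiation. Detects ripple events in local field potential
    traces by band-pass filtering, envelope extraction and SD thresholding;
    computes place-field rate maps and per-trial firing-position rasters;
    derives SWR-conditioned spike statistics (spikes per SWR, peri-SWR
    histograms, population co-activity, SWR-restricted cross-correlograms);
    classifies causal CA3->CA1 spike pairs inside a fractional window around
    ripple onset; builds three-channel slice stimulation protocols (spike-train
    replay, timed pairing, sine-wave surrogates); and quantifies synaptic
    change from EPSC sweep series, correlating it with spike-train predictors.
    A seeded synthetic-data generator produces ground-truth-labeled sessions
    (LFP, spike trains, trajectory, EPSC series) so every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
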