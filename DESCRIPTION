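Package: calciumflow
Title: Trace-Level Analysis of Two-Photon Calcium Imaging Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of somatic calcium fluorescence traces from two-photon
    imaging of mouse visual cortex: neuropil correction, rolling-percentile
    baseline estimation, standardized dF/F0, locomotion and pupillometry
    conditioning, behavioral-state segmentation, permutation-null
    cross-correlation of activity with locomotion, pairwise synchrony,
    orientation-tuning statistics (gOSI, DSI, SNR, split-half signal
    correlation, noise correlation), contrast-response summaries (log-scale
    centre of mass, contrast-preference classes), hierarchical bootstrap
    inference for nested (animal/neuron) data, and quantification of
    monosynaptic rabies-tracing cell tables.  A seeded synthetic-session
    generator emulates the recordings (semi-Markov locomotion bouts, Poisson
    events through a calcium kernel, neuropil contamination, trial schedules)
    so that every stage of the analysis is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
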