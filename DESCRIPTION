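Package: erpnet
Title: Emotional-Oddball ERP Statistics and Phase-Locking Networks for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for probing residual emotional
    processing in multichannel EEG recorded under an auditory emotional
    oddball paradigm, aimed at studies of disorders of consciousness.
    Provides a synthetic EEG generator with controlled event-related
    components and inter-channel phase coupling for three subject groups
    (healthy controls, minimally conscious state, unresponsive wakefulness
    syndrome); EDF reading and writing; preprocessing (mastoid
    re-referencing, zero-phase filtering, epoching, artifact rejection,
    channel interpolation); mass-univariate paired permutation statistics
    with Benjamini-Yekutieli false-discovery-rate control; phase-locking-value
    functional connectivity; weighted graph-theoretic network properties
    (clustering coefficient, characteristic path length, global and local
    efficiency, small-worldness); and mixed repeated-measures ANOVA with
    Mauchly/Greenhouse-Geisser sphericity handling plus edge-wise network
    contrasts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
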