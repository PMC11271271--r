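Package: lrdpipe
Title: Detection and Analysis of Large Rhythmic Depolarizations in Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis stack for spontaneous synaptic activity in cortical
    neurons and slice networks. Detects and classifies depolarizing synaptic
    events (unitary EPSPs versus compound large rhythmic depolarizations) in
    intracellular membrane-potential traces, measures their kinetics and
    summary statistics, estimates passive and active intrinsic membrane
    properties from current-step protocols, computes Morlet-wavelet
    time-frequency representations and amplitude spectra, processes
    multi-electrode-array recordings (band-pass filtering, MAD-threshold spike
    detection, cumulative-moving-average burst detection, local field
    potential detection), and quantifies network synchrony with a 200-ms-bin
    co-activity graph and mean degree centrality. A seeded synthetic-data
    generator emulates the event statistics of human layer 2/3 recordings,
    including noradrenergic and cholinergic modulation regimes, so that every
    stage of the pipeline can be verified against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
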