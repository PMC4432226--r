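Package: ng2circuit
Title: Analysis of GABAergic Interneuron-NG2 Cell Synaptic Microcircuits
Version: 0.1.0
Authors@R: person("Circuit", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse unitary GABAergic synaptic
    connections between cortical interneurons and NG2 glial progenitor
    cells in the developing neocortex. Provides spike-waveform feature
    extraction and fast-spiking/non-fast-spiking interneuron
    classification, detection and quantal analysis of unitary
    postsynaptic currents under a binomial release model,
    photostimulation-based connectivity mapping with distance-resolved
    connection probabilities, 3D synaptic puncta colocalization and
    eccentric-shell density geometry, and binomial connectivity
    statistics (Wilson score intervals, interval-overlap rule, Pearson
    chi-square). A synthetic-data module generates every input the
    analyses consume, with analytic ground truth, so the full pipeline
    can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
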