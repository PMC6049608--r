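Package: minstim
Title: Quantal Analysis of Silent Synapses from Minimal-Stimulation Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the fraction of silent (AMPA-receptor-lacking)
    synapses from minimal-stimulation voltage-clamp experiments under a Poisson
    quantal release model: sweep-set data structures and plain-text file layouts,
    evoked-EPSC event detection (baseline and noise estimation, charge and peak
    measurement, failure classification at hyperpolarized and depolarized holding
    potentials, drift and noise quality control), failure-rate and mean-quantal-
    content estimators, the silent-synapse fraction estimator, potency versus
    failure-rate quantal-size fits, AMPA/NMDA ratio measurement, fEPSP slope and
    LTP time-course quantification, input-output slope analysis, and a seeded
    synthetic sweep simulator with known ground truth that makes every stage of
    the pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
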