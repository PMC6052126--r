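Package: spikectx
Title: Behavioral-Context-Dependent Spiking Variability and Beta Phase Locking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of trial-segmented extracellular recordings from
    multielectrode arrays: local spike-time irregularity (CV2), trial-to-trial
    spike-count variability (Fano factor), their relationship under the renewal
    point-process prediction FF ~ CV^2, and phase locking of spikes to local
    field potential beta oscillations via neighbor-averaged LFP signals,
    zero-phase bandpass filtering, Hilbert phase and the Rayleigh test.
    Includes a doubly stochastic gamma-renewal session generator that
    reproduces the wait/movement statistical regimes (FF >> CV2^2 during
    movement preparation, FF ~ CV2^2 during execution) so that every pipeline
    stage can be exercised and calibrated on synthetic sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
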