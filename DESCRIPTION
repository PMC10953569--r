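Package: meapipe
Title: Microelectrode-Array Electrophysiology Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for in vitro microelectrode-array (MEA)
    electrophysiology: raw multichannel recording I/O (flat int16 binary with
    JSON sidecar, HDF5 container), Butterworth band-pass conditioning,
    median-based noise estimation and threshold spike detection with waveform
    cutouts, PCA spike sorting, channel and network statistics (firing rates,
    active-channel rule, SNR, binned spike-train correlation, burst detection,
    box summaries, spatial firing maps), MEA layout geometry generators
    (rectangular, curved, perturbed, multi-well), electrical and optical
    stimulation protocol compilers, calcium dF/F0 trace analysis with
    first-edge alignment against the local field potential, and a ground-truth
    simulator that renders extracellular traces and matched fluorescence from
    known spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    readr,
    signal,
    cluster,
    jsonlite,
    yaml,
    rhdf5,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
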