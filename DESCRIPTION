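Package: cvautonomics
Title: Cardiovascular Autonomic Analysis of Rat Physiological Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of anesthetized-rat cardiovascular
    recordings: R-peak detection and beat segmentation of ECG and arterial
    pressure, continuous-wavelet (Morlet) low-frequency/high-frequency band
    power and the LF/HF sympathovagal balance index, pharmacologically
    provoked baroreflex gain and chemoreflex sensitivity, picrosirius-red
    collagen (fibrotic-area) quantification from stained-section images, and
    the group-statistics layer (mean +/- SEM, normality and variance checks,
    one-way ANOVA with Dunnett comparisons against control, unpaired
    t-tests). A calibrated synthetic-data generator emulates the recordings,
    histology images and group tables with known ground truth so every stage
    of the pipeline is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    png,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
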