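Package: hgalpha
Title: Alpha and High-Gamma Dynamics Across Human Auditory Cortical Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of intracranial local field potential
    recordings from primary (posteromedial Heschl's gyrus) and non-primary
    (anterolateral Heschl's gyrus) human auditory cortex. Provides click-train
    and three-band noise-vocoded stimulus synthesis, functional localization of
    recording contacts by inter-trial phase coherence and evoked-potential
    latency, Morlet wavelet time-frequency power with decibel baseline
    correction, separation of the aperiodic 1/f spectral component from
    narrowband alpha oscillations, exact Wilcoxon signed-rank inference with
    r-equivalent effect sizes, distance-decay regression, and a seeded
    end-to-end pipeline over synthetic multi-contact, multi-hemisphere
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
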