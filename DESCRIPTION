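Package: finpulse
Title: Fin Whale 20-Hz Pulse Detection and Seismic-Survey Period Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying the association between seismic
    airgun shooting and fin whale 20-Hz pulse detections in passive acoustic
    recordings. Provides a synthetic-scene generator (downsweep whale pulses,
    impulsive airgun shots, pink ambient noise, and negative-binomial hourly
    count tables), a PCEN spectrogram frontend, a small convolutional neural
    network frame detector with evaluation utilities (confusion, ROC/AUC,
    optimal threshold), hourly/daily detection aggregation over survey
    periods, a negative-binomial mixed model with estimated marginal means
    and Tukey-adjusted contrasts, a worst-case acoustic masking correction,
    and LOESS trend reporting with detector-uncertainty ribbons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    emmeans,
    ggplot2,
    glmmTMB,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
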