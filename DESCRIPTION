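Package: eegperm
Title: Sensor-Space EEG Spectral Analysis with Mixed Models, TFCE and
    Max-Statistic Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for within-subject sensor-space EEG spectral analysis in
    small samples: deterministic preprocessing (first-order high-pass,
    Butterworth band-stop line filtering, spherical-spline interpolation of
    bad channels, average re-referencing), Welch power spectral density over
    non-overlapping 30-second windows with artifact-based window rejection,
    per-channel linear mixed models of band power with a participant random
    intercept, threshold-free cluster enhancement (TFCE) of channel statistic
    maps over a sensor adjacency graph, and family-wise inference via a
    max-statistic permutation null that relabels condition blocks within
    participants. A synthetic-data generator emulates the target study design
    (five participants, within-subject condition blocks crossing hypnosis,
    memory and recall-focus factors, 257 channels at 250 Hz, 1/f background
    spectra, injected alpha-band effects) so that every stage can be validated
    against known ground truth. Also includes scoring and small-sample
    nonparametric statistics for the accompanying phenomenology instruments
    (Greyson NDE scale, SHSS:C categories, MCQ totals, visual analogue
    scales, Wilcoxon signed-rank tests with effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    igraph,
    jsonlite,
    yaml,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
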