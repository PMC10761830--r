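Package: sensorygain
Title: Gain Modulation, Population Correlation and Detection Metrics for
    Sensory Neuroscience Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of within-subject pharmacological
    experiments on sensory cortex: seeded generators for trial-organised
    spike trains (gamma-renewal counts with controlled first-spike latency),
    GCaMP-like population fluorescence with a shared latent factor, and
    go/no-go detection sessions with a psychometric observer; plus the
    matching analysis layer - evoked firing rates and response functions,
    first-spike latency and jitter, Fano factors, multiplicative-vs-additive
    gain decomposition, delta-F/F0 processing with neuropil correction,
    pairwise noise correlations and joint-PSTH, lick-based trial
    classification, block detection rates and d-prime, and a nonparametric
    comparison layer (Friedman test with Dunn's multiple comparisons,
    Wilcoxon signed-rank, paired t) with a normality gate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
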