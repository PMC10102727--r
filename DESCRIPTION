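Package: brainrev
Title: Temporal Asymmetry (Irreversibility) Analysis of Parcellated Brain Time Series
Version: 0.1.0
Authors@R:
    person("brainrev", "maintainers", email = "maintainers@brainrev.example.org",
           role = c("aut", "cre"))
Description: Model-free quantification of time-irreversibility in multivariate
    (e.g. parcellated fMRI BOLD) time series by comparing mutual-information
    transformed time-shifted correlation matrices of the forward and
    time-reversed signals. Provides sliding-window dynamics (average and
    deviation reversibility per subject), a resting-state-network
    decomposition of the statistic, nonparametric group comparisons
    (Mann-Whitney rank-sum with Benjamini-Hochberg FDR), a seeded synthetic
    cohort generator based on lag-1 vector autoregression with controllable
    coupling asymmetry, and a file-based pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
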