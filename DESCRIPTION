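Package: eegmicrostates
Title: EEG Microstate and Band-Power Analysis of Mental Workload
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for spectral and microstate analysis of multichannel
    scalp EEG under contrasting mental-workload conditions. Provides a
    synthetic EEG generator with planted microstate dynamics and band-power
    contrasts, a standard offline preprocessing chain (resampling,
    zero-phase band-pass and notch filtering, amplitude-based epoch
    rejection, common average reference, epoching), periodogram band-power
    estimation for the classical delta/theta/alpha/beta bands,
    polarity-invariant modified k-means microstate segmentation with
    two-level (subject then grand-mean) clustering, back-fitting, temporal
    and syntax parameters, and the accompanying statistical battery
    (paired t tests with Cohen's d, one-way repeated-measures ANOVA with
    partial eta squared, Fisher protected LSD, Pearson correlation with
    strength categories, and Benjamini-Hochberg FDR correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
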