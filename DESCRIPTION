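Package: lumitrf
Title: Luminance-Tagging Temporal Response Functions for Figure-Ground EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissociate foreground and background neural responses
    during visual texture segregation from a single EEG stream. Provides
    constrained random luminance-sequence generation for luminance tagging,
    a linear-convolution forward model for simulating multichannel EEG with
    known temporal response functions (TRFs), a standard preprocessing chain
    (Butterworth band-pass, mastoid re-referencing, epoching, baseline
    correction, amplitude-threshold rejection, decimation), ridge-regression
    TRF estimation on lagged stimulus designs, texture-segregation visual
    evoked potential (tsVEP) subtraction, trial-shuffle null controls, and
    component-window region-of-interest statistics (one-sample t tests with
    Cohen's d and Bonferroni correction; two-way repeated-measures ANOVA
    with Mauchly's test and Greenhouse-Geisser correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
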