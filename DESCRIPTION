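Package: condind
Title: Combining Conditionally Independent Sources of Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for combining multiple sources of probabilistic evidence
    about a discrete outcome under the assumption of conditional
    independence, and for testing whether that assumption holds in data.
    Provides the closed-form combination rules for two or many evidence
    sources, odds and linear-approximation variants, diagnostics on joint
    count tables (conditional-independence residuals, the g-factor, the
    identifiability condition), binomial resampling of combined estimates,
    correlated binary outcome simulators, and four worked application
    suites: repeated diagnostic testing, biomarker-based biological age,
    multisensory cue integration, and selection-history analysis of a
    simulated visual search task.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
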