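Package: fluxmend
Title: Misspecification Diagnostics and Repair for Overdetermined Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Least-squares estimation of intracellular fluxes from measured
    exchange fluxes in overdetermined metabolic flux analysis (MFA), together
    with a toolkit for stoichiometric model misspecification: a closed-form
    bias formula for omitted reactions, three specification tests (Ramsey
    RESET, nested F-test, heteroscedasticity-consistent Lagrange multiplier),
    an iterative F-test procedure that repairs a model by promoting candidate
    reactions, and a random-network simulation harness for benchmarking
    detection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
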