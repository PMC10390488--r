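Package: luadsim
Title: Mechanistic Simulation of EGFR-Mutant Lung Adenocarcinoma Under
    Gefitinib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clone-structured mechanistic simulator of tumor growth in
    EGFR-mutant lung adenocarcinoma under first-generation EGFR tyrosine
    kinase inhibition (gefitinib).  Couples a per-clone five-state growth
    model (proliferating, quiescent and dead cells, neo-angiogenic
    carrying capacity, immune pressure) to algebraic EGFR-pathway
    signaling, closed-form oral pharmacokinetics with Emax inhibition,
    and RECIST-based time-to-progression read-outs.  Includes a virtual
    population engine with baseline comparison statistics (Fisher exact
    and t tests), a Kaplan-Meier validation protocol with bootstrapped
    prediction intervals and bootstrapped log-rank tests, tornado
    sensitivity analysis, allometric rescaling between in vitro, mouse
    and human settings, and synthetic reference-trial generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
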