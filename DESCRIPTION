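Package: circaqt
Title: Circadian Heart-Rate and Electrolyte Rhythms in Simulated QT/QTc and
    Drug-Induced QTc Prolongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based cardiac safety pipeline coupling circadian models of
    the RR interval and plasma potassium, sodium and calcium to the
    ten Tusscher-Panfilov 2006 human ventricular myocyte model in a
    heterogeneous one-dimensional fibre. Pseudo-ECG traces are computed from
    the fibre, QT intervals are measured by the tangent method, corrected for
    heart rate with fixed or fitted exponents (Fridericia, Bazett, individual,
    study-specific), and used to run virtual thorough-QT trials of a
    hERG-blocking drug (tolterodine-like synthetic pharmacokinetics, Hill
    pore-block pharmacodynamics) in a virtual population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
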