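Package: primsoup
Title: Self-Organisation and Markov Blankets in a Synthetic Primordial Soup
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an ensemble of stochastically coupled subsystems with
    Newtonian (structural) and Lorenz-form electrochemical (functional)
    dynamics, and analyses the self-organisation that emerges: spectral
    recovery of the principal Markov blanket from a windowed contact graph,
    a canonical-variates test that internal dynamics predict the motion of
    external subsystems (against a time-reversal null), lesion experiments
    probing autopoietic maintenance of structural integrity, and numerical
    verification of the variational free-energy lemma on tractable
    linear-Gaussian systems in Helmholtz standard form.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
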