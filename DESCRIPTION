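Package: wormqg
Title: Quantitative Genetics of Nematode Locomotion Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of locomotion behavior in
    experimental Caenorhabditis elegans populations. Locomotion is modeled as a
    three-state continuous-time Markov chain (still, forward, backward) whose
    six transition rates are the component traits; the package estimates those
    rates from worm-track data by maximum a posteriori or MCMC inference,
    estimates broad-sense genetic covariance matrices (G) from inbred-line
    panels with a Bayesian multivariate mixed model, compares G-matrices via
    spectral analysis, eigenvector angles and genetic covariance eigentensors,
    estimates quadratic (Lande-Arnold) selection surfaces with canonical
    analysis, and projects the loss of genetic variance expected under drift in
    the infinitesimal model. Simulators with known ground truth for every data
    type support end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    data.table,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
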