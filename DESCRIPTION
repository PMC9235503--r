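Package: fpkit
Title: Deep Kernel Learning for Molecular Fingerprint Prediction from
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("fpkit", "developers", email = "fpkit@example.org", role = c("aut", "cre"))
Description: Predicts binary molecular fingerprints from tandem mass
    spectrometry (MS/MS) data and uses the predicted fingerprints to rank
    candidate structures in a database search. Spectral similarity kernels
    (the probability product kernel is built in; fragmentation-tree kernels
    enter as precomputed matrices) are embedded into a finite feature space
    with the Nystroem approximation; a linear support vector machine or a
    deep neural network is then trained on the embedding by minibatch
    gradient descent with per-compound sample weights. Includes MGF/MSP
    readers, spectrum merging and noise simulation, Platt probability
    calibration, structure-disjoint cross-validation, multi-label metrics
    (MCC, bookmaker informedness, Tanimoto) with micro averaging of rare
    labels, and a synthetic benchmark generator so the full pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
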