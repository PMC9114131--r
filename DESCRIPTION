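Package: chembias
Title: Bias-Corrected Molecular Property Prediction with Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and mitigating sample-selection bias in
    molecular property regression. Provides a synthetic generator of
    molecular-like labeled graphs, four biased-sampling scenarios driven by
    sigmoid inclusion probabilities calibrated to a target average sampling
    rate, a message-passing graph neural network regressor (edge-type
    conditioned messages, gated recurrent unit updates, set2set readout)
    trained with Adam, and two debiasing estimators from causal inference:
    inverse propensity scoring (IPS) with a train-versus-test propensity
    classifier, and counterfactual regression (CFR) with a Wasserstein
    integral probability metric between domain embeddings and a closed-form
    importance-weight head. Includes an experiment harness with paired
    significance testing and indicator-binned error diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
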