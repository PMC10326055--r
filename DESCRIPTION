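Package: metacognet
Title: Performance-Optimized Neural Network Models of Decision Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying decision confidence and metacognition with
    performance-optimized neural networks. Provides a compact vectorized
    neural-network engine (convolutional encoders, batch normalization,
    Adam), supervised confidence networks and an actor-critic opt-out task,
    a two-dimensional denoising variational autoencoder with a latent
    Bayesian ideal observer, a type-1/type-2 signal-detection battery
    (d-prime, maximum-likelihood meta-d-prime, response-specific variants),
    positive-evidence-bias and sensitivity-dissociation experiments,
    representation-geometry and single-unit analyses, and simulated
    lesion/TMS perturbations, together with synthetic stimulus generators so
    every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
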