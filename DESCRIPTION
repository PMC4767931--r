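Package: vasculearn
Title: Vascular-Gated Dropout in Autoencoder Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of a coupled neurovascular model in which a ring
    network of vascular oscillators gates stochastic dropout in the hidden
    layer of a rate-coded autoencoder, while the autoencoder's reconstruction
    error feeds back to the vessels as neuronal energy demand. Provides the
    vascular oscillator ring with its deficit-driven input signal, a
    rectified-linear autoencoder trained by minibatch gradient descent under
    an externally supplied dropout mask, the vessel-to-neuron projection and
    demand scheduler that close the loop, synthetic bar-pattern and MNIST IDX
    data handling, synchrony (average pairwise correlation) and
    feature-independence (mutual information index, structural similarity
    index) metrics, and orchestration for synchrony, connectivity and
    temporal-ratio experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
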