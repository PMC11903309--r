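Package: flowrep
Title: Unsupervised Representation of Dynamics over Latent Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes multi-trial dynamical systems data (for example neural
    population firing rates) into local flow fields over latent manifolds and
    embeds them in a shared latent space with an unsupervised contrastive
    geometric neural network. Manifolds are approximated by continuous
    k-nearest-neighbour graphs; tangent frames are estimated by local singular
    value decomposition and aligned by parallel transport (Kabsch); vector
    fields are optionally denoised by vector diffusion under the connection
    Laplacian and summarised by directional-derivative (gradient) filters,
    optionally reduced to rotation-invariant inner-product features. Latent
    distributions are compared across conditions with exact optimal-transport
    distances, with multidimensional scaling, hierarchical clustering and
    generic decoders for post-hoc analysis. Includes self-contained simulators:
    planar toy vector fields, the Van der Pol oscillator lifted to a
    paraboloid, and trainable rank-two rate recurrent networks performing a
    delayed-match-to-sample task.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    deSolve,
    jsonlite,
    lhs,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
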