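Package: tomexo
Title: Tree of Mutually Exclusive Oncogenes for Cancer Progression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic tree-structured modelling of cancer progression from
    cross-sectional binary mutation data. Driver genes are grouped into nodes of
    mutually exclusive genes (driver pathways) arranged in a rooted tree that
    encodes the order in which driver mutations accumulate. The package provides
    a linear-time dynamic-programming likelihood that marginalises over the
    latent noise-free mutation matrix under global false-positive and
    false-negative error rates, Metropolis-Hastings structure inference with a
    set of dedicated tree and gene-assignment moves, a generative simulator for
    benchmark cohorts, empirical and gradient-based error-rate estimation, and
    method-independent validation statistics (probabilistic-causation
    progression and mutual-exclusivity scores with binomial tail p-values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
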