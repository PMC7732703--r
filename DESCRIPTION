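Package: actinfr
Title: Discrete-State Active Inference Agents for Partially Observed
    Markov Decision Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and simulating discrete state-space active
    inference agents. Provides containers for categorical generative models
    (likelihood, transition, prior and preference distributions, policy
    spaces), policy-conditioned state estimation by gradient descent on
    variational free energy, planning by expected free energy with its
    risk/ambiguity and extrinsic/epistemic decompositions, softmax policy
    posteriors with precision and Occam-window pruning, Dirichlet learning
    of the likelihood mapping, Bayesian model reduction and expansion, and
    synthetic task environments (T-maze epistemic foraging, seeded random
    POMDPs) for end-to-end simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
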