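Package: banditlens
Title: Characterising Black-Box Choice Models in Restless Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates restless four-armed bandit tasks with Gaussian-drift
    payoffs and heterogeneous synthetic agent populations, trains recurrent
    (LSTM) next-action prediction models on fixed-length action-reward
    windows, fits a group-level Q-learning model by maximum likelihood, and
    characterises the black-box recurrent model against the two explicit
    cognitive models via held-out accuracy comparison, a trial-wise
    prediction-similarity statistic, and probe-based experimental
    simulations scored with symmetric Kullback-Leibler distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
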