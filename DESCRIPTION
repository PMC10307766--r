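Package: pabalance
Title: Workload-Balanced Patient Assignment via a Distributed Genetic Algorithm
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Balances patient-to-doctor assignment in online (cloud)
    healthcare triage. Each patient carries an estimated diagnosis time and a
    list of eligible doctors; the objective is to minimise the time factor
    (TF), the population standard deviation of per-doctor total diagnosis
    time. The package implements an island-model (distributed) genetic
    algorithm with integer encoding, uniform crossover, candidate-list
    mutation, family selection and ring-topology elite migration, together
    with Random, Greedy, discrete-adapted DE/best/1 and panmictic GA
    baselines, ablation variants, a seeded benchmark instance generator, a
    plain-text instance format, and an experiment harness with Wilcoxon
    rank-sum comparisons and convergence reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
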