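Package: causaltriad
Title: Causal Inference on Genotype-Mediator-Phenotype Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking of causal-inference procedures on
    triplets consisting of a SNP genotype G, an intermediate molecular trait X
    (e.g. gene expression) and an outcome phenotype Y. Generates data under
    twelve linear-Gaussian causal scenarios (optionally with a latent shared
    environmental confounder), and applies six procedures for recovering the
    causal structure: Mendelian randomisation (single-instrument two-stage
    least squares), a four-component causal inference test of complete
    mediation, lowest-BIC selection among testable Gaussian path models,
    Bayes-factor selection among the nine direct/indirect/unassociated
    genotype-association partitions, and exhaustive score-based Bayesian
    network selection with both a conditional-Gaussian BIC score and an
    imaginary-sample-size Bayesian score. Includes replicated benchmark
    drivers for detection proportions, proportion-correct summaries, mean
    score matrices and effect-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
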