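Package: ornor
Title: Transcription Factor Activity Inference with Noisy OR-NOR Bayesian Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers active transcription factors from discretized differential
    gene-expression evidence and a signed TF-gene causal graph, using a Bayesian
    network in which gene regulation follows noisy Boolean logic: down-regulation
    is a noisy OR over active inhibitors, up-regulation a noisy OR over active
    activators gated by a NOR over inhibitors, and leak priors absorb regulation
    the graph cannot explain. Latent TF activity states, per-TF activity
    probabilities, per-edge modes of regulation and true gene states are sampled
    jointly by multi-chain Gibbs sampling with Gelman-Rubin convergence
    monitoring and early stopping. Includes generators for random signed
    bipartite regulatory networks with negative-binomial out-degrees and
    ground-truth evidence, data and network randomization perturbations, and
    ROC/precision-recall benchmarking of regulator recovery, plus readers and
    writers for tabular network, evidence and result formats and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
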