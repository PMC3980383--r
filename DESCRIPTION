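Package: drugprop
Title: Drug-Disease Association Inference by Heterogeneous Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers drug-disease associations by propagating probability from a
    query disease phenotype across an integrated heterogeneous network built
    from three weighted homo-networks (chemical-similarity drug network,
    expression-weighted protein-interaction network, phenotype-similarity
    network) and two bipartite hetero-networks (drug-target and gene-phenotype
    links). Converged visitation probabilities are corrected for topological
    bias against a reference run with uniform protein-interaction weights and
    candidate drugs are ranked by a Z-score specificity statistic. Includes
    ROC/AUC benchmarking, a diffusion-parameter sweep, and a synthetic-fixture
    generator with planted drug-disease associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
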