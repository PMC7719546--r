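Package: devonet
Title: Stochastic Gene-Network Development and the Evolution of
    Phenotypic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a small gene-regulatory network that
    develops a quantitative phenotype in a single cell, using a
    tau-leaping stochastic scheme for transcription, translation, decay
    and signal input.  Developing individuals may sense their environment
    through an open-loop environmental signal or a closed-loop
    performance signal (a negative feedback on the mismatch between the
    current and the optimal phenotype), both acting through cooperative
    (Hill) binding with the product of dedicated signal-binding genes.
    Populations of such individuals evolve under a haploid Wright-Fisher
    model with Gaussian stabilizing selection and a six-type mutation
    model (duplication, deletion and four regulatory-effect channels).
    Assays measure reaction norms, classify genotypes as plastic, and
    quantify developmental noise; an orchestration layer runs the full
    two-environment by three-signal experimental design and summarizes
    it with Welch and Fisher tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
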