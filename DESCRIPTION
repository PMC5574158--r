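Package: episel
Title: Forward Simulation of Genomic Selection Under Epistasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward gene-dropping simulator and evaluation pipeline for
    in-silico divergent genomic selection on a Drosophila-like genome.
    Generates synthetic founder haplotype panels with a U-shaped site
    frequency spectrum and sex-specific genetic maps (no male
    recombination), assigns quantitative trait nucleotides under additive
    or complementary-epistasis architectures, drops gametes through
    truncation-selected pedigrees, evaluates candidates with Bayesian
    GBLUP (additive, dominance and Hadamard epistatic kernels fitted by
    Gibbs sampling on eigendecomposed relationship matrices), and computes
    response to selection, progeny-test breeding values, additive
    variance, prediction accuracy, linkage-disequilibrium decay with a
    Hill-Weir fit, and excess-homozygosity inbreeding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
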