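Package: mitostruct
Title: Population Structure and Demographic Model Choice from Ancient
    Mitochondrial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing grouped, heterochronous (serially sampled)
    mitochondrial genome alignments. Provides haplogroup frequency tables
    with macro-haplogroup collapsing and principal component analysis;
    within-group diversity statistics (haplotype count and diversity,
    segregating sites, mean pairwise differences, Tajima's D); distance-based
    differentiation (pairwise difference and Kimura two-parameter distances,
    one-level distance AMOVA with permutation tests, pairwise PhiST matrices,
    classical multidimensional scaling); a serial-sampling coalescent
    simulator with finite-sites mutation for competing continuity and
    discontinuity demographic models; and Approximate Bayesian Computation
    model choice via random forests with linear discriminant augmentation,
    out-of-bag confusion matrices and error-regression posterior
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
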