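Package: haplodrift
Title: Distinguishing Explanations for Deep Mitochondrial Divergence Within
    a Population Sample
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide among four explanations for deep mitochondrial
    DNA divergence observed within a single population sample:
    drift-mutation equilibrium in a large population, balancing selection,
    cryptic species, and introgression following secondary contact.
    Implements nucleotide diversity and mismatch distributions with a
    mixture-based bimodality assessment, minimum spanning haplotype
    networks, Nei-Gojobori Ka/Ks counting under the invertebrate
    mitochondrial code, exact and Markov chain Hardy-Weinberg and
    genotypic linkage-disequilibrium tests, Weir-Cockerham F_ST, genetic
    landscape shape interpolation, genotype/trait encoding with PCA and
    model-based clustering concordance (Cohen's kappa), a rule-based
    verdict engine, and coalescent scenario simulators that generate data
    with the statistical signature each hypothesis predicts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: PopulationGenetics, Genetics, Coalescent, SequenceMatching
RoxygenNote: 7.3.3
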