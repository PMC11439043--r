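Package: mitosel
Title: Branch-Site Selection Tests and Structural Mapping for Mitochondrial OXPHOS Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and interpreting positive selection in
    mitochondrial protein-coding genes. Implements the Goldman-Yang codon
    substitution model with branch-site Model A site classes, maximum
    likelihood fitting by Felsenstein pruning, likelihood ratio tests with
    Bonferroni correction, Naive Empirical Bayes identification of selected
    sites, and pairwise dN/dS estimation (maximum likelihood and Nei-Gojobori
    counting). Adds a scanner for clade-fixed derived nonsynonymous
    substitutions with chemical-change classification, projection of selected
    residues onto protein structures with minimum-distance proximity classes
    relative to annotated proton-channel residue sets, Kabsch superposition,
    extracellular-flux (oxygen consumption rate) derived metrics, genome
    composition statistics, and simulators for every input class with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    seqinr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
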