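Package: mitorelax
Title: Comparative Mitogenomics and Codon-Model Tests of Selective Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative characterization of avian
    mitochondrial genomes and for maximum-likelihood codon-model tests of
    selective relaxation. Parses and writes annotated mitogenomes (GenBank
    flatfile), extracts and translates genes under the vertebrate
    mitochondrial code with incomplete-stop and frameshift handling,
    computes base composition, AT/GC skews, amino-acid usage and relative
    synonymous codon usage, builds per-gene identity matrices and
    sliding-window entropy profiles, and annotates control-region domains,
    conserved blocks (ETAS/F/E/D/C/CSB/Bird Box), poly-C tracts, short
    tandem repeats and hairpin candidates. The selection engine implements
    GY94-style codon substitution models with F3x4 frequencies (M0, branch,
    free-ratios, M2a_rel, clade model C and branch-site model A) via
    Felsenstein pruning, likelihood-ratio tests, Nei-Gojobori dN/dS
    counting, and body-mass~omega regression. Seeded generators simulate
    annotated mitogenomes, codon alignments under branch- or clade-specific
    omega, and control-region haplotype sets with full truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
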