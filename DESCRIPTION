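Package: musakit
Title: Cytometric, Microsatellite and ITS Characterization of Wild Banana Accessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the molecular characterization of wild Musa (banana)
    germplasm. Estimates nuclear 2C DNA content from flow-cytometry histograms
    with an internal reference standard and converts it to monoploid genome
    size, performs ANOVA with Bonferroni all-pairwise grouping (compact letter
    display) and Spearman correlation of chromosome number against DNA amount,
    converts microsatellite (SSR) allele profiles to binary code and clusters
    accessions by Nei's genetic distance with UPGMA, and annotates
    ITS1-5.8S-ITS2 ribosomal DNA clone sequences: region delineation, GC
    content, conserved 5.8S motif scanning, ITS2/5.8S secondary-structure
    verification by base-pair maximization, putative pseudogene classification,
    nucleotide diversity, and Jukes-Cantor BioNJ phylogenies with bootstrap
    support. Includes deterministic simulators for flow histograms, SSR panels
    and ITS clone families with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'musakit-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'flowsize.R'
    'io.R'
    'its-annotate.R'
    'its-fold.R'
    'its-phylo.R'
    'simulate.R'
    'ssr.R'
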