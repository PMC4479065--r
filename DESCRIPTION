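Package: ldphase
Title: Linkage Disequilibrium, Gametic Phase Consistency and Ancestral
    Effective Population Size from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A multi-population analysis pipeline for medium-density SNP
    array genotypes (e.g. livestock 50k panels): per-population genotype
    quality control with per-criterion accounting; pairwise linkage
    disequilibrium from unphased genotypes via the Burrows-type composite
    disequilibrium estimator and r-squared, with adjacent-marker summaries,
    distance-binned decay curves and the Hill-Robertson small-sample
    correction; consistency of gametic phase between populations as the
    per-distance-bin Pearson correlation of signed r; ancestral effective
    population size from binned r-squared under Sved's drift-recombination
    expectation; and population structure through the VanRaden genomic
    relationship matrix and its principal components. A forward
    Wright-Fisher diploid simulator with recombination, population splits
    and admixture supplies phased ground truth for validation. Reads and
    writes PLINK text and binary genotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
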