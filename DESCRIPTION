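Package: flockdiv
Title: Pedigree and Genomic Genetic Diversity Analysis for Managed
    Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify genetic diversity and population structure in
    managed livestock populations from pedigree records and medium-density
    SNP genotypes. Implements pedigree validation and tracing, generation
    metrics and completeness, Meuwissen-Luo inbreeding coefficients, average
    relatedness, founder and ancestor analyses (effective numbers of founders
    and ancestors, marginal contributions, genetic conservation index), seven
    pedigree-based effective population size estimators and a linkage
    disequilibrium based genomic estimator, PLINK-format genotype input and
    quality control, runs of homozygosity, a hidden Markov model for
    homozygosity-by-descent, VanRaden genomic relationship matrices,
    heterozygosity statistics, flock-level fixation indices (pedigree
    coancestry based and Weir-Cockerham), and principal component analysis
    with per-flock subsampling. A gene-dropping simulator with tracked
    founder-haplotype identity-by-descent provides exact autozygosity truth
    for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
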