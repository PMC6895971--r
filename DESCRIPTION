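Package: rohsel
Title: Runs of Homozygosity, Demographic History and Selection Scans for SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for diploid autosomal SNP-array genotypes in
    structured livestock populations: PLINK text/binary input and output,
    marker and sample quality control with an exclusion ledger, run-of-
    homozygosity (ROH) detection with F_ROH and F_HOM inbreeding coefficients
    and ROH-island calling, a K-class homozygosity-by-descent hidden Markov
    model yielding class-partitioned autozygosity and F_G-T, historical
    effective population size from binned linkage-disequilibrium decay via
    Sved's relation, population differentiation (Reynolds distance,
    Weir-Cockerham FST, AMOVA, LD pruning, PCA, neighbour-joining tree), and
    a three-statistic selection scan (FST, nucleotide-diversity ratio,
    XP-EHH) with outlier intersection and region annotation. A synthetic-
    genotype module generates multi-population chip-like data with planted
    autozygous tracts, Balding-Nichols divergence, Wright-Fisher linkage
    disequilibrium and hard selective sweeps so every stage is verifiable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
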