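Package: ovisweep
Title: Population Structure and Selection-Signature Scans for SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for diploid biallelic SNP genotypes from
    livestock arrays: quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, Pi-HAT relatedness pruning, linkage
    disequilibrium pruning), genetic diversity (observed and expected
    heterozygosity, inbreeding coefficients), consecutive-method runs of
    homozygosity with F_ROH and group ROH islands, LD decay and effective
    population size trajectories from Sved's relation, Weir-Cockerham F_ST
    with permutation significance, windowed Z(F_ST) outlier scans, EHH-based
    cross-population XP-EHH scans, neighbor-joining trees and genotype PCA,
    and multi-evidence consensus calling of candidate selection regions.
    Includes a seeded synthetic-genotype generator (Balding-Nichols
    divergence, haplotype mosaics, injected sweeps and autozygous tracts,
    forward Wright-Fisher simulation) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
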